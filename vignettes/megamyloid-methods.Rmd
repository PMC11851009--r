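---
title: "Methods: amyloid-MEG association analysis with megamyloid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amyloid-MEG association analysis with megamyloid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megamyloid)
```

## What the package computes

`megamyloid` implements a longitudinal analysis linking amyloid-beta
burden (continuous PET binding potential, BP~ND~) to resting-state MEG
neurophysiology in cognitively unimpaired adults, including monozygotic
twin cohorts. The analysis chain is:

1. **Spectral analysis** — relative oscillatory power in six canonical
   bands (delta 0.5--4, theta 4--8, alpha1 8--10, alpha2 10--13, beta
   13--30, gamma 30--48 Hz), per epoch, per source region.
2. **Functional connectivity** — three pairwise statistics with
   complementary sensitivity profiles: inverted joint permutation
   entropy (JPE~inv~), leakage-corrected amplitude envelope correlation
   (AEC-c) and the phase lag index (PLI).
3. **ROI aggregation** — mapping region-level results onto three
   analysis levels: the early Alzheimer's disease composite ROI
   (bilateral posterior cingulate + orbitofrontal cortex), ROI-to-rest
   connectivity, and the whole brain (90-region parcellation, 78
   cortical + 12 sub-cortical).
4. **Inference** — linear mixed models with subject and family random
   intercepts, an amyloid-by-time interaction, interaction-gated model
   selection, permutation nulls of the t-statistic, annual-change
   models with explicit outlier screening, and Benjamini--Hochberg FDR
   over the primary measures.

Because source-space MEG recordings of real participants are not
distributable, the package ships a first-class synthetic-data module
that emulates the statistical structure this analysis assumes. All
validation is against that generator plus analytic limits and
brute-force oracles.

## The synthetic cohort generator

`generateCohort()` draws a two-visit cohort whose defaults are the
study conditions the pipeline targets: 110 individuals including 50
monozygotic twin pairs (10 singletons with unique family identifiers),
age 67.9 ± 5.7 years, visits 4.1 ± 0.3 years apart, baseline
whole-brain amyloid BP~ND~ 0.16 ± 0.11. Twins share family, age, sex
and (with intra-pair correlation 0.5 by default) part of their amyloid
burden. Follow-up amyloid is baseline plus an individual annual drift
times the individual interval. The drift defaults, 0.005 ± 0.025
BP~ND~/year, were chosen once so that the implied follow-up marginal is
approximately 0.18 ± 0.15; BP~ND~ values are truncated below at −0.1,
since binding-potential estimation is noisy around zero. An optional
"fast accumulator" injector produces participants with extreme annual
change (offset 8 drift SDs, which surfaces as an observed z-score near
6 after the outlier inflates the sample SD), to exercise the
outlier-screening path.

`generateRecording()` synthesizes source-space signals: each region is
a sum of band-limited stochastic oscillations — zero-phase Butterworth
filtered white noise, one component per band, scaled to the configured
relative amplitudes — plus white noise. This is deliberately *not* a
neural-mass model: it reproduces spectra and coupling structure, not
neuronal dynamics. Pairwise coupling comes in two modes that matter for
validating connectivity measures:

* `shared_lagged` — the pair shares a band-limited component inserted
  with a sample lag (genuine lagged interaction; visible to PLI and
  JPE~inv~);
* `shared_zero_lag` — the same component inserted instantaneously,
  which is exactly the signature of volume conduction / source leakage
  and must be rejected by the corrected measures.

With coupling strength $s$ the coupled band becomes
$\sqrt{1-s^2}\,\mathrm{own} + s\,\mathrm{shared}$, so band variance is
preserved and $s$ is interpretable as a mixing proportion. Lagged
insertion uses a circular shift, which keeps epochs stationary and
equal-length.

`attachEffects()` implements the generator's "true model" at the
signal level: theta amplitude is linear in standardized amyloid with
slope `effect_cross`, and its per-year change linear in amyloid with
slope `effect_interaction`. `simulateMeasure()` provides the same true
model directly at the outcome level (family + subject random intercepts
+ residual, calibrated to unit marginal variance so nominal slopes are
true standardized effects); parameter-recovery and type-I-error
simulations use this fast path because they need hundreds of replicate
model fits, not signal synthesis.

What the generator does **not** emulate: 1/f (aperiodic) spectral
structure, non-stationarity within or across epochs, spatially
structured leakage from a real forward model, artefacts (ocular,
cardiac), or realistic regional heterogeneity. Passing tests therefore
demonstrate correctness of the statistical machinery under the assumed
data-generating model, not robustness to every property of real MEG.

All randomness flows from one root seed through named substreams
(cohort, per-participant signals, measure simulation, permutations), so
any stage is reproducible in isolation and full pipeline runs are
byte-identical for a fixed configuration.

## Spectral conventions

Power uses a plain FFT periodogram of the demeaned epoch, one-sided and
Parseval-scaled so band powers sum to the signal variance. No taper is
applied by default (a Hann taper is available via `taper = "hann"`;
whether the original analysis tapered within an epoch is not public, so
the choice is exposed and documented rather than hidden). "Relative"
power is the band's share of total 0.5--48 Hz power — the union of the
six bands — which makes the six fractions sum to exactly 1. Band edges
are half-open intervals $[low, high)$: a bin exactly on a shared edge
belongs to the upper band, so the bands partition the analysis range
deterministically. Everything is computed per epoch and then averaged
per participant (epoch-then-average), never Welch-style across the
whole recording.

## Connectivity conventions

**JPE~inv~.** Both series are converted to ordinal symbols with
embedding dimension $n = 4$ and delay $\tau = 1$: window $t$ maps to
the permutation sorting $(x_t, x_{t+\tau}, \dots, x_{t+(n-1)\tau})$
ascending, with ties broken by temporal order (stable sort, no noise
injection — deterministic and reproducible). The joint distribution of
time-aligned symbol pairs forms a $24 \times 24$ matrix. For the
volume-conduction correction, cells whose symbols are identical or
opposite-sign are zero-weighted; the *opposite-sign* symbol is defined
as the ordinal pattern of the sign-flipped window, i.e. the reversed
argsort pattern, the only reading that makes the relation a mutual
involution (so the correction mask is symmetric and the statistic
symmetric in its arguments). Three details are conventions of this
implementation, stated here prominently because the measure's published
description does not fix them: after zeroing, the remaining mass is
**renormalized**; the Shannon entropy is taken in **base 2** and
normalized by $\log_2$ of the number of admissible cells
($24^2 - 2 \cdot 24 = 528$ when correcting); and the reported value is
the **inversion** $1 - H/H_{max}$, bounding JPE~inv~ in $[0, 1]$ with
higher values meaning stronger coupling. A pair whose joint mass is
entirely removed by the correction (e.g. $y = 2x$) returns 0 with a
`fully-leakage-degenerate` warning; a constant series is an error (no
ordinal variability). When a band is named (the pipeline's primary
measure is JPE~inv~ theta), the series are band-filtered first;
broadband mode is available.

**AEC-c.** Both series are zero-phase band-filtered (the pipeline's
envelope measure uses a merged alpha band, 8--13 Hz). Leakage
correction is pairwise time-domain least-squares orthogonalization in
both directions: the residual of $y$ on $x$ has exactly zero sample
covariance with $x$. Envelopes are magnitudes of the analytic signal
(frequency-domain Hilbert construction); filter and Hilbert edge
transients — one cycle of the lower band edge — are trimmed from both
ends before correlating. Each direction's correlation is mapped to
$[0,1]$ by $(r+1)/2$ (0.5 = no coupling) and the two directions are
averaged. Note that for very strong instantaneous mixing a small
second-order elevation above 0.5 remains: both mixtures' envelopes
co-vary with the magnitude of the shared component even after linear
orthogonalization. The tests therefore check central tendency near 0.5
and the large contrast against uncorrected AEC, not exact equality.

**PLI.** Instantaneous phases come from the analytic signal of the
band-filtered series, with the same edge trimming. The statistic is
$|\langle \mathrm{sign}(\sin \Delta\phi_t) \rangle|$: phase differences
at 0 mod $\pi$ contribute zero, which is what makes PLI insensitive to
zero-lag (volume-conducted) coupling; 1 indicates perfect locking at a
consistent non-zero lag.

All three measures are estimated per epoch over all unordered region
pairs and epoch-averaged into a symmetric `ConnectivityMatrix` with an
undefined (NA) diagonal.

## ROI mapping

The 90-region parcellation uses the standard automated anatomical
labelling region list (78 cortical, 12 sub-cortical). The early-disease
composite maps "bilateral posterior cingulate + orbitofrontal gyrus"
onto this parcellation as `Cingulum_Post` plus all orbital-cortex
labels (superior/middle/inferior/medial orbital and gyrus rectus),
bilaterally — 12 labels. The exact orbitofrontal subset is configurable
(`earlyADRoi(orbitofrontal = ...)`) because the PET-side ROI comes from
a different atlas and the mapping is not unique. ROI power is the
unweighted mean over member regions; ROI-to-rest connectivity averages
exactly the ROI-by-non-ROI pairs (within-ROI pairs excluded by
construction); whole-brain connectivity averages the strict upper
triangle (within-ROI pairs included). PET-side composites are out of
scope: the cohort table carries precomputed `abeta_early_roi` and
`abeta_whole_brain` columns.

## Mixed-model inference

The longitudinal model is

$$ z(\mathrm{MEG}) \sim z(\mathrm{A}\beta_{baseline}) + time +
z(\mathrm{A}\beta) \times time + z(age) + sex +
(1 | family/subject), $$

fitted by REML. Scaling conventions: outcome, amyloid and age are
z-scaled on the rows entering each model (so reported coefficients are
standardized effects comparable across models); time stays in years;
sex is 0/1 (F = 1). The random-effects structure nests subject
intercepts within family intercepts — a monozygotic twin pair is one
family; the nesting reading of "subject and family random effects" was
chosen over crossed effects because subjects never change family.
Parametric p-values use the t-statistic with residual-based degrees of
freedom ($n_{rows} - n_{fixed}$); they exist mainly to drive the
interaction gate. If the interaction is not significant at 0.05, the
cross-sectional association is re-estimated from a model without the
interaction term (`selectModel()`), and the provenance is recorded.

**Permutation nulls.** Because residual normality is not guaranteed,
each reported effect can be accompanied by a permutation p-value: the
participant-level baseline amyloid vector is shuffled across
individuals (both visits of a participant carry the same shuffled
value), the model is refitted, and the two-sided p-value is the add-one
estimator $(1 + \#\{|t^*| \ge |t_{obs}|\})/(B+1)$ over $B$ refits
(default 1000), which is never zero and bounded below by $1/(B+1)$.
Shuffling is done separately for the early-ROI and whole-brain amyloid
variables, matching the analysis level of each grid cell. The
permutation unit is the individual — the literal reading of shuffling
"across individuals" — with a family-level variant available as a
sensitivity option, since individual-level shuffling breaks twin
exchangeability. Scaling is computed once on the observed data and
reused inside the loop. Non-converged permutation refits are dropped
and counted; more than 10% failures is an error. Refits use the
modular lme4 interface (design matrices rebuilt per permutation, same
REML criterion), which is an order of magnitude faster than re-parsing
the model formula and numerically identical to `lmer()` — an equality
the test suite asserts against an independent `nlme` fit.

**Annual change.** Change is (follow-up − baseline)/interval per
participant. Before the change-on-change models, the amyloid change
columns are z-transformed and participants beyond $|z| > 4$ (default,
explicit and configurable) are excluded and reported — a stated rule
standing in for the ad-hoc removal of a single extreme accumulator; an
infinite threshold reproduces the unscreened sensitivity analysis. The
change model is $z(\Delta \mathrm{MEG}) \sim z(\Delta \mathrm{A}\beta)
+ z(age) + sex + (1|family)$.

**Multiplicity.** FDR q-values are computed per result table over the
primary-measure cells only — relative theta power and JPE~inv~ theta
across the three level pairings (6 tests) — because the original family
definition is not fully specified; the family is configurable in code.
Secondary measures carry uncorrected p-values only.

## Numerical choices and degenerate inputs

* Butterworth order 4 (effective order doubled by the forward-backward
  pass); stable down to the delta band at 312 Hz.
* Analytic signal by zeroing negative frequencies in the FFT;
  edge trimming one cycle of the low band edge, capped so at least half
  the epoch (and at least 64 samples) remains.
* Ordinal ranks computed by vectorized pairwise comparison with the
  stable tie rule; symbol tables (pattern list, opposite-symbol map,
  admissibility mask) cached per embedding dimension.
* Zero-probability cells contribute 0 to the entropy; degenerate
  spectra (zero total power), constant series, zero-variance envelopes
  and constant analytic phases are errors, not silent NaNs.
* Singular mixed-model fits (a variance component estimated at zero,
  common in small synthetic cohorts) are warnings and flagged in the
  result, not errors.
* Grid cells whose model cannot be fitted are recorded as explicit
  error rows; the grid stays complete.

## Problem sizes used in the shipped validation

The test suite exercises the full geometry (90 regions, 10 × 4096
samples at 312 Hz) where the contract is about shape, and reduced
geometries (2--6 regions, 1--3 epochs of 256--4096 samples) where the
contract is statistical, with replicate counts chosen to keep each
property identifiable: 200 null cohorts of n = 40 at B = 99 for the
type-I error of the permutation test (empirical rate required in
[0.02, 0.09] at the nominal 0.05), 100 replicates at the full n = 110
for recovery of standardized slopes 0.2 (cross-sectional) and 0.1
(interaction) within ±0.05 mean bias, and exhaustive enumeration over
all 3-letter series of length 6 (plus randomized lengths up to 12) for
the ordinal-symbol machinery against a brute-force oracle.

## Known limitations

* The generator's signals are filtered noise: results say nothing about
  robustness to aperiodic-component shifts, artefacts, or realistic
  leakage geometry.
* JPE~inv~ normalization and inversion are this implementation's
  conventions (documented above); absolute values are comparable within
  the package, not necessarily across other implementations.
* The parametric p-values use a residual-df approximation rather than
  Satterthwaite/Kenward-Roger corrections; the permutation p-values are
  the inferential workhorse.
* Individual-level permutation breaks family exchangeability; the
  family-level variant exists but is not the default, matching the
  analysis this package mirrors.
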