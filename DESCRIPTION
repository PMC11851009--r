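Package: megamyloid
Title: Longitudinal Amyloid-MEG Association Analysis for Source-Space
    Neurophysiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for linking amyloid-beta burden to resting-state
    magnetoencephalography (MEG) measures in longitudinal cohorts.
    Implements relative oscillatory band power, three leakage-aware
    functional-connectivity statistics (inverted joint permutation
    entropy, orthogonalized amplitude envelope correlation, phase lag
    index), region-of-interest aggregation over a 90-region source
    parcellation, and linear mixed-model inference with permutation
    nulls, annual-change models, outlier screening and false discovery
    rate control. A synthetic-data module generates twin cohorts and
    coupled oscillatory source signals so the full pipeline can be
    exercised and validated without access to participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nlme,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'parcellation.R'
    'synthdata-cohort.R'
    'synthdata-signals.R'
    'synthdata-effects.R'
    'spectral.R'
    'connectivity-ordinal.R'
    'connectivity-envelope.R'
    'connectivity-phase.R'
    'connectivity-matrix.R'
    'aggregate.R'
    'stats-scale.R'
    'stats-lmm.R'
    'stats-permutation.R'
    'stats-change.R'
    'stats-grid.R'
    'io-recording.R'
    'io-cohort.R'
    'report.R'
    'pipeline.R'
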