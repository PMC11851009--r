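# Independent brute-force oracles used across the suite. These stay
# deliberately naive (explicit loops, direct definitions) so they cannot
# share a defect with the vectorized implementation paths.

# Stable argsort pattern of one window, 0-based: positions of the values
# in ascending order, ties broken by temporal position.
oracle_pattern <- function(w) order(w) - 1L

# Joint histogram of time-aligned ordinal patterns by direct enumeration
# of every embedded window; returns an n! x n! count matrix indexed by
# the lexicographic pattern order used by symbolPatterns().
oracle_joint_counts <- function(x, y, n = 4L, tau = 1L) {
  pats <- symbolPatterns(n)
  pat_key <- apply(pats, 1L, paste, collapse = ",")
  L <- length(x) - (n - 1L) * tau
  counts <- matrix(0L, nrow(pats), nrow(pats))
  for (t in seq_len(L)) {
    idx <- t + (0:(n - 1L)) * tau
    sx <- match(paste(oracle_pattern(x[idx]), collapse = ","), pat_key)
    sy <- match(paste(oracle_pattern(y[idx]), collapse = ","), pat_key)
    counts[sx, sy] <- counts[sx, sy] + 1L
  }
  counts
}

# Corrected, normalized, inverted joint permutation entropy computed
# directly from the definition.
oracle_jpe_inv <- function(x, y, n = 4L, tau = 1L, correct = TRUE) {
  counts <- oracle_joint_counts(x, y, n, tau)
  pats <- symbolPatterns(n)
  nf <- nrow(pats)
  if (correct) {
    for (i in seq_len(nf)) {
      counts[i, i] <- 0L
      opp <- which(apply(pats, 1L, function(p) {
        all(p == rev(pats[i, ]))
      }))
      counts[i, opp] <- 0L
    }
    n_adm <- nf * nf - 2L * nf
  } else {
    n_adm <- nf * nf
  }
  if (sum(counts) == 0L) return(0)
  p <- counts[counts > 0L] / sum(counts)
  1 - (-sum(p * log2(p))) / log2(n_adm)
}

# Small standard recording for fixture use.
tiny_recording <- function(n_regions = 4L, n_epochs = 2L, epoch_len = 512L,
                           seed = 1L, coupling = NULL) {
  generateRecording(
    "P001",
    signalConfig(
      n_regions = n_regions, n_epochs = n_epochs, epoch_len = epoch_len,
      coupling = coupling, seed = seed
    )
  )
}

# Long-format cohort with a directly simulated outcome measure.
simulated_cohort <- function(n = 40L, pairs = 18L, effect_cross = 0,
                             effect_interaction = 0, seed = 1L,
                             measure_seed = seed + 1000L) {
  cohort <- generateCohort(cohortConfig(
    n_individuals = n, n_twin_pairs = pairs, seed = seed
  ))
  simulateMeasure(cohort,
    effect_cross = effect_cross,
    effect_interaction = effect_interaction, seed = measure_seed
  )
}
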