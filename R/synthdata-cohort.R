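# All generator randomness flows from one root seed through named
# substreams so each component is reproducible in isolation.
.substreamSeed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  (as.integer(seed) %% 1000003L) * 2011L + (h %% 2011L)
}

.withSeed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

.checkField <- function(ok, field, why) {
  if (!isTRUE(ok)) {
    stop("invalid cohort configuration: field '", field, "' ", why,
      call. = FALSE
    )
  }
}

#' Configuration for the synthetic twin cohort generator
#'
#' Defaults emulate the study cohort the pipeline targets: 110 cognitively
#' unimpaired individuals including 50 monozygotic twin pairs (so 10
#' singletons), age 67.9 +/- 5.7 years, two visits 4.1 +/- 0.3 years apart,
#' baseline whole-brain amyloid binding potential (BP_ND) 0.16 +/- 0.11.
#' The annual amyloid drift defaults (0.005 +/- 0.025 BP_ND/year) reproduce
#' the follow-up marginal of roughly 0.18 +/- 0.15.
#'
#' @param n_individuals number of participants.
#' @param n_twin_pairs number of monozygotic twin pairs
#'   (`2 * n_twin_pairs <= n_individuals`); twins share family, age and sex.
#' @param age_mean,age_sd baseline age distribution (years).
#' @param sex_fraction_female expected fraction of female participants.
#' @param followup_mean,followup_sd follow-up interval (years).
#' @param abeta_baseline_mean,abeta_baseline_sd baseline whole-brain
#'   amyloid BP_ND marginal (dimensionless).
#' @param abeta_annual_drift_mean,abeta_annual_drift_sd per-year amyloid
#'   accumulation rate (BP_ND/year).
#' @param abeta_floor lower truncation for BP_ND values; binding-potential
#'   estimates are noisy around zero and mildly negative values occur.
#' @param abeta_twin_icc intra-pair correlation of baseline amyloid.
#' @param abeta_early_cor correlation between early-ROI and whole-brain
#'   amyloid burden.
#' @param family_sd,subject_sd,residual_sd random-effect and residual
#'   standard deviations used when simulating outcome measures directly
#'   (see [simulateMeasure()]); on the standardized outcome scale.
#' @param effect_cross true standardized cross-sectional amyloid-to-outcome
#'   slope used by [attachEffects()] and [simulateMeasure()].
#' @param effect_interaction true amyloid-by-time slope (per year).
#' @param n_fast_accumulators number of injected "fast accumulator"
#'   participants with extreme annual amyloid change, for exercising the
#'   outlier-exclusion path.
#' @param fast_accumulator_z drift offset of injected accumulators, in
#'   units of `abeta_annual_drift_sd`.
#' @param seed integer root seed.
#' @return A list with class `"CohortConfig"`.
#' @examples
#' cfg <- cohortConfig(n_individuals = 10, n_twin_pairs = 4, seed = 1)
#' nrow(generateCohort(cfg))
#' @export
cohortConfig <- function(n_individuals = 110L,
                         n_twin_pairs = 50L,
                         age_mean = 67.9, age_sd = 5.7,
                         sex_fraction_female = 0.53,
                         followup_mean = 4.1, followup_sd = 0.3,
                         abeta_baseline_mean = 0.16,
                         abeta_baseline_sd = 0.11,
                         abeta_annual_drift_mean = 0.005,
                         abeta_annual_drift_sd = 0.025,
                         abeta_floor = -0.1,
                         abeta_twin_icc = 0.5,
                         abeta_early_cor = 0.9,
                         family_sd = 0.35, subject_sd = 0.45,
                         residual_sd = 0.55,
                         effect_cross = 0, effect_interaction = 0,
                         n_fast_accumulators = 0L,
                         fast_accumulator_z = 8,
                         seed = 1L) {
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    n_twin_pairs = as.integer(n_twin_pairs),
    age_mean = age_mean, age_sd = age_sd,
    sex_fraction_female = sex_fraction_female,
    followup_mean = followup_mean, followup_sd = followup_sd,
    abeta_baseline_mean = abeta_baseline_mean,
    abeta_baseline_sd = abeta_baseline_sd,
    abeta_annual_drift_mean = abeta_annual_drift_mean,
    abeta_annual_drift_sd = abeta_annual_drift_sd,
    abeta_floor = abeta_floor,
    abeta_twin_icc = abeta_twin_icc,
    abeta_early_cor = abeta_early_cor,
    family_sd = family_sd, subject_sd = subject_sd,
    residual_sd = residual_sd,
    effect_cross = effect_cross, effect_interaction = effect_interaction,
    n_fast_accumulators = as.integer(n_fast_accumulators),
    fast_accumulator_z = fast_accumulator_z,
    seed = as.integer(seed)
  )
  class(cfg) <- "CohortConfig"
  validateCohortConfig(cfg)
  cfg
}

#' Validate a cohort configuration
#'
#' @param cfg a `CohortConfig`.
#' @return `cfg`, invisibly, or an error naming the offending field.
#' @export
validateCohortConfig <- function(cfg) {
  .checkField(cfg$n_individuals >= 1L, "n_individuals", "must be >= 1")
  .checkField(cfg$n_twin_pairs >= 0L, "n_twin_pairs", "must be >= 0")
  .checkField(
    2L * cfg$n_twin_pairs <= cfg$n_individuals, "n_twin_pairs",
    "requires 2 * n_twin_pairs <= n_individuals"
  )
  for (f in c(
    "age_sd", "followup_sd", "abeta_baseline_sd", "abeta_annual_drift_sd",
    "family_sd", "subject_sd", "residual_sd"
  )) {
    .checkField(cfg[[f]] >= 0, f, "must be >= 0")
  }
  for (f in c("sex_fraction_female", "abeta_twin_icc")) {
    .checkField(cfg[[f]] >= 0 && cfg[[f]] <= 1, f, "must lie in [0, 1]")
  }
  .checkField(
    abs(cfg$abeta_early_cor) <= 1, "abeta_early_cor",
    "must lie in [-1, 1]"
  )
  .checkField(cfg$followup_mean > 0, "followup_mean", "must be > 0")
  .checkField(
    cfg$n_fast_accumulators <= cfg$n_individuals, "n_fast_accumulators",
    "cannot exceed n_individuals"
  )
  invisible(cfg)
}

#' Generate a synthetic two-visit twin cohort
#'
#' Draws a long-format participant-by-visit table with the clustering
#' structure the downstream mixed models assume: monozygotic twins share a
#' family identifier, age, sex and part of their amyloid burden; singletons
#' get unique family identifiers. Each participant contributes exactly one
#' baseline row (`time_since_baseline == 0`) and one follow-up row.
#' Follow-up amyloid is baseline plus an individual annual drift times the
#' individual follow-up interval; all BP_ND values are truncated below at
#' `cfg$abeta_floor`.
#'
#' @param cfg a [cohortConfig()] object.
#' @return A `data.frame` with columns `participant_id`, `family_id`,
#'   `age`, `sex` (`"F"`/`"M"`), `visit`, `time_since_baseline`,
#'   `abeta_early_roi`, `abeta_whole_brain`, plus per-participant annual
#'   drift columns (`drift_early_roi`, `drift_whole_brain`) retained as
#'   generator ground truth.
#' @examples
#' tab <- generateCohort(cohortConfig(seed = 1))
#' table(tab$visit)
#' @export
generateCohort <- function(cfg) {
  validateCohortConfig(cfg)
  n <- cfg$n_individuals
  npair <- cfg$n_twin_pairs
  .withSeed(.substreamSeed(cfg$seed, "cohort"), {
    family_of <- c(rep(seq_len(npair), each = 2L),
      npair + seq_len(n - 2L * npair)
    )
    n_fam <- max(family_of)
    fam_age <- stats::rnorm(n_fam, cfg$age_mean, cfg$age_sd)
    fam_sex <- stats::rbinom(n_fam, 1L, cfg$sex_fraction_female)

    z_fam <- stats::rnorm(n_fam)
    z_ind <- stats::rnorm(n)
    icc <- cfg$abeta_twin_icc
    z_wb <- sqrt(icc) * z_fam[family_of] + sqrt(1 - icc) * z_ind
    rho <- cfg$abeta_early_cor
    z_early <- rho * z_wb + sqrt(1 - rho^2) * stats::rnorm(n)
    ab_wb <- pmax(
      cfg$abeta_baseline_mean + cfg$abeta_baseline_sd * z_wb,
      cfg$abeta_floor
    )
    ab_early <- pmax(
      cfg$abeta_baseline_mean + cfg$abeta_baseline_sd * z_early,
      cfg$abeta_floor
    )

    interval <- pmax(
      stats::rnorm(n, cfg$followup_mean, cfg$followup_sd), 0.5
    )
    zd_wb <- stats::rnorm(n)
    zd_early <- rho * zd_wb + sqrt(1 - rho^2) * stats::rnorm(n)
    if (cfg$n_fast_accumulators > 0L) {
      idx <- sample.int(n, cfg$n_fast_accumulators)
      zd_wb[idx] <- cfg$fast_accumulator_z
      zd_early[idx] <- cfg$fast_accumulator_z
    }
    drift_wb <- cfg$abeta_annual_drift_mean +
      cfg$abeta_annual_drift_sd * zd_wb
    drift_early <- cfg$abeta_annual_drift_mean +
      cfg$abeta_annual_drift_sd * zd_early

    fu_wb <- pmax(ab_wb + drift_wb * interval, cfg$abeta_floor)
    fu_early <- pmax(ab_early + drift_early * interval, cfg$abeta_floor)

    ids <- sprintf("P%03d", seq_len(n))
    base <- data.frame(
      participant_id = ids,
      family_id = sprintf("F%03d", family_of),
      age = fam_age[family_of],
      sex = ifelse(fam_sex[family_of] == 1L, "F", "M"),
      visit = "baseline",
      time_since_baseline = 0,
      abeta_early_roi = ab_early,
      abeta_whole_brain = ab_wb,
      drift_early_roi = drift_early,
      drift_whole_brain = drift_wb,
      stringsAsFactors = FALSE
    )
    fup <- base
    fup$visit <- "followup"
    fup$time_since_baseline <- interval
    fup$abeta_early_roi <- fu_early
    fup$abeta_whole_brain <- fu_wb
    out <- rbind(base, fup)
    rownames(out) <- NULL
    attr(out, "cohort_config") <- cfg
    out
  })
}
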