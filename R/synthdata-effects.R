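#' Attach amyloid-dependent effects to per-visit signal configurations
#'
#' Implements the generator's "true model" at the signal level: the theta
#' band amplitude is made linear in standardized baseline amyloid burden
#' with slope `effect_cross`, and its per-year change linear in amyloid
#' with slope `effect_interaction`, so that downstream spectral and
#' connectivity analyses face a known ground truth. With both effects
#' zero, all participants receive exchangeable configurations.
#'
#' @param cohort a cohort table from [generateCohort()].
#' @param base_config a [signalConfig()] used as template for every
#'   participant-visit.
#' @param effect_cross standardized cross-sectional slope of theta
#'   amplitude on amyloid; defaults to the cohort config's value.
#' @param effect_interaction amyloid-by-time slope per year.
#' @param abeta_var which amyloid column drives the effect.
#' @return A list with components `configs` (named list of `SignalConfig`,
#'   one per participant-visit, names `"<id>.<visit>"`) and `truth`
#'   (data.frame sidecar: participant, visit, time, standardized amyloid,
#'   imposed theta amplitude) for recovery tests.
#' @export
attachEffects <- function(cohort, base_config,
                          effect_cross = NULL, effect_interaction = NULL,
                          abeta_var = "abeta_whole_brain") {
  cfg0 <- attr(cohort, "cohort_config")
  if (is.null(effect_cross)) {
    effect_cross <- if (is.null(cfg0)) 0 else cfg0$effect_cross
  }
  if (is.null(effect_interaction)) {
    effect_interaction <- if (is.null(cfg0)) 0 else cfg0$effect_interaction
  }
  base <- cohort[cohort$visit == "baseline", , drop = FALSE]
  ab <- base[[abeta_var]]
  z <- if (stats::sd(ab) > 0) (ab - mean(ab)) / stats::sd(ab) else ab * 0
  names(z) <- base$participant_id

  amp0 <- base_config$band_amplitudes[["theta"]]
  configs <- list()
  truth <- NULL
  for (r in seq_len(nrow(cohort))) {
    id <- cohort$participant_id[r]
    visit <- cohort$visit[r]
    tt <- cohort$time_since_baseline[r]
    mult <- 1 + effect_cross * z[[id]] + effect_interaction * z[[id]] * tt
    mult <- max(mult, 0.05) # amplitudes cannot go negative
    cfg <- base_config
    cfg$band_amplitudes[["theta"]] <- amp0 * mult
    cfg$seed <- .substreamSeed(base_config$seed, paste0("fx:", id, visit))
    configs[[paste(id, visit, sep = ".")]] <- cfg
    truth <- rbind(truth, data.frame(
      participant_id = id, visit = visit, time = tt,
      z_abeta = z[[id]], theta_amplitude = amp0 * mult,
      stringsAsFactors = FALSE
    ))
  }
  list(
    configs = configs, truth = truth,
    effect_cross = effect_cross, effect_interaction = effect_interaction
  )
}

#' Simulate an outcome measure directly from the mixed-model truth
#'
#' Bypasses signal synthesis and draws a participant-visit outcome from
#' the generative model the longitudinal analysis assumes:
#' `y = b_c * z(abeta) + b_i * z(abeta) * time + u_family + u_subject + e`,
#' with Gaussian random intercepts for family and subject. The noise
#' components are calibrated so the marginal outcome variance is 1; the
#' nominal slopes are then true *standardized* effects, directly
#' comparable to the standardized coefficients the mixed models report.
#'
#' @param cohort a cohort table from [generateCohort()].
#' @param effect_cross true standardized cross-sectional slope.
#' @param effect_interaction true amyloid-by-time slope (per year).
#' @param abeta_var amyloid column driving the effect.
#' @param family_sd,subject_sd,residual_sd relative sizes of the noise
#'   components; rescaled jointly so total outcome variance is 1.
#'   Defaults come from the cohort's configuration.
#' @param seed integer seed; defaults to a substream of the cohort seed.
#' @return The cohort table with an added `outcome` column and attribute
#'   `"measure_truth"` (list of the true slopes and variance components).
#' @examples
#' cohort <- generateCohort(cohortConfig(seed = 2))
#' sim <- simulateMeasure(cohort, effect_cross = 0.2)
#' @export
simulateMeasure <- function(cohort, effect_cross = NULL,
                            effect_interaction = NULL,
                            abeta_var = "abeta_whole_brain",
                            family_sd = NULL, subject_sd = NULL,
                            residual_sd = NULL, seed = NULL) {
  cfg0 <- attr(cohort, "cohort_config")
  take <- function(x, f, d) {
    if (!is.null(x)) x else if (!is.null(cfg0)) cfg0[[f]] else d
  }
  effect_cross <- take(effect_cross, "effect_cross", 0)
  effect_interaction <- take(effect_interaction, "effect_interaction", 0)
  family_sd <- take(family_sd, "family_sd", 0.35)
  subject_sd <- take(subject_sd, "subject_sd", 0.45)
  residual_sd <- take(residual_sd, "residual_sd", 0.55)
  if (is.null(seed)) {
    seed <- .substreamSeed(if (is.null(cfg0)) 1L else cfg0$seed, "measure")
  }

  base <- cohort[cohort$visit == "baseline", , drop = FALSE]
  ab <- base[[abeta_var]]
  sdab <- stats::sd(ab)
  z <- if (sdab > 0) (ab - mean(ab)) / sdab else ab * 0
  names(z) <- base$participant_id
  zr <- z[cohort$participant_id]
  tt <- cohort$time_since_baseline
  fixed <- effect_cross * zr + effect_interaction * zr * tt

  vfix <- mean((fixed - mean(fixed))^2)
  rem <- 1 - vfix
  if (rem <= 0) {
    stop("effects too large: fixed-part variance >= 1, cannot calibrate")
  }
  w <- c(family_sd, subject_sd, residual_sd)^2
  if (sum(w) == 0) {
    vc <- c(0, 0, 0)
  } else {
    vc <- rem * w / sum(w)
  }

  fam <- factor(cohort$family_id)
  subj <- factor(cohort$participant_id)
  out <- .withSeed(seed, {
    u_fam <- stats::rnorm(nlevels(fam), 0, sqrt(vc[1L]))
    u_sub <- stats::rnorm(nlevels(subj), 0, sqrt(vc[2L]))
    fixed + u_fam[as.integer(fam)] + u_sub[as.integer(subj)] +
      stats::rnorm(nrow(cohort), 0, sqrt(vc[3L]))
  })
  cohort$outcome <- as.numeric(out)
  attr(cohort, "measure_truth") <- list(
    effect_cross = effect_cross, effect_interaction = effect_interaction,
    var_family = vc[1L], var_subject = vc[2L], var_residual = vc[3L]
  )
  cohort
}
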