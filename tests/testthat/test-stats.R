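test_that("z-scaling matches the direct computation and is idempotent", {
  tab <- data.frame(a = c(1, 2, 3), b = c(5, 5, 8))
  sc <- zScale(tab, "a")
  expect_equal(sc$a, c(-1, 0, 1))
  expect_equal(mean(sc$a), 0)
  expect_equal(sd(sc$a), 1)
  set.seed(1)
  r <- data.frame(x = rnorm(50, 10, 3))
  expect_equal(zScale(r, "x")$x, (r$x - mean(r$x)) / sd(r$x))
  expect_equal(zScale(zScale(r, "x"), "x"), zScale(r, "x"), tolerance = 1e-12)
  expect_error(zScale(data.frame(k = rep(2, 5)), "k"), "'k' has zero variance")
})

test_that("BH q-values follow the step-up rule and respect ordering", {
  expect_equal(fdrCorrect(0.04), 0.04)
  expect_equal(fdrCorrect(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(fdrCorrect(rep(1, 4)), rep(1, 4))
  set.seed(2)
  p <- runif(20)
  q <- fdrCorrect(p)
  expect_true(all(q >= p))
  o <- sample(20)
  expect_equal(fdrCorrect(p[o]), q[o])
  expect_error(fdrCorrect(c(0.5, 1.2)), "0, 1")
})

test_that("annual change divides the visit difference by the interval", {
  cohort <- generateCohort(cohortConfig(
    n_individuals = 12, n_twin_pairs = 5, seed = 4
  ))
  ch <- annualChange(cohort, c("abeta_whole_brain", "abeta_early_roi"))
  expect_equal(nrow(ch), 12)
  base <- cohort[cohort$visit == "baseline", ]
  fup <- cohort[cohort$visit == "followup", ]
  m <- match(base$participant_id, fup$participant_id)
  expect_equal(
    ch$change_abeta_whole_brain,
    (fup$abeta_whole_brain[m] - base$abeta_whole_brain) /
      fup$time_since_baseline[m]
  )
  # equal visits give zero change; simple arithmetic case
  same <- cohort
  same$abeta_whole_brain <- 0.2
  expect_equal(
    annualChange(same, "abeta_whole_brain")$change_abeta_whole_brain,
    rep(0, 12)
  )
  two <- data.frame(
    participant_id = c("P1", "P1"), family_id = "F1", age = 70,
    sex = "F", visit = c("baseline", "followup"),
    time_since_baseline = c(0, 4), v = c(0.16, 0.18)
  )
  expect_equal(annualChange(two, "v")$change_v, 0.005)
  bad <- two
  bad$time_since_baseline <- c(0, -1)
  expect_error(annualChange(bad, "v"), "non-positive")
})

test_that("outlier screening excludes exactly the injected fast accumulator", {
  cohort <- generateCohort(cohortConfig(
    n_individuals = 110, n_twin_pairs = 50, n_fast_accumulators = 1,
    seed = 6
  ))
  truth_id <- cohort$participant_id[
    which.max(cohort$drift_whole_brain)
  ]
  ch <- annualChange(cohort, c("abeta_whole_brain", "abeta_early_roi"))
  out <- detectOutliers(ch, threshold = 4)
  expect_setequal(unique(out$excluded$participant_id), truth_id)
  expect_equal(nrow(out$kept), 109)
  expect_gt(min(abs(out$excluded$z)), 4)
  # no screening with an infinite threshold; clean cohorts keep everyone
  expect_null(detectOutliers(ch, threshold = Inf)$excluded)
  clean <- annualChange(generateCohort(cohortConfig(seed = 7)),
    "abeta_whole_brain"
  )
  expect_null(detectOutliers(clean, threshold = 4)$excluded)
})

test_that("the longitudinal mixed model agrees with an independent fitter", {
  sim <- simulated_cohort(
    n = 60, pairs = 25, effect_cross = 0.3, effect_interaction = 0.1,
    seed = 8
  )
  fit <- suppressWarnings(fitLongitudinal(sim, "outcome", "abeta_whole_brain"))
  co <- fit$coefficients
  expect_setequal(
    co$term, c("(Intercept)", "pred", "time", "age", "sex", "pred:time")
  )
  # independent route: nlme on the identical prepared data
  d <- fit$prepared
  ref <- nlme::lme(
    y ~ pred + time + age + sex + pred:time,
    random = ~ 1 | family_id / participant_id,
    data = d, method = "REML",
    control = nlme::lmeControl(opt = "optim", returnObject = TRUE)
  )
  fe <- nlme::fixef(ref)
  expect_equal(co$beta[match(names(fe), co$term)], unname(fe),
    tolerance = 1e-3
  )
})

test_that("model selection gates on the interaction and refits reduced", {
  strong <- simulated_cohort(
    n = 80, pairs = 30, effect_cross = 0.2, effect_interaction = 0.25,
    seed = 9
  )
  fit <- suppressWarnings(fitLongitudinal(strong, "outcome", "abeta_whole_brain"))
  kept <- suppressWarnings(selectModel(fit))
  expect_true(kept$interaction_retained)
  expect_true("pred:time" %in% kept$coefficients$term)

  cross_only <- simulated_cohort(
    n = 80, pairs = 30, effect_cross = 0.3, effect_interaction = 0,
    seed = 10
  )
  fit2 <- suppressWarnings(fitLongitudinal(cross_only, "outcome",
    "abeta_whole_brain"))
  sel2 <- suppressWarnings(selectModel(fit2))
  if (!sel2$interaction_retained) {
    expect_false("pred:time" %in% sel2$coefficients$term)
  }
})

test_that("a pure cross-sectional effect is recovered by the reduced model", {
  est <- vapply(1:20, function(i) {
    sim <- simulated_cohort(
      n = 110, pairs = 50, effect_cross = 0.3, effect_interaction = 0,
      seed = 100 + i, measure_seed = 900 + i
    )
    fit <- suppressWarnings(
      fitLongitudinal(sim, "outcome", "abeta_whole_brain")
    )
    sel <- suppressWarnings(selectModel(fit))
    sel$coefficients$beta[sel$coefficients$term == "pred"]
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.3), 0.1)
})

test_that("permutation p-values respect the add-one estimator bounds", {
  sim <- simulated_cohort(
    n = 30, pairs = 12, effect_cross = 0.8, seed = 11
  )
  fit <- suppressWarnings(fitLongitudinal(sim, "outcome", "abeta_whole_brain"))
  one <- permutationPvalue(fit, B = 1, effect = "main", seed = 1)
  expect_true(one$p_perm %in% c(0.5, 1))
  # a dominant effect should beat every permutation: p = 1/(B+1)
  strong <- permutationPvalue(fit, B = 39, effect = "main", seed = 2)
  expect_equal(strong$p_perm, 1 / 40)
  # deterministic for a fixed seed
  again <- permutationPvalue(fit, B = 39, effect = "main", seed = 2)
  expect_identical(strong$p_perm, again$p_perm)
  expect_gte(strong$p_perm, 1 / 40)
})

test_that("the change model recovers a coupled-drift slope and twin clustering inflates SEs", {
  # coupled annual drifts with known standardized slope
  set.seed(12)
  reps <- vapply(1:10, function(i) {
    cohort <- generateCohort(cohortConfig(
      n_individuals = 107, n_twin_pairs = 48, seed = 200 + i
    ))
    ch <- annualChange(cohort, "abeta_whole_brain")
    zx <- scale(ch$change_abeta_whole_brain)[, 1]
    ch$change_meg <- 0.3 * zx + sqrt(1 - 0.09) * rnorm(107)
    fit <- suppressWarnings(
      fitChangeModel(ch, "change_meg", "change_abeta_whole_brain")
    )
    fit$coefficients$beta[fit$coefficients$term == "pred"]
  }, numeric(1))
  expect_lt(abs(mean(reps) - 0.3), 0.1)

  # strong family clustering of a between-family predictor: twins are
  # duplicated observations, so the naive OLS SE is too small and the
  # family-aware mixed model must report a larger one
  set.seed(14)
  n_fam <- 30
  pred_f <- rnorm(n_fam)
  u <- rnorm(n_fam, 0, 1.5)
  ch <- data.frame(
    participant_id = sprintf("P%03d", 1:(2 * n_fam)),
    family_id = rep(sprintf("F%03d", 1:n_fam), each = 2),
    age = rep(rnorm(n_fam, 68, 5), each = 2),
    sex = rep(sample(c("F", "M"), n_fam, replace = TRUE), each = 2),
    followup_time = 4,
    change_abeta_whole_brain = rep(pred_f, each = 2),
    stringsAsFactors = FALSE
  )
  ch$change_meg <- 0.1 * rep(pred_f, each = 2) + rep(u, each = 2) +
    0.3 * rnorm(2 * n_fam)
  fit <- suppressWarnings(
    fitChangeModel(ch, "change_meg", "change_abeta_whole_brain")
  )
  dd <- fit$prepared
  ols <- summary(lm(y ~ pred + age + sex, data = dd))
  se_mixed <- fit$coefficients$se[fit$coefficients$term == "pred"]
  se_ols <- ols$coefficients["pred", "Std. Error"]
  expect_gt(se_mixed, se_ols)
})

test_that("the analysis grid is complete and localizes an injected theta effect", {
  # synthetic measure table built directly: 18 level-measure-band cells
  cohort <- generateCohort(cohortConfig(
    n_individuals = 120, n_twin_pairs = 55, seed = 15
  ))
  cells <- expand.grid(
    analysis_level = c("early_roi", "whole_brain"),
    measure = "rel_power",
    band = c("delta", "theta", "alpha1", "alpha2", "beta", "gamma"),
    stringsAsFactors = FALSE
  )
  conn <- expand.grid(
    analysis_level = c("early_roi_to_rest", "whole_brain"),
    measure = c("jpe_inv", "aec_c", "pli"),
    stringsAsFactors = FALSE
  )
  conn$band <- ifelse(conn$measure == "aec_c", "alpha", "theta")
  cells <- rbind(cells, conn)
  measures <- do.call(rbind, lapply(seq_len(nrow(cells)), function(k) {
    eff <- if (cells$band[k] == "theta" && cells$measure[k] == "rel_power") {
      0.5
    } else {
      0
    }
    sim <- simulateMeasure(cohort,
      effect_cross = eff, effect_interaction = 0,
      seed = 300 + k
    )
    data.frame(
      participant_id = sim$participant_id, visit = sim$visit,
      analysis_level = cells$analysis_level[k], measure = cells$measure[k],
      band = cells$band[k], value = sim$outcome, stringsAsFactors = FALSE
    )
  }))
  res <- suppressWarnings(runGrid(measures, cohort,
    directions = "abeta_to_meg", B = 0, seed = 16
  ))
  expect_equal(nrow(res$cross_sectional), 27)
  expect_equal(nrow(res$longitudinal), 27)
  expect_equal(sum(res$cross_sectional$primary), 6)
  expect_equal(sum(!is.na(res$cross_sectional$q)), 6)
  cs <- res$cross_sectional
  theta_p <- cs$p[cs$measure == "rel_power" & cs$band == "theta"]
  other_p <- cs$p[!(cs$measure == "rel_power" & cs$band == "theta")]
  expect_true(all(theta_p < 0.05))
  expect_gt(median(other_p), 0.1)
})
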