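test_that("cohort generation is deterministic and respects the twin design", {
  cfg <- cohortConfig(n_individuals = 30, n_twin_pairs = 12, seed = 7)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(a, b)
  expect_false(identical(
    a$abeta_whole_brain,
    generateCohort(cohortConfig(
      n_individuals = 30, n_twin_pairs = 12, seed = 8
    ))$abeta_whole_brain
  ))

  base <- a[a$visit == "baseline", ]
  fup <- a[a$visit == "followup", ]
  expect_equal(nrow(base), 30)
  expect_equal(nrow(fup), 30)
  expect_true(all(base$time_since_baseline == 0))
  expect_true(all(fup$time_since_baseline > 0))

  # twins share family, age and sex; singletons have unique families
  fam_sizes <- table(base$family_id)
  expect_equal(sum(fam_sizes == 2), 12)
  expect_equal(sum(fam_sizes == 1), 6)
  for (f in names(fam_sizes[fam_sizes == 2])) {
    twins <- base[base$family_id == f, ]
    expect_equal(twins$age[1], twins$age[2])
    expect_equal(twins$sex[1], twins$sex[2])
  }
})

test_that("invalid cohort configurations fail naming the field", {
  expect_error(cohortConfig(n_individuals = 10, n_twin_pairs = 6),
    "n_twin_pairs"
  )
  expect_error(cohortConfig(age_sd = -1), "age_sd")
  expect_error(cohortConfig(sex_fraction_female = 1.5),
    "sex_fraction_female"
  )
})

test_that("zero-variance configuration collapses to identical twins", {
  tab <- generateCohort(cohortConfig(
    n_individuals = 2, n_twin_pairs = 1, age_sd = 0, followup_sd = 0,
    abeta_baseline_sd = 0, abeta_annual_drift_sd = 0, seed = 3
  ))
  base <- tab[tab$visit == "baseline", ]
  expect_equal(base$age[1], base$age[2])
  expect_equal(base$abeta_whole_brain[1], base$abeta_whole_brain[2])
  expect_equal(base$family_id[1], base$family_id[2])
})

test_that("configured moments are recovered at large n", {
  cfg <- cohortConfig(n_individuals = 1000, n_twin_pairs = 0, seed = 7)
  tab <- generateCohort(cfg)
  base <- tab[tab$visit == "baseline", ]
  fup <- tab[tab$visit == "followup", ]
  # within 3 standard errors of the configured means
  expect_lt(
    abs(mean(base$abeta_whole_brain) - 0.16), 3 * 0.11 / sqrt(1000)
  )
  expect_lt(abs(mean(base$age) - 67.9), 3 * 5.7 / sqrt(1000))
  expect_lt(
    abs(mean(fup$time_since_baseline) - 4.1), 3 * 0.3 / sqrt(1000)
  )
  expect_lt(abs(sd(base$abeta_whole_brain) - 0.11), 0.02)
  # amyloid floor respected
  expect_true(all(tab$abeta_whole_brain >= -0.1))
})

test_that("recordings have the declared geometry and are reproducible", {
  cfg <- signalConfig(
    n_regions = 5, n_epochs = 3, epoch_len = 256, seed = 11
  )
  rec <- generateRecording("P009", cfg)
  expect_s4_class(rec, "SourceRecording")
  expect_equal(dim(rec@data), c(3, 5, 256))
  expect_identical(rec@data, generateRecording("P009", cfg)@data)
  # same seed, different participant -> different stream
  expect_false(identical(rec@data, generateRecording("P010", cfg)@data))
})

test_that("uncoupled regions are close to uncorrelated", {
  rec <- tiny_recording(
    n_regions = 4, n_epochs = 1, epoch_len = 4096, seed = 5
  )
  m <- epochData(rec, 1)
  cors <- cor(t(m))
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.1)
})

test_that("a lagged shared theta component makes its pair the PLI maximum", {
  coupling <- data.frame(
    region_i = 1, region_j = 2, mode = "shared_lagged",
    strength = 0.9, lag = 10, band = "theta"
  )
  rec <- tiny_recording(
    n_regions = 5, n_epochs = 2, epoch_len = 2048, seed = 21,
    coupling = coupling
  )
  cm <- connectivityMatrix(rec, "pli", "theta")
  v <- connValues(cm)
  expect_equal(
    which(v == max(v, na.rm = TRUE), arr.ind = TRUE)[1, ],
    c(row = 2L, col = 1L)
  )
})

test_that("signal configuration rejects bad lags, bands and rates", {
  expect_error(
    signalConfig(epoch_len = 32), "epoch_len"
  )
  expect_error(signalConfig(sampling_rate = 80), "sampling_rate")
  expect_error(
    signalConfig(band_amplitudes = c(sigma = 1)), "unknown band"
  )
  expect_error(
    signalConfig(coupling = data.frame(
      region_i = 1, region_j = 2, mode = "shared_lagged",
      strength = 0.5, lag = 5000, band = "theta"
    )),
    "lag"
  )
})

test_that("attachEffects imposes the configured amyloid-theta coupling", {
  cohort <- generateCohort(cohortConfig(
    n_individuals = 40, n_twin_pairs = 0, seed = 2
  ))
  base_cfg <- signalConfig(n_regions = 2, n_epochs = 1, epoch_len = 256)

  fx0 <- attachEffects(cohort, base_cfg,
    effect_cross = 0, effect_interaction = 0
  )
  amps <- vapply(
    fx0$configs, function(cf) cf$band_amplitudes[["theta"]], numeric(1)
  )
  expect_equal(length(unique(round(amps, 12))), 1L)

  fx <- attachEffects(cohort, base_cfg,
    effect_cross = 0.2, effect_interaction = 0.1
  )
  tr <- fx$truth
  tb <- tr[tr$visit == "baseline", ]
  expect_gt(cor(tb$z_abeta, tb$theta_amplitude), 0)
  # follow-up minus baseline amplitude grows with amyloid x time
  tf <- tr[tr$visit == "followup", ]
  delta <- tf$theta_amplitude[match(tb$participant_id, tf$participant_id)] -
    tb$theta_amplitude
  slope <- coef(lm(delta ~ I(tb$z_abeta * tf$time)))[2]
  expect_gt(slope, 0)
})
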