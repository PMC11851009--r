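test_that("symbolization matches the stable argsort oracle", {
  # monotone series: every window is the identity pattern
  s <- symbolize(1:20, ordinalParams(4, 1))
  expect_length(s, 17)
  pats <- symbolPatterns(4)
  expect_true(all(apply(pats[s, ], 1, identical, y = 0:3)))

  expect_equal(pats[symbolize(c(1, 3, 2, 5))[1], ], oracle_pattern(c(1, 3, 2, 5)))

  # random windows, with and without ties, against the oracle
  set.seed(14)
  for (rep in 1:20) {
    x <- if (rep %% 2) rnorm(12) else sample(0:2, 12, replace = TRUE)
    s <- unclass(symbolize(x, ordinalParams(4, 1)))
    for (t in seq_along(s)) {
      expect_equal(pats[s[t], ], oracle_pattern(x[t:(t + 3)]))
    }
  }

  # ordinal invariance under shifts and positive scaling
  x <- rnorm(50)
  expect_identical(symbolize(x), symbolize(x + 10))
  expect_identical(symbolize(x), symbolize(3 * x))
  expect_error(symbolize(c(1, 2, 3), ordinalParams(4, 1)), "too short")
})

test_that("tau-delayed embeddings follow the same oracle", {
  set.seed(15)
  x <- rnorm(30)
  pr <- ordinalParams(3, 4)
  s <- unclass(symbolize(x, pr))
  pats <- symbolPatterns(3)
  expect_length(s, 30 - 2 * 4)
  for (t in seq_along(s)) {
    expect_equal(pats[s[t], ], oracle_pattern(x[c(t, t + 4, t + 8)]))
  }
})

test_that("the opposite symbol is the pattern of the negated window", {
  expect_equal(oppositeSymbol(c(0, 1, 2, 3)), c(3, 2, 1, 0))
  expect_equal(oppositeSymbol(c(0, 2, 1, 3)), c(3, 1, 2, 0))
  # against the argsort-of-negated-window oracle on tie-free windows
  set.seed(16)
  for (i in 1:10) {
    w <- rnorm(4)
    expect_equal(oppositeSymbol(oracle_pattern(w)), oracle_pattern(-w))
  }
  # involution over all 24 patterns
  pats <- symbolPatterns(4)
  for (i in seq_len(nrow(pats))) {
    expect_equal(oppositeSymbol(oppositeSymbol(pats[i, ])), pats[i, ])
  }
  expect_error(oppositeSymbol(c(0, 0, 1, 2)), "not a valid")
})

test_that("joint symbol histograms equal direct window enumeration", {
  set.seed(17)
  for (len in c(5, 8, 12)) {
    for (rep in 1:3) {
      x <- sample(0:2, len, replace = TRUE)
      y <- sample(0:2, len, replace = TRUE)
      jm <- jointSymbolMatrix(x, y)
      oc <- oracle_joint_counts(x, y)
      expect_equal(jm, oc / sum(oc))
    }
  }
})

test_that("inverted joint permutation entropy matches its brute-force oracle", {
  set.seed(18)
  x <- rnorm(400)
  y <- 0.5 * x + rnorm(400)
  for (correct in c(TRUE, FALSE)) {
    expect_equal(
      jpeInv(x, y, correct = correct),
      oracle_jpe_inv(x, y, correct = correct),
      tolerance = 1e-12
    )
  }
})

test_that("entropy connectivity has the expected analytic limits", {
  set.seed(19)
  x <- rnorm(4096)
  # identical series, uncorrected: mass on the diagonal, high coupling
  high <- jpeInv(x, x, correct = FALSE)
  indep <- jpeInv(x, rnorm(4096), correct = FALSE)
  expect_gt(high, indep + 0.2)
  # positive scaling of x removes all admissible mass under correction
  expect_warning(v <- jpeInv(x, 2 * x), "fully-leakage-degenerate")
  expect_equal(v, 0)
  # independent pair: normalized joint entropy near its maximum
  expect_lt(jpeInv(x, rnorm(4096)), 0.05)
  expect_error(jpeInv(rep(1, 100), x[1:100]), "no ordinal variability")
})

test_that("entropy connectivity is symmetric and affine-invariant", {
  set.seed(20)
  x <- rnorm(600)
  y <- rnorm(600)
  expect_equal(jpeInv(x, y), jpeInv(y, x), tolerance = 1e-12)
  expect_equal(jpeInv(2 + 3 * x, y), jpeInv(x, y), tolerance = 1e-12)
})

test_that("band-pass filtering isolates the requested band", {
  fs <- 312
  t <- (0:4095) / fs
  tone6 <- sin(2 * pi * 6 * t)
  y6 <- bandpassFilter(tone6, "theta", fs)
  mid <- 1000:3000
  expect_equal(max(abs(y6[mid])), 1, tolerance = 0.05)
  tone20 <- sin(2 * pi * 20 * t)
  y20 <- bandpassFilter(tone20, "theta", fs)
  expect_lt(
    20 * log10(max(abs(y20[mid])) / 1), -20
  )
  # broadband noise: >= 95% of output power inside 4-8 Hz
  set.seed(22)
  yn <- bandpassFilter(rnorm(8192), "theta", fs)
  p <- periodogram(yn, fs)
  inband <- p$frequency >= 4 & p$frequency < 8
  expect_gt(sum(p$power[inband]) / sum(p$power), 0.95)
  expect_error(bandpassFilter(tone6, c(100, 200), fs), "Nyquist")
})

test_that("the amplitude envelope recovers tone amplitude and modulators", {
  fs <- 312
  t <- (0:4095) / fs
  env <- amplitudeEnvelope(sin(2 * pi * 6 * t))
  mid <- 500:3500
  expect_lt(max(abs(env[mid] - 1)), 0.05)
  # amplitude-modulated tone: envelope tracks the modulator mid-epoch
  mod <- 1 + 0.5 * sin(2 * pi * 0.5 * t)
  env2 <- amplitudeEnvelope(mod * sin(2 * pi * 10 * t))
  expect_lt(sqrt(mean((env2[mid] - mod[mid])^2)) / mean(mod[mid]), 0.05)
  expect_equal(amplitudeEnvelope(rep(0, 256)), rep(0, 256))
})

test_that("orthogonalization removes the linear contribution of the reference", {
  set.seed(23)
  x <- rnorm(2048)
  expect_equal(orthogonalize(x, x), rep(0, 2048), tolerance = 1e-12)
  z <- rnorm(2048)
  y <- 0.7 * x + z
  res <- orthogonalize(y, x)
  expect_lt(abs(cor(res, x)), 1e-6)
  expect_gt(cor(res, z), 0.9)
  # already-orthogonal input is returned (up to its tiny sample covariance)
  z_perp <- orthogonalize(z, x)
  expect_equal(orthogonalize(z_perp, x), z_perp, tolerance = 1e-10)
  expect_warning(r <- orthogonalize(y, rep(0, 2048)), "constant")
  expect_equal(r, y)
})

test_that("envelope correlation is centred at 0.5 for independent signals", {
  set.seed(24)
  vals <- replicate(10, {
    aecC(rnorm(4096), rnorm(4096), c(8, 13), 312)
  })
  # null distribution centred on 0.5; individual draws scatter with the
  # limited time-bandwidth product of a 13.1 s narrowband epoch
  expect_lt(abs(mean(vals) - 0.5), 0.05)
  expect_true(all(abs(vals - 0.5) < 0.15))
})

test_that("zero-lag mixing fools uncorrected AEC but not AEC-c or PLI", {
  set.seed(25)
  fs <- 312
  raw <- replicate(8, {
    x <- rnorm(4096)
    y <- x + rnorm(4096)
    c(
      aec = aec(x, y, "alpha1", fs),
      aec_c = aecC(x, y, "alpha1", fs),
      pli = pli(x, y, "theta", fs)
    )
  })
  null_pli <- replicate(40, pli(rnorm(4096), rnorm(4096), "theta", fs))
  expect_gt(mean(raw["aec", ]), 0.6)
  expect_lt(mean(abs(raw["aec_c", ] - 0.5)), 0.1)
  # the correction removes most of the leakage-induced elevation
  expect_gt(
    mean(raw["aec", ]) - 0.5, 4 * abs(mean(raw["aec_c", ]) - 0.5)
  )
  expect_lt(median(raw["pli", ]), quantile(null_pli, 0.95))
})

test_that("the phase lag index attains its analytic limits", {
  fs <- 312
  t <- (0:4095) / fs
  x <- sin(2 * pi * 6 * t)
  y <- sin(2 * pi * 6 * t - pi / 2)
  expect_equal(pli(x, y, "theta", fs), 1)
  expect_equal(
    pliFromPhaseDifferences(c(pi / 2, pi / 2, -pi / 2, pi / 2)), 0.5
  )
  expect_equal(pli(y, x, "theta", fs), 1) # symmetry via absolute value
  expect_error(pli(rep(0, 512), rep(0, 512), "theta", fs), "degenerate")
})

test_that("independent-pair nulls tighten with epoch length", {
  set.seed(26)
  fs <- 312
  short_pli <- replicate(8, pli(rnorm(512), rnorm(512), "theta", fs))
  long_pli <- replicate(8, pli(rnorm(4096), rnorm(4096), "theta", fs))
  expect_lt(median(long_pli), median(short_pli))
  short_aec <- replicate(8, abs(aecC(rnorm(512), rnorm(512), "alpha1", fs) - 0.5))
  long_aec <- replicate(8, abs(aecC(rnorm(4096), rnorm(4096), "alpha1", fs) - 0.5))
  expect_lt(median(long_aec), median(short_aec))
})

test_that("connectivity matrices are symmetric, bounded and label-consistent", {
  rec <- tiny_recording(n_regions = 4, n_epochs = 2, epoch_len = 512, seed = 6)
  for (meas in c("jpe_inv", "aec_c", "pli")) {
    cm <- connectivityMatrix(rec, meas, "theta")
    v <- connValues(cm)
    expect_s4_class(cm, "ConnectivityMatrix")
    expect_equal(v, t(v))
    off <- v[upper.tri(v)]
    expect_true(all(off >= 0 & off <= 1))
    expect_true(all(is.na(diag(v))))
    expect_identical(rownames(v), regionLabels(rec))
  }
})

test_that("identical regions give maximal uncorrected envelope coupling", {
  base <- tiny_recording(n_regions = 1, n_epochs = 1, epoch_len = 1024, seed = 8)
  arr <- array(0, dim = c(1, 3, 1024))
  for (r in 1:3) arr[1, r, ] <- base@data[1, 1, ]
  rec <- sourceRecording(arr, region_labels = c("A", "B", "C"),
    sampling_rate = 312)
  cm <- connectivityMatrix(rec, "aec", "alpha1")
  off <- connValues(cm)[upper.tri(connValues(cm))]
  expect_equal(off, rep(1, 3), tolerance = 1e-9)
})

test_that("relabelling regions permutes the connectivity matrix consistently", {
  rec <- tiny_recording(n_regions = 4, n_epochs = 1, epoch_len = 512, seed = 9)
  cm <- connValues(connectivityMatrix(rec, "pli", "theta"))
  perm <- c(3, 1, 4, 2)
  rec2 <- sourceRecording(
    rec@data[, perm, , drop = FALSE],
    region_labels = regionLabels(rec)[perm],
    sampling_rate = samplingRate(rec)
  )
  cm2 <- connValues(connectivityMatrix(rec2, "pli", "theta"))
  expect_equal(cm2, cm[perm, perm], tolerance = 1e-12)
})

test_that("per-epoch matrices average to the reported matrix", {
  rec <- tiny_recording(n_regions = 3, n_epochs = 3, epoch_len = 512, seed = 10)
  cm <- connectivityMatrix(rec, "pli", "theta", keep_epochs = TRUE)
  expect_length(cm@per_epoch, 3)
  expect_equal(averageEpochs(cm@per_epoch), connValues(cm))
})
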