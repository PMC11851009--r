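make_power <- function(vals, regions, bands = "theta") {
  matrix(vals,
    nrow = length(regions), ncol = length(bands),
    dimnames = list(regions, bands)
  )
}

sym_matrix <- function(n, seed = 1, labels = LETTERS[seq_len(n)]) {
  set.seed(seed)
  v <- matrix(runif(n * n), n, n, dimnames = list(labels, labels))
  v <- (v + t(v)) / 2
  diag(v) <- NA
  v
}

test_that("ROI power is the unweighted mean of member regions", {
  pw <- make_power(c(0.1, 0.2, 0.3, 0.4), c("A", "B", "C", "D"))
  expect_equal(
    roiPower(pw, roiDefinition("r", c("A", "B", "C", "D")))[["theta"]], 0.25
  )
  expect_equal(roiPower(pw, roiDefinition("r", "C"))[["theta"]], 0.3)
  set.seed(2)
  pw2 <- make_power(runif(12), letters[1:4], c("theta", "beta", "gamma"))
  roi <- roiDefinition("r", c("a", "c"))
  expect_equal(
    roiPower(pw2, roi),
    colMeans(pw2[c("a", "c"), ])
  )
  expect_error(
    roiPower(pw, roiDefinition("r", c("A", "Z"))), "absent.*Z"
  )
})

test_that("ROI-to-rest connectivity averages exactly the cross pairs", {
  v <- sym_matrix(3)
  v["A", "B"] <- v["B", "A"] <- 0.2
  v["A", "C"] <- v["C", "A"] <- 0.4
  expect_equal(roiToRestConnectivity(v, roiDefinition("r", "A")), 0.3)

  const <- sym_matrix(5)
  const[!is.na(const)] <- 0.7
  expect_equal(roiToRestConnectivity(const, roiDefinition("r", c("A", "B"))), 0.7)

  # enumeration oracle over the 24 cross pairs of a 4-region ROI
  v10 <- sym_matrix(10, seed = 3)
  roi <- roiDefinition("r", LETTERS[1:4])
  acc <- 0
  npair <- 0
  for (i in LETTERS[1:4]) {
    for (j in LETTERS[5:10]) {
      acc <- acc + v10[i, j]
      npair <- npair + 1
    }
  }
  expect_equal(npair, 24)
  expect_equal(roiToRestConnectivity(v10, roi), acc / npair)
  expect_error(
    roiToRestConnectivity(v, roiDefinition("r", c("A", "B", "C"))),
    "covers all regions"
  )
})

test_that("whole-brain connectivity averages all unordered pairs", {
  v2 <- sym_matrix(2)
  expect_equal(wholeBrainConnectivity(v2), v2[1, 2])
  const <- sym_matrix(4)
  const[!is.na(const)] <- 0.42
  expect_equal(wholeBrainConnectivity(const), 0.42)
  v90 <- sym_matrix(90, seed = 4, labels = sprintf("R%02d", 1:90))
  acc <- 0
  for (i in 1:89) for (j in (i + 1):90) acc <- acc + v90[i, j]
  expect_equal(wholeBrainConnectivity(v90), acc / 4005)
})

test_that("aggregations are invariant to region ordering", {
  v <- sym_matrix(6, seed = 5)
  perm <- sample(6)
  vp <- v[perm, perm]
  roi <- roiDefinition("r", c("B", "E"))
  expect_equal(
    roiToRestConnectivity(vp, roi), roiToRestConnectivity(v, roi)
  )
  expect_equal(wholeBrainConnectivity(vp), wholeBrainConnectivity(v))
  # bounded by the matrix extremes
  r <- roiToRestConnectivity(v, roi)
  expect_gte(r, min(v, na.rm = TRUE))
  expect_lte(r, max(v, na.rm = TRUE))
})

test_that("the measure table is complete over levels, measures and bands", {
  rec_b <- tiny_recording(n_regions = 4, n_epochs = 1, epoch_len = 512, seed = 1)
  rec_f <- generateRecording("P001",
    signalConfig(n_regions = 4, n_epochs = 1, epoch_len = 512, seed = 2),
    visit = "followup"
  )
  roi <- roiDefinition("early_ad", c("region_01", "region_02"))
  mt <- buildMeasureTable(list(rec_b, rec_f), roi = roi)
  # 6 power bands x 2 levels + 3 connectivity x 2 levels, per visit
  expect_equal(nrow(mt), 2 * (6 * 2 + 3 * 2))
  expect_true(all(is.finite(mt$value)))
  key <- unique(mt[, c("analysis_level", "measure", "band")])
  expect_equal(nrow(key), 18)
  expect_setequal(
    unique(mt$analysis_level),
    c("early_roi", "whole_brain", "early_roi_to_rest")
  )
})
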