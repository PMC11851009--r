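#' Canonical frequency band set
#'
#' The six canonical resting-state bands: delta (0.5-4 Hz), theta
#' (4-8 Hz), alpha1 (8-10 Hz), alpha2 (10-13 Hz), beta (13-30 Hz) and
#' gamma (30-48 Hz). Bands are treated as half-open intervals
#' `[low, high)`, so shared edges belong to the upper band and the six
#' bands partition the 0.5-48 Hz analysis range.
#'
#' @param ... optional replacement bands as `name = c(low, high)` pairs;
#'   when omitted the defaults above are returned.
#' @return Named list of length-2 numeric vectors, ordered by lower edge.
#' @examples
#' bandSet()$theta
#' @export
bandSet <- function(...) {
  bands <- list(...)
  if (!length(bands)) {
    bands <- list(
      delta = c(0.5, 4), theta = c(4, 8), alpha1 = c(8, 10),
      alpha2 = c(10, 13), beta = c(13, 30), gamma = c(30, 48)
    )
  }
  for (nm in names(bands)) {
    b <- bands[[nm]]
    if (length(b) != 2L || b[1L] >= b[2L]) {
      stop("band '", nm, "' must be c(low, high) with low < high")
    }
  }
  bands[order(vapply(bands, `[`, numeric(1), 1L))]
}

#' Periodogram of one epoch
#'
#' Plain FFT periodogram of a demeaned epoch, one-sided, scaled so that
#' the power summed over all positive-frequency bins equals the epoch's
#' (population) variance -- Parseval-consistent. An optional Hann taper
#' is available (power renormalized for the taper); the default is no
#' taper, i.e. a plain FFT of the demeaned signal.
#'
#' @param x numeric vector, one epoch of one region (>= 2 finite samples).
#' @param sampling_rate sampling rate in Hz.
#' @param demean subtract the epoch mean first (default `TRUE`).
#' @param taper `"none"` (default) or `"hann"`.
#' @return `data.frame` with columns `frequency` (Hz, from 0 to Nyquist)
#'   and `power`.
#' @examples
#' p <- periodogram(sin(2 * pi * 6 * (0:4095) / 312), 312)
#' p$frequency[which.max(p$power)] # close to 6 Hz
#' @export
periodogram <- function(x, sampling_rate, demean = TRUE,
                        taper = c("none", "hann")) {
  taper <- match.arg(taper)
  if (length(x) < 2L) stop("need at least 2 samples")
  if (anyNA(x) || !all(is.finite(x))) stop("non-finite input samples")
  n <- length(x)
  if (demean) x <- x - mean(x)
  if (taper == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
    x <- x * w / sqrt(mean(w^2))
  }
  X <- stats::fft(x)
  p2 <- Mod(X)^2 / n^2 # two-sided
  nhalf <- floor(n / 2)
  idx <- seq_len(nhalf + 1L) # bins 0 .. Nyquist
  p1 <- p2[idx]
  # fold the negative frequencies onto their positive counterparts
  interior <- 2:(if (n %% 2 == 0) nhalf else nhalf + 1L)
  p1[interior] <- 2 * p1[interior]
  data.frame(
    frequency = (idx - 1L) * sampling_rate / n,
    power = p1
  )
}

#' Relative band power from a spectrum
#'
#' Fractions of spectral power per band, with the total 0.5-48 Hz power
#' (the union of the six canonical bands) as denominator, so the
#' fractions sum to one. Band membership uses half-open intervals
#' `[low, high)`.
#'
#' @param spectrum a `data.frame` from [periodogram()].
#' @param bands a [bandSet()].
#' @return Named numeric vector of fractions, one per band, summing to 1.
#' @export
relativeBandPower <- function(spectrum, bands = bandSet()) {
  lo <- min(vapply(bands, `[`, numeric(1), 1L))
  hi <- max(vapply(bands, `[`, numeric(1), 2L))
  if (max(spectrum$frequency) < hi) {
    stop(
      "spectrum does not cover the analysis range (needs frequencies up ",
      "to ", hi, " Hz)"
    )
  }
  f <- spectrum$frequency
  p <- spectrum$power
  total <- sum(p[f >= lo & f < hi])
  if (total <= 0) stop("degenerate spectrum: zero total power in band range")
  out <- vapply(bands, function(b) {
    sum(p[f >= b[1L] & f < b[2L]]) / total
  }, numeric(1))
  out
}

#' Average per-epoch results
#'
#' Arithmetic mean over epochs, region-wise: the epoch-then-average
#' contract used for every spectral and connectivity measure.
#'
#' @param results list of conformable numeric matrices (or vectors) with
#'   identical dimnames, one per epoch.
#' @return The element-wise mean, same shape as each input.
#' @export
averageEpochs <- function(results) {
  if (!length(results)) stop("need at least one epoch")
  ref <- results[[1L]]
  for (r in results[-1L]) {
    if (!identical(dimnames(r), dimnames(ref)) ||
        !identical(dim(r), dim(ref)) || length(r) != length(ref)) {
      stop("epoch results have mismatched regions or shape")
    }
  }
  Reduce(`+`, results) / length(results)
}

#' Epoch-averaged relative band power of a recording
#'
#' Computes the per-epoch, per-region relative band power of a
#' [SourceRecording-class] and averages over epochs.
#'
#' @param recording a [SourceRecording-class].
#' @param bands a [bandSet()].
#' @param taper passed to [periodogram()].
#' @return Numeric matrix, regions x bands, rows summing to 1; attribute
#'   `"epoch_averaged"` is `TRUE`.
#' @export
relativePower <- function(recording, bands = bandSet(),
                          taper = c("none", "hann")) {
  taper <- match.arg(taper)
  fs <- samplingRate(recording)
  per_epoch <- lapply(seq_len(nEpochs(recording)), function(e) {
    m <- epochData(recording, e)
    out <- t(apply(m, 1L, function(x) {
      relativeBandPower(periodogram(x, fs, taper = taper), bands)
    }))
    colnames(out) <- names(bands)
    out
  })
  avg <- averageEpochs(per_epoch)
  attr(avg, "epoch_averaged") <- TRUE
  avg
}

#' Long-format power table for a set of recordings
#'
#' @param recordings list of [SourceRecording-class] objects.
#' @param bands a [bandSet()].
#' @return `data.frame` with columns `participant_id`, `visit`, `region`,
#'   `band`, `fraction`.
#' @export
powerTable <- function(recordings, bands = bandSet()) {
  do.call(rbind, lapply(recordings, function(rec) {
    rp <- relativePower(rec, bands)
    data.frame(
      participant_id = participantId(rec),
      visit = visitLabel(rec),
      region = rep(rownames(rp), times = ncol(rp)),
      band = rep(colnames(rp), each = nrow(rp)),
      fraction = as.vector(rp),
      stringsAsFactors = FALSE
    )
  }))
}
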