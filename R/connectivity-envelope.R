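#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth filtering, used both to
#' isolate a band before a connectivity statistic and to synthesize
#' band-limited components in the signal generator.
#'
#' @param x numeric series.
#' @param band a band name from `bands` (e.g. `"theta"`) or a numeric
#'   `c(low, high)` in Hz.
#' @param sampling_rate sampling rate in Hz; the upper band edge must be
#'   below Nyquist.
#' @param order Butterworth design order (the effective attenuation is
#'   doubled by the forward-backward pass).
#' @param bands band lookup used when `band` is a name.
#' @return Filtered series, same length as `x`.
#' @examples
#' x <- sin(2 * pi * 6 * (0:4095) / 312)
#' y <- bandpassFilter(x, "theta", 312) # 6 Hz tone passes
#' @export
bandpassFilter <- function(x, band, sampling_rate, order = 4L,
                           bands = bandSet()) {
  if (is.character(band)) {
    if (!band %in% names(bands)) stop("unknown band name: ", band)
    band <- bands[[band]]
  }
  if (band[2L] >= sampling_rate / 2) {
    stop(
      "band upper edge (", band[2L], " Hz) is at or above Nyquist (",
      sampling_rate / 2, " Hz)"
    )
  }
  bf <- signal::butter(order, band / (sampling_rate / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# Analytic signal via the frequency-domain Hilbert construction.
.analytic <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

# Samples to drop from each end before envelope/phase statistics:
# one cycle of the band's lower edge, capped so at least 64 samples
# (or half the series for very short input) remain.
.edgeTrim <- function(len, band, sampling_rate) {
  ntrim <- ceiling(sampling_rate / band[1L])
  max_trim <- floor((len - max(64L, floor(len / 2))) / 2)
  max(0L, min(ntrim, max_trim))
}

.bandLimits <- function(band, bands = bandSet()) {
  if (is.character(band)) bands[[band]] else band
}

#' Amplitude envelope of a (band-filtered) series
#'
#' Magnitude of the analytic signal. When `band` is supplied the series
#' is zero-phase band-filtered first.
#'
#' @param x numeric series.
#' @param band optional band name or `c(low, high)` Hz; `NULL` means the
#'   series is used as given.
#' @param sampling_rate sampling rate in Hz (required when filtering).
#' @return Non-negative numeric series, same length as `x`.
#' @export
amplitudeEnvelope <- function(x, band = NULL, sampling_rate = NULL) {
  if (!is.null(band)) {
    if (is.null(sampling_rate)) stop("sampling_rate required to filter")
    x <- bandpassFilter(x, band, sampling_rate)
  }
  Mod(.analytic(x))
}

#' Least-squares orthogonalization of one series on another
#'
#' Residualizes `y` on `x` in the time domain so the residual has zero
#' sample covariance with `x` -- the pairwise leakage correction applied
#' before envelope correlation.
#'
#' @param y series to orthogonalize.
#' @param x reference series.
#' @return Residual series. If `x` has zero variance the input `y` is
#'   returned unchanged with a warning.
#' @export
orthogonalize <- function(y, x) {
  if (length(x) != length(y)) stop("series must have equal length")
  vx <- stats::var(x)
  if (vx == 0) {
    warning("reference series is constant; returning y unchanged")
    return(y)
  }
  y - stats::cov(x, y) / vx * x
}

.mapUnit <- function(r) (r + 1) / 2

# Shared worker: envelope correlation of two band-filtered series,
# optionally with pairwise orthogonalization in both directions.
.aecFiltered <- function(xf, yf, band, sampling_rate, corrected) {
  trim <- .edgeTrim(length(xf), band, sampling_rate)
  keep <- (trim + 1L):(length(xf) - trim)
  envcor <- function(a, b) {
    ea <- Mod(.analytic(a))[keep]
    eb <- Mod(.analytic(b))[keep]
    if (stats::sd(ea) == 0 || stats::sd(eb) == 0) {
      stop("zero-variance amplitude envelope")
    }
    stats::cor(ea, eb)
  }
  if (!corrected) {
    return(.mapUnit(envcor(xf, yf)))
  }
  r_yx <- envcor(orthogonalize(yf, xf), xf)
  r_xy <- envcor(orthogonalize(xf, yf), yf)
  mean(c(.mapUnit(r_yx), .mapUnit(r_xy)))
}

#' Amplitude envelope correlation (uncorrected)
#'
#' Linear correlation of the band-limited amplitude envelopes of two
#' series, mapped to `[0, 1]` via `(r + 1) / 2`; 0.5 indicates no
#' coupling. Sensitive to zero-lag leakage -- see [aecC()] for the
#' corrected variant.
#'
#' @param x,y equal-length numeric series.
#' @param band band name or `c(low, high)` Hz.
#' @param sampling_rate sampling rate in Hz.
#' @return Scalar in `[0, 1]`.
#' @export
aec <- function(x, y, band, sampling_rate) {
  if (length(x) != length(y)) stop("series must have equal length")
  bl <- .bandLimits(band)
  xf <- bandpassFilter(x, band, sampling_rate)
  yf <- bandpassFilter(y, band, sampling_rate)
  .aecFiltered(xf, yf, bl, sampling_rate, corrected = FALSE)
}

#' Leakage-corrected amplitude envelope correlation (AEC-c)
#'
#' Pairwise orthogonalization in both directions (`x` on `y` and `y` on
#' `x`) on the band-filtered signals, followed by the envelope
#' correlation of each orthogonalized series with its reference; both
#' direction values are mapped to `[0, 1]` via `(r + 1) / 2` and
#' averaged. Filter/Hilbert edge transients (one cycle of the lower band
#' edge) are trimmed before the correlation. 0.5 indicates no coupling;
#' instantaneous (zero-lag) mixing is removed by the orthogonalization.
#'
#' @inheritParams aec
#' @return Scalar in `[0, 1]`.
#' @export
aecC <- function(x, y, band, sampling_rate) {
  if (length(x) != length(y)) stop("series must have equal length")
  bl <- .bandLimits(band)
  xf <- bandpassFilter(x, band, sampling_rate)
  yf <- bandpassFilter(y, band, sampling_rate)
  .aecFiltered(xf, yf, bl, sampling_rate, corrected = TRUE)
}
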