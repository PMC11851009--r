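#' Phase lag index from a phase-difference series
#'
#' The absolute mean sign of the instantaneous phase differences, with
#' differences at 0 mod pi contributing zero -- phase differences that
#' centre around 0 mod pi are discarded by construction, which makes the
#' statistic insensitive to zero-lag (volume-conducted) coupling.
#'
#' @param dphi numeric vector of phase differences (radians).
#' @return Scalar in `[0, 1]`.
#' @examples
#' pliFromPhaseDifferences(c(pi / 2, pi / 2, -pi / 2, pi / 2)) # 0.5
#' @export
pliFromPhaseDifferences <- function(dphi) {
  if (!length(dphi)) stop("empty phase-difference series")
  abs(mean(sign(sin(dphi))))
}

#' Phase lag index of two series
#'
#' Band-filters both series (zero-phase), extracts instantaneous phases
#' from the analytic signal, trims filter/Hilbert edge transients (one
#' cycle of the lower band edge) and evaluates the asymmetry of the
#' phase-difference distribution: `|mean(sign(sin(phi_x - phi_y)))|`.
#' 0 indicates no (or purely zero-lag) coupling, 1 perfect phase locking
#' at a consistent non-zero lag.
#'
#' @param x,y equal-length numeric series.
#' @param band band name or `c(low, high)` Hz.
#' @param sampling_rate sampling rate in Hz.
#' @return Scalar in `[0, 1]`.
#' @export
pli <- function(x, y, band, sampling_rate) {
  if (length(x) != length(y)) stop("series must have equal length")
  bl <- .bandLimits(band)
  xf <- bandpassFilter(x, band, sampling_rate)
  yf <- bandpassFilter(y, band, sampling_rate)
  ax <- .analytic(xf)
  ay <- .analytic(yf)
  trim <- .edgeTrim(length(xf), bl, sampling_rate)
  keep <- (trim + 1L):(length(xf) - trim)
  phx <- Arg(ax[keep])
  phy <- Arg(ay[keep])
  if (stats::var(phx) == 0 || stats::var(phy) == 0) {
    stop("degenerate (constant) analytic phase")
  }
  pliFromPhaseDifferences(phx - phy)
}
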