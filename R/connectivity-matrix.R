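#' Pairwise connectivity matrix of a recording
#'
#' Computes one connectivity measure for every unordered region pair,
#' separately per epoch, and averages the per-epoch matrices -- the
#' epoch-then-average contract. Band filtering, symbolization, analytic
#' phases and envelopes are computed once per region per epoch; the
#' orthogonalization step of AEC-c is inherently pairwise.
#'
#' @param recording a [SourceRecording-class] with at least 2 regions.
#' @param measure `"jpe_inv"`, `"aec_c"`, `"aec"` or `"pli"`.
#' @param band band name (e.g. `"theta"`), numeric `c(low, high)` in Hz,
#'   or `NULL` for broadband (JPE only; envelope/phase measures require a
#'   band).
#' @param params [ordinalParams()] for the JPE symbolization.
#' @param correct apply the JPE volume-conduction correction.
#' @param keep_epochs retain the per-epoch matrices in the result.
#' @param bands band lookup for named bands.
#' @return A [ConnectivityMatrix-class] object.
#' @examples
#' rec <- generateRecording("P1", signalConfig(
#'   n_regions = 3, n_epochs = 2,
#'   epoch_len = 512
#' ))
#' connectivityMatrix(rec, "pli", "theta")
#' @export
connectivityMatrix <- function(recording,
                               measure = c("jpe_inv", "aec_c", "aec", "pli"),
                               band = "theta",
                               params = ordinalParams(),
                               correct = TRUE,
                               keep_epochs = FALSE,
                               bands = bandSet()) {
  measure <- match.arg(measure)
  nr <- nRegions(recording)
  if (nr < 2L) stop("need at least 2 regions")
  if (is.null(band) && measure != "jpe_inv") {
    stop("measure '", measure, "' requires a frequency band")
  }
  labs <- regionLabels(recording)
  fs <- samplingRate(recording)
  bl <- if (is.null(band)) NULL else .bandLimits(band, bands)
  band_label <- if (is.null(band)) {
    "broadband"
  } else if (is.character(band)) {
    band
  } else {
    paste0(band[1L], "-", band[2L], "Hz")
  }

  per_epoch <- lapply(seq_len(nEpochs(recording)), function(e) {
    m <- epochData(recording, e)
    if (!is.null(bl)) {
      m <- t(apply(m, 1L, bandpassFilter, band = bl, sampling_rate = fs,
        bands = bands))
    }
    out <- matrix(NA_real_, nr, nr, dimnames = list(labs, labs))
    pairFail <- function(i, j, err) {
      stop("pair (", labs[i], ", ", labs[j], "): ", conditionMessage(err),
        call. = FALSE)
    }
    if (measure == "jpe_inv") {
      tabs <- .symbolTables(params$n)
      if (correct && sum(tabs$mask) < 2L) {
        stop("volume-conduction correction leaves no admissible cells")
      }
      syms <- lapply(seq_len(nr), function(r) {
        if (diff(range(m[r, ])) == 0) {
          stop("region ", labs[r], ": no ordinal variability")
        }
        unclass(symbolize(m[r, ], params))
      })
      for (i in seq_len(nr - 1L)) {
        for (j in (i + 1L):nr) {
          v <- tryCatch(
            .jpeFromSymbols(syms[[i]], syms[[j]], tabs, correct),
            error = function(err) pairFail(i, j, err)
          )
          out[i, j] <- out[j, i] <- v
        }
      }
    } else if (measure == "pli") {
      trim <- .edgeTrim(ncol(m), bl, fs)
      keep <- (trim + 1L):(ncol(m) - trim)
      ph <- lapply(seq_len(nr), function(r) Arg(.analytic(m[r, ]))[keep])
      for (i in seq_len(nr - 1L)) {
        if (stats::var(ph[[i]]) == 0) {
          stop("region ", labs[i], ": degenerate analytic phase")
        }
        for (j in (i + 1L):nr) {
          out[i, j] <- out[j, i] <-
            pliFromPhaseDifferences(ph[[i]] - ph[[j]])
        }
      }
    } else if (measure == "aec") {
      trim <- .edgeTrim(ncol(m), bl, fs)
      keep <- (trim + 1L):(ncol(m) - trim)
      env <- lapply(seq_len(nr), function(r) Mod(.analytic(m[r, ]))[keep])
      for (i in seq_len(nr - 1L)) {
        for (j in (i + 1L):nr) {
          if (stats::sd(env[[i]]) == 0 || stats::sd(env[[j]]) == 0) {
            pairFail(i, j, simpleError("zero-variance amplitude envelope"))
          }
          out[i, j] <- out[j, i] <- .mapUnit(stats::cor(env[[i]], env[[j]]))
        }
      }
    } else { # aec_c
      for (i in seq_len(nr - 1L)) {
        for (j in (i + 1L):nr) {
          v <- tryCatch(
            .aecFiltered(m[i, ], m[j, ], bl, fs, corrected = TRUE),
            error = function(err) pairFail(i, j, err)
          )
          out[i, j] <- out[j, i] <- v
        }
      }
    }
    out
  })

  avg <- averageEpochs(per_epoch)
  new("ConnectivityMatrix",
    measure = measure, band = band_label, values = avg,
    per_epoch = if (keep_epochs) per_epoch else list()
  )
}
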