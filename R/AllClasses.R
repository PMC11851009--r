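#' SourceRecording: epoch-segmented source-space MEG signals
#'
#' Container for one participant-visit worth of source-reconstructed
#' resting-state signals: an `epochs x regions x samples` array plus the
#' region labels and sampling rate. The canonical acquisition geometry is
#' 10 non-overlapping epochs of 4096 samples at 312 Hz (13.1 s each) over
#' a 90-region source parcellation, but any consistent geometry is
#' accepted.
#'
#' @slot participant_id character scalar participant identifier.
#' @slot visit `"baseline"` or `"followup"`.
#' @slot region_labels character vector naming the source regions.
#' @slot data numeric array with `dim = c(epochs, regions, samples)`;
#'   all values finite.
#' @slot sampling_rate sampling rate in Hz.
#'
#' @seealso [sourceRecording()] for the user-facing constructor,
#'   [generateRecording()] to simulate one, [readRecording()] /
#'   [writeRecording()] for plain-text serialization.
#' @export
setClass("SourceRecording",
  representation(
    participant_id = "character",
    visit = "character",
    region_labels = "character",
    data = "array",
    sampling_rate = "numeric"
  )
)

setValidity("SourceRecording", function(object) {
  msgs <- character(0)
  d <- dim(object@data)
  if (length(d) != 3L) {
    msgs <- c(msgs, "data must be a 3-d array (epochs x regions x samples)")
  } else {
    if (d[2L] != length(object@region_labels)) {
      msgs <- c(msgs, sprintf(
        "region dimension (%d) does not match number of labels (%d)",
        d[2L], length(object@region_labels)
      ))
    }
  }
  if (anyNA(object@data) || !all(is.finite(object@data))) {
    msgs <- c(msgs, "data contains non-finite samples")
  }
  if (length(object@sampling_rate) != 1L || object@sampling_rate <= 0) {
    msgs <- c(msgs, "sampling_rate must be a single positive number")
  }
  if (length(object@visit) != 1L ||
      !object@visit %in% c("baseline", "followup")) {
    msgs <- c(msgs, "visit must be 'baseline' or 'followup'")
  }
  if (anyDuplicated(object@region_labels)) {
    msgs <- c(msgs, "region labels must be unique")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a SourceRecording
#'
#' @param data numeric array `c(epochs, regions, samples)`.
#' @param region_labels character vector of region names; defaults to the
#'   matching prefix of [aalLabels()] when the region count allows it.
#' @param sampling_rate sampling rate in Hz.
#' @param participant_id,visit identifiers stored with the recording.
#' @return A [SourceRecording-class] object.
#' @examples
#' x <- sourceRecording(array(rnorm(2 * 3 * 128), c(2, 3, 128)),
#'   region_labels = c("A", "B", "C"), sampling_rate = 312
#' )
#' nEpochs(x)
#' @export
sourceRecording <- function(data, region_labels = NULL, sampling_rate = 312,
                            participant_id = "P000", visit = "baseline") {
  if (is.null(region_labels)) {
    nr <- dim(data)[2L]
    labs <- aalLabels()
    if (nr == length(labs)) {
      region_labels <- labs
    } else {
      region_labels <- sprintf("region_%02d", seq_len(nr))
    }
  }
  new("SourceRecording",
    participant_id = as.character(participant_id),
    visit = visit,
    region_labels = as.character(region_labels),
    data = data,
    sampling_rate = sampling_rate
  )
}

#' @rdname regionLabels
setMethod("regionLabels", "SourceRecording", function(x) x@region_labels)

#' @rdname samplingRate
setMethod("samplingRate", "SourceRecording", function(x) x@sampling_rate)

#' @rdname nEpochs
setMethod("nEpochs", "SourceRecording", function(x) dim(x@data)[1L])

#' @rdname nRegions
setMethod("nRegions", "SourceRecording", function(x) dim(x@data)[2L])

#' @rdname participantId
setMethod("participantId", "SourceRecording", function(x) x@participant_id)

#' @rdname visitLabel
setMethod("visitLabel", "SourceRecording", function(x) x@visit)

#' @rdname epochData
setMethod("epochData", "SourceRecording", function(x, i) {
  stopifnot(length(i) == 1L, i >= 1L, i <= nEpochs(x))
  m <- x@data[i, , , drop = TRUE]
  if (nRegions(x) == 1L) m <- matrix(m, nrow = 1L)
  rownames(m) <- x@region_labels
  m
})

setMethod("show", "SourceRecording", function(object) {
  d <- dim(object@data)
  cat(
    "SourceRecording:", object@participant_id,
    sprintf("[%s]", object@visit), "\n",
    sprintf(
      " %d epochs x %d regions x %d samples at %g Hz (%.1f s/epoch)\n",
      d[1L], d[2L], d[3L], object@sampling_rate,
      d[3L] / object@sampling_rate
    )
  )
  invisible(object)
})

#' ConnectivityMatrix: symmetric pairwise functional connectivity
#'
#' Holds one epoch-averaged region-by-region connectivity matrix for a
#' single measure and frequency band, with optional per-epoch matrices.
#' Values are bounded in `[0, 1]` for all three shipped measures; the
#' diagonal is undefined and stored as `NA`.
#'
#' @slot measure measure name (`"jpe_inv"`, `"aec_c"`, `"aec"` or `"pli"`).
#' @slot band band name, or `"broadband"`.
#' @slot values symmetric numeric matrix with region-label dimnames and
#'   `NA` diagonal.
#' @slot per_epoch list of per-epoch matrices (may be empty).
#' @seealso [connectivityMatrix()]
#' @export
setClass("ConnectivityMatrix",
  representation(
    measure = "character",
    band = "character",
    values = "matrix",
    per_epoch = "list"
  )
)

setValidity("ConnectivityMatrix", function(object) {
  msgs <- character(0)
  v <- object@values
  if (nrow(v) != ncol(v)) msgs <- c(msgs, "values must be square")
  if (is.null(rownames(v))) msgs <- c(msgs, "values must carry region labels")
  off <- v[row(v) != col(v)]
  if (anyNA(off)) {
    msgs <- c(msgs, "off-diagonal values must be finite")
  } else {
    if (max(abs(v - t(v)), na.rm = TRUE) > 1e-12) {
      msgs <- c(msgs, "values must be symmetric within 1e-12")
    }
    if (any(off < -1e-12 | off > 1 + 1e-12)) {
      msgs <- c(msgs, "connectivity values must lie in [0, 1]")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' @rdname regionLabels
setMethod("regionLabels", "ConnectivityMatrix", function(x) rownames(x@values))

#' @rdname nRegions
setMethod("nRegions", "ConnectivityMatrix", function(x) nrow(x@values))

#' @rdname measureName
setMethod("measureName", "ConnectivityMatrix", function(x) x@measure)

#' @rdname bandName
setMethod("bandName", "ConnectivityMatrix", function(x) x@band)

#' @rdname connValues
setMethod("connValues", "ConnectivityMatrix", function(x) x@values)

setMethod("show", "ConnectivityMatrix", function(object) {
  off <- object@values[row(object@values) != col(object@values)]
  cat(
    sprintf(
      "ConnectivityMatrix: %s [%s], %d regions, %d per-epoch matrices\n",
      object@measure, object@band, nrow(object@values),
      length(object@per_epoch)
    ),
    sprintf(
      " off-diagonal range [%.3f, %.3f], mean %.3f\n",
      min(off), max(off), mean(off)
    )
  )
  invisible(object)
})
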