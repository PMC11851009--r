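#' @import methods
NULL

#' Region labels of an object
#'
#' @param x a [SourceRecording-class] or [ConnectivityMatrix-class] object.
#' @return Character vector of region labels.
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))

#' Sampling rate in Hz
#'
#' @param x a [SourceRecording-class] object.
#' @return Sampling rate (Hz).
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Number of epochs
#'
#' @param x a [SourceRecording-class] object.
#' @return Integer epoch count.
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' Number of regions
#'
#' @param x a [SourceRecording-class] or [ConnectivityMatrix-class] object.
#' @return Integer region count.
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))

#' Extract one epoch as a regions-by-samples matrix
#'
#' @param x a [SourceRecording-class] object.
#' @param i epoch index (1-based).
#' @return Numeric matrix, regions in rows, samples in columns.
#' @export
setGeneric("epochData", function(x, i) standardGeneric("epochData"))

#' Participant identifier
#'
#' @param x a [SourceRecording-class] object.
#' @return Character scalar.
#' @export
setGeneric("participantId", function(x) standardGeneric("participantId"))

#' Visit label
#'
#' @param x a [SourceRecording-class] object.
#' @return `"baseline"` or `"followup"`.
#' @export
setGeneric("visitLabel", function(x) standardGeneric("visitLabel"))

#' Connectivity measure name
#'
#' @param x a [ConnectivityMatrix-class] object.
#' @return Character scalar, e.g. `"jpe_inv"`.
#' @export
setGeneric("measureName", function(x) standardGeneric("measureName"))

#' Frequency band name
#'
#' @param x a [ConnectivityMatrix-class] object.
#' @return Character scalar, e.g. `"theta"`, or `"broadband"`.
#' @export
setGeneric("bandName", function(x) standardGeneric("bandName"))

#' Epoch-averaged connectivity values
#'
#' @param x a [ConnectivityMatrix-class] object.
#' @return Symmetric numeric matrix with `NA` diagonal.
#' @export
setGeneric("connValues", function(x) standardGeneric("connValues"))
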