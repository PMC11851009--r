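# Plain-text recording dialect: one whitespace-delimited matrix file per
# participant-visit (header line of region labels, samples as rows,
# epochs concatenated) plus a JSON sidecar holding the sampling rate and
# epoch boundaries.

.sidecarPath <- function(path) paste0(path, ".json")

#' Write a recording as a plain-text matrix plus JSON sidecar
#'
#' @param recording a [SourceRecording-class].
#' @param path output file path for the matrix; the sidecar is written
#'   to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
writeRecording <- function(recording, path) {
  ne <- nEpochs(recording)
  len <- dim(recording@data)[3L]
  m <- do.call(rbind, lapply(seq_len(ne), function(e) {
    t(epochData(recording, e))
  }))
  colnames(m) <- regionLabels(recording)
  utils::write.table(
    format(m, digits = 17, scientific = TRUE, trim = TRUE),
    file = path, quote = FALSE, row.names = FALSE, col.names = TRUE
  )
  sidecar <- list(
    participant_id = participantId(recording),
    visit = visitLabel(recording),
    sampling_rate = samplingRate(recording),
    n_epochs = ne,
    epoch_starts = as.integer((seq_len(ne) - 1L) * len + 1L),
    epoch_len = as.integer(len)
  )
  jsonlite::write_json(sidecar, .sidecarPath(path),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a recording written by [writeRecording()]
#'
#' Validates shape and finiteness; a non-finite cell is reported with
#' its row and column, ragged rows are a parse error, and a missing
#' sidecar is an error.
#'
#' @param path matrix file path (sidecar expected at
#'   `paste0(path, ".json")`).
#' @return A [SourceRecording-class].
#' @export
readRecording <- function(path) {
  if (!file.exists(path)) stop("recording file not found: ", path)
  sc_path <- .sidecarPath(path)
  if (!file.exists(sc_path)) {
    stop("missing sidecar for recording: ", sc_path)
  }
  sidecar <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  m <- tryCatch(
    as.matrix(utils::read.table(path, header = TRUE, check.names = FALSE)),
    error = function(e) stop("parse error in ", path, ": ",
      conditionMessage(e), call. = FALSE)
  )
  if (!is.numeric(m)) {
    bad <- which(!grepl("^[-+0-9.eE]+$", m))[1L]
    stop(
      "non-numeric cell in ", path, " at row ",
      ((bad - 1L) %% nrow(m)) + 1L, ", column ",
      ((bad - 1L) %/% nrow(m)) + 1L
    )
  }
  if (anyNA(m) || !all(is.finite(m))) {
    bad <- which(!is.finite(m))[1L]
    stop(
      "non-finite sample in ", path, " at row ",
      ((bad - 1L) %% nrow(m)) + 1L, " (data row), column ",
      ((bad - 1L) %/% nrow(m)) + 1L, " (", colnames(m)[((bad - 1L) %/%
        nrow(m)) + 1L], ")"
    )
  }
  ne <- sidecar$n_epochs
  len <- sidecar$epoch_len
  if (nrow(m) != ne * len) {
    stop(
      "file has ", nrow(m), " sample rows but sidecar declares ",
      ne, " epochs of ", len
    )
  }
  arr <- array(0, dim = c(ne, ncol(m), len))
  for (e in seq_len(ne)) {
    rows <- sidecar$epoch_starts[e] + seq_len(len) - 1L
    arr[e, , ] <- t(m[rows, , drop = FALSE])
  }
  sourceRecording(arr,
    region_labels = colnames(m),
    sampling_rate = sidecar$sampling_rate,
    participant_id = sidecar$participant_id,
    visit = sidecar$visit
  )
}
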