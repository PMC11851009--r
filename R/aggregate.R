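.roiCheckMembers <- function(members, labels, roi_name) {
  absent <- setdiff(members, labels)
  if (length(absent)) {
    stop(
      "ROI '", roi_name, "' members absent from parcellation: ",
      paste(absent, collapse = ", ")
    )
  }
}

#' ROI-averaged relative power
#'
#' Unweighted mean of the member regions' relative power, per band.
#'
#' @param power regions x bands matrix as returned by [relativePower()]
#'   (rows named by region).
#' @param roi a [roiDefinition()]; all members must be present.
#' @return Named numeric vector, one value per band.
#' @export
roiPower <- function(power, roi) {
  .roiCheckMembers(roi$members, rownames(power), roi$name)
  colMeans(power[roi$members, , drop = FALSE])
}

#' ROI-to-rest average connectivity
#'
#' Mean connectivity over all pairs with one region inside the ROI and
#' one outside; within-ROI pairs are excluded by construction.
#'
#' @param conn a [ConnectivityMatrix-class] or symmetric numeric matrix
#'   with region-label dimnames.
#' @param roi a [roiDefinition()]; must be a proper subset of the
#'   parcellation.
#' @return Scalar mean connectivity.
#' @export
roiToRestConnectivity <- function(conn, roi) {
  v <- if (is(conn, "ConnectivityMatrix")) connValues(conn) else conn
  labs <- rownames(v)
  .roiCheckMembers(roi$members, labs, roi$name)
  rest <- setdiff(labs, roi$members)
  if (!length(rest)) {
    stop("ROI '", roi$name, "' covers all regions; no 'rest' to average over")
  }
  mean(v[roi$members, rest, drop = FALSE])
}

#' Whole-brain average connectivity
#'
#' Mean over the strict upper triangle: all unordered region pairs,
#' diagonal excluded (within-ROI pairs included).
#'
#' @param conn a [ConnectivityMatrix-class] or symmetric numeric matrix.
#' @return Scalar mean connectivity.
#' @export
wholeBrainConnectivity <- function(conn) {
  v <- if (is(conn, "ConnectivityMatrix")) connValues(conn) else conn
  if (nrow(v) < 2L) stop("need at least 2 regions")
  mean(v[upper.tri(v)])
}

#' Default connectivity measure grid
#'
#' The three connectivity outcomes and their bands: inverted joint
#' permutation entropy in theta (4-8 Hz), leakage-corrected amplitude
#' envelope correlation in alpha (8-13 Hz) and phase lag index in theta.
#'
#' @return `data.frame` with columns `measure` and `band`.
#' @export
connectivityGrid <- function() {
  data.frame(
    measure = c("jpe_inv", "aec_c", "pli"),
    band = c("theta", "alpha", "theta"),
    stringsAsFactors = FALSE
  )
}

# Band lookup covering the six canonical bands plus the merged alpha
# band used by the amplitude envelope correlation.
.extendedBands <- function(bands = bandSet()) {
  if (!"alpha" %in% names(bands)) bands$alpha <- c(8, 13)
  bands
}

#' Build the participant-level measure table
#'
#' Maps region-level power and pairwise connectivity of each recording
#' onto the three analysis levels: the early Alzheimer's disease ROI
#' (`early_roi`: ROI-mean power), its connectivity with the rest of the
#' brain (`early_roi_to_rest`) and the whole brain (`whole_brain`:
#' all-region mean power / strict-upper-triangle mean connectivity).
#'
#' @param recordings list of [SourceRecording-class] objects.
#' @param roi the early-disease [roiDefinition()]; default [earlyADRoi()].
#' @param bands a [bandSet()] for power.
#' @param conn_grid connectivity measures and bands, see
#'   [connectivityGrid()]; pass a zero-row data.frame to skip
#'   connectivity.
#' @param params [ordinalParams()] for the entropy measure.
#' @return Long `data.frame` (the measure table) with columns
#'   `participant_id`, `visit`, `analysis_level`, `measure`, `band`,
#'   `value`; one row per participant-visit-level-measure-band.
#' @export
buildMeasureTable <- function(recordings, roi = earlyADRoi(),
                              bands = bandSet(),
                              conn_grid = connectivityGrid(),
                              params = ordinalParams()) {
  allb <- .extendedBands(bands)
  rows <- lapply(recordings, function(rec) {
    id <- participantId(rec)
    visit <- visitLabel(rec)
    rp <- relativePower(rec, bands)
    roi_p <- roiPower(rp, roi)
    wb_p <- colMeans(rp)
    out <- data.frame(
      participant_id = id, visit = visit,
      analysis_level = rep(c("early_roi", "whole_brain"),
        each = length(roi_p)
      ),
      measure = "rel_power",
      band = rep(names(roi_p), 2L),
      value = c(roi_p, wb_p),
      stringsAsFactors = FALSE
    )
    if (nrow(conn_grid)) {
      for (k in seq_len(nrow(conn_grid))) {
        cm <- connectivityMatrix(rec,
          measure = conn_grid$measure[k],
          band = conn_grid$band[k], params = params, bands = allb
        )
        out <- rbind(out, data.frame(
          participant_id = id, visit = visit,
          analysis_level = c("early_roi_to_rest", "whole_brain"),
          measure = conn_grid$measure[k],
          band = conn_grid$band[k],
          value = c(
            roiToRestConnectivity(cm, roi),
            wholeBrainConnectivity(cm)
          ),
          stringsAsFactors = FALSE
        ))
      }
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (anyNA(out$value) || !all(is.finite(out$value))) {
    stop("measure table contains non-finite values")
  }
  out
}
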