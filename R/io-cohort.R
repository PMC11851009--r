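.cohort_required_cols <- c(
  "participant_id", "family_id", "age", "sex", "visit",
  "time_since_baseline", "abeta_early_roi", "abeta_whole_brain"
)

#' Validate a cohort table
#'
#' Enforces the cohort invariants: required columns present, one
#' baseline and at most one follow-up row per participant, time zero at
#' baseline and positive at follow-up, known sex codes, and no
#' duplicate participant-visit rows.
#'
#' @param tab a cohort `data.frame`.
#' @return The table, canonically sorted by participant then visit.
#' @export
validateCohort <- function(tab) {
  missing_cols <- setdiff(.cohort_required_cols, names(tab))
  if (length(missing_cols)) {
    stop("cohort lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!all(tab$visit %in% c("baseline", "followup"))) {
    stop("visit must be 'baseline' or 'followup'")
  }
  if (!all(tab$sex %in% c("F", "M"))) {
    stop("unknown sex code (expected 'F' or 'M')")
  }
  key <- paste(tab$participant_id, tab$visit)
  if (anyDuplicated(key)) {
    stop("duplicate participant-visit row(s): ", key[duplicated(key)][1L])
  }
  base <- tab[tab$visit == "baseline", , drop = FALSE]
  if (!setequal(base$participant_id, unique(tab$participant_id))) {
    stop("every participant needs exactly one baseline row")
  }
  if (any(base$time_since_baseline != 0)) {
    stop("time_since_baseline must be 0 at baseline")
  }
  fup <- tab[tab$visit == "followup", , drop = FALSE]
  if (any(fup$time_since_baseline <= 0)) {
    stop("time_since_baseline must be > 0 at follow-up")
  }
  tab[order(tab$participant_id, tab$visit), , drop = FALSE]
}

#' Write a cohort table as CSV
#'
#' UTF-8, header row, '.' decimal separator.
#'
#' @param tab cohort table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCohort <- function(tab, path) {
  keep <- intersect(
    c(.cohort_required_cols, "drift_early_roi", "drift_whole_brain"),
    names(tab)
  )
  utils::write.csv(tab[, keep, drop = FALSE], path,
    row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' Read and validate a cohort CSV
#'
#' @param path CSV path.
#' @return Validated, canonically sorted cohort `data.frame`.
#' @export
readCohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  # sex must be read as character: a column of "F" would otherwise be
  # parsed as logical FALSE
  tab <- utils::read.csv(path,
    stringsAsFactors = FALSE,
    colClasses = c(
      participant_id = "character", family_id = "character",
      sex = "character", visit = "character"
    )
  )
  tab <- validateCohort(tab)
  rownames(tab) <- NULL
  tab
}
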