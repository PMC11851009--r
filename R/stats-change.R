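#' Annual change per participant
#'
#' `(follow-up - baseline) / follow-up interval` for each requested
#' variable, one row per participant, carrying age, sex and family for
#' the change-on-change models. Participants missing either visit for a
#' variable get `NA` for that change (missingness propagates; models
#' drop such rows listwise).
#'
#' @param data long-format participant-visit table (cohort columns plus
#'   any measure columns).
#' @param variables columns to difference.
#' @return `data.frame`: `participant_id`, `family_id`, `age`, `sex`,
#'   `followup_time`, and one `change_<variable>` column per input.
#' @examples
#' cohort <- generateCohort(cohortConfig(seed = 1))
#' ch <- annualChange(cohort, "abeta_whole_brain")
#' @export
annualChange <- function(data, variables) {
  base <- data[data$visit == "baseline", , drop = FALSE]
  fup <- data[data$visit == "followup", , drop = FALSE]
  m <- match(base$participant_id, fup$participant_id)
  interval <- fup$time_since_baseline[m]
  if (any(!is.na(interval) & interval <= 0)) {
    stop("non-positive follow-up interval")
  }
  out <- data.frame(
    participant_id = base$participant_id,
    family_id = base$family_id,
    age = base$age,
    sex = base$sex,
    followup_time = interval,
    stringsAsFactors = FALSE
  )
  for (v in variables) {
    out[[paste0("change_", v)]] <- (fup[[v]][m] - base[[v]]) / interval
  }
  out
}

#' Screen annual amyloid change for extreme participants
#'
#' Z-transforms each named change column and excludes participants whose
#' absolute z-value exceeds the threshold in any of them -- the explicit
#' rule standing in for ad-hoc removal of "fast accumulators" whose
#' extreme annual change would otherwise dominate the change-on-change
#' models. `threshold = Inf` retains everyone.
#'
#' @param change a table from [annualChange()].
#' @param variables change column names to screen (default: all
#'   `change_*` columns).
#' @param threshold absolute z-value cut-off (default 4).
#' @return List: `kept` (filtered table), `excluded` (data.frame of
#'   participant, variable, z for each exclusion).
#' @export
detectOutliers <- function(change, variables = NULL, threshold = 4) {
  if (is.null(variables)) {
    variables <- grep("^change_", names(change), value = TRUE)
  }
  rows <- stats::complete.cases(change[, variables, drop = FALSE])
  if (sum(rows) < 3L) stop("need at least 3 participants with change values")
  excluded <- NULL
  drop <- rep(FALSE, nrow(change))
  for (v in variables) {
    x <- change[[v]]
    z <- (x - mean(x, na.rm = TRUE)) / stats::sd(x, na.rm = TRUE)
    bad <- !is.na(z) & abs(z) > threshold
    if (any(bad)) {
      excluded <- rbind(excluded, data.frame(
        participant_id = change$participant_id[bad],
        variable = v, z = z[bad], stringsAsFactors = FALSE
      ))
      drop <- drop | bad
    }
  }
  if (all(drop)) stop("outlier screening excluded every participant")
  list(kept = change[!drop, , drop = FALSE], excluded = excluded)
}

#' Fit a change-on-change mixed model
#'
#' `z(change in outcome) ~ z(change in predictor) + z(age) + sex` with a
#' family random intercept, by REML -- the annual-change analysis
#' relating amyloid accumulation rate to the rate of change of a MEG
#' measure.
#'
#' @param change a table from [annualChange()] (after optional
#'   [detectOutliers()] screening).
#' @param outcome,predictor change column names.
#' @return A `"FitResult"` (see [fitLongitudinal()]); the predictor term
#'   is named `pred`.
#' @export
fitChangeModel <- function(change, outcome, predictor) {
  d <- data.frame(
    participant_id = change$participant_id,
    family_id = change$family_id,
    y = change[[outcome]],
    pred = change[[predictor]],
    age = change$age,
    sex = as.numeric(change$sex %in% c("F", "f", 1)),
    stringsAsFactors = FALSE
  )
  keep <- stats::complete.cases(d)
  excluded <- unique(d$participant_id[!keep])
  d <- d[keep, , drop = FALSE]
  if (nrow(d) < 6L) stop("too few complete rows to fit the model")
  d <- zScale(d, c("y", "pred", "age"))
  d$time <- 0 # unused; keeps the shared design helpers applicable
  structure_ <- .longStructure(d, random = "~(1 | family_id)")
  X <- cbind(`(Intercept)` = 1, pred = d$pred, age = d$age, sex = d$sex)
  fit <- .fitModular(X, structure_)
  if (!fit$converged) stop("change model failed to converge")
  res <- list(
    coefficients = .coefTable(fit, nrow(d), ncol(X)),
    n_used = nrow(d),
    n_rows = nrow(d),
    excluded_ids = excluded,
    singular = fit$singular,
    interaction_retained = FALSE,
    model_note = "annual-change model (family random intercept)",
    prepared = d,
    structure = structure_,
    xbuilder = function(dd) {
      cbind(`(Intercept)` = 1, pred = dd$pred, age = dd$age, sex = dd$sex)
    }
  )
  class(res) <- "FitResult"
  res
}
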