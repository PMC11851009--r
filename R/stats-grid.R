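# The analysis grid: 9 MEG outcomes (6 relative-power bands + 3
# connectivity measures) x 3 level pairings, per direction.

.outcomeGrid <- function() {
  rbind(
    data.frame(
      measure = "rel_power",
      band = c("delta", "theta", "alpha1", "alpha2", "beta", "gamma"),
      stringsAsFactors = FALSE
    ),
    connectivityGrid()
  )
}

.pairings <- function() {
  data.frame(
    pairing = c("early~early", "early~wholebrain", "wholebrain~wholebrain"),
    abeta_var = c("abeta_early_roi", "abeta_early_roi", "abeta_whole_brain"),
    meg_level_power = c("early_roi", "whole_brain", "whole_brain"),
    meg_level_conn = c("early_roi_to_rest", "whole_brain", "whole_brain"),
    stringsAsFactors = FALSE
  )
}

.isPrimary <- function(measure, band) {
  (measure == "rel_power" & band == "theta") |
    (measure == "jpe_inv" & band == "theta")
}

# Merge one outcome's measure values onto the cohort rows.
.mergeOutcome <- function(measures, cohort, measure, band, level) {
  sel <- measures[
    measures$measure == measure & measures$band == band &
      measures$analysis_level == level, , drop = FALSE
  ]
  key_c <- paste(cohort$participant_id, cohort$visit)
  key_m <- paste(sel$participant_id, sel$visit)
  cohort$meg <- sel$value[match(key_c, key_m)]
  cohort
}

.cellRow <- function(measure, band, pairing, fit, term, primary) {
  co <- fit$coefficients
  i <- match(term, co$term)
  data.frame(
    measure = measure, band = band, pairing = pairing,
    beta = co$beta[i], se = co$se[i], t = co$t[i], p = co$p[i],
    p_perm = if (is.null(fit$p_perm)) NA_real_ else fit$p_perm,
    primary = primary, n = fit$n_used,
    note = fit$model_note,
    stringsAsFactors = FALSE
  )
}

.addFdr <- function(tab, p_col = "p") {
  tab$q <- NA_real_
  idx <- which(tab$primary & !is.na(tab[[p_col]]))
  if (length(idx)) tab$q[idx] <- fdrCorrect(tab[[p_col]][idx])
  tab
}

# Failed cells are recorded, not fatal: the grid stays complete with an
# explicit error note in place of estimates.
.errorRow <- function(measure, band, pairing, primary, err) {
  data.frame(
    measure = measure, band = band, pairing = pairing,
    beta = NA_real_, se = NA_real_, t = NA_real_, p = NA_real_,
    p_perm = NA_real_, primary = primary, n = NA_integer_,
    note = paste("error:", conditionMessage(err)),
    stringsAsFactors = FALSE
  )
}

#' Run the full amyloid-MEG analysis grid
#'
#' Fits, for every MEG outcome (6 relative-power bands, 3 connectivity
#' measures) and every level pairing (early-disease ROI amyloid vs
#' early-ROI MEG, early-ROI amyloid vs whole-brain MEG, whole-brain
#' amyloid vs whole-brain MEG):
#' \itemize{
#'   \item the longitudinal model (amyloid-by-time interaction),
#'   \item the cross-sectional association (interaction-gated model
#'     selection, see [selectModel()]),
#'   \item optionally the reverse direction (baseline MEG predicting
#'     amyloid), and
#'   \item the change-on-change model on annual changes, after screening
#'     extreme amyloid accumulators ([detectOutliers()]).
#' }
#' Permutation p-values shuffle the amyloid variable matching the
#' pairing's level across individuals (`B` refits per cell; `B = 0`
#' skips permutation). False discovery rate q-values are computed per
#' result table over the primary-measure cells (theta relative power and
#' theta entropy connectivity across the 3 pairings, 6 tests).
#'
#' @param measures a measure table from [buildMeasureTable()].
#' @param cohort a cohort table from [generateCohort()] (or equivalent).
#' @param directions subset of `c("abeta_to_meg", "meg_to_abeta",
#'   "change")`.
#' @param B permutations per cell (default 1000; 0 disables).
#' @param seed root seed for the permutation streams.
#' @param alpha_gate interaction gate level for model selection.
#' @param outlier_z z-threshold for annual-change screening.
#' @return List of result tables (`cross_sectional`, `longitudinal`,
#'   `reverse_cross_sectional`, `reverse_longitudinal`, `change` as
#'   requested), plus `exclusions` and `settings`.
#' @export
runGrid <- function(measures, cohort,
                    directions = c("abeta_to_meg", "meg_to_abeta", "change"),
                    B = 1000L, seed = 1L, alpha_gate = 0.05,
                    outlier_z = 4) {
  directions <- match.arg(directions, several.ok = TRUE)
  grid <- .outcomeGrid()
  pairs <- .pairings()
  res <- list()
  exclusions <- list()

  cellSeed <- function(...) {
    .substreamSeed(seed, paste(..., collapse = ":"))
  }
  permIf <- function(fit, effect, sd) {
    if (B > 0L) permutationPvalue(fit, B = B, effect = effect, seed = sd)
    else fit
  }

  forward <- "abeta_to_meg" %in% directions
  reverse <- "meg_to_abeta" %in% directions
  if (forward || reverse) {
    cs <- lon <- rcs <- rlon <- NULL
    for (g in seq_len(nrow(grid))) {
      m <- grid$measure[g]
      b <- grid$band[g]
      primary <- .isPrimary(m, b)
      for (p in seq_len(nrow(pairs))) {
        level <- if (m == "rel_power") {
          pairs$meg_level_power[p]
        } else {
          pairs$meg_level_conn[p]
        }
        dat <- .mergeOutcome(measures, cohort, m, b, level)
        abv <- pairs$abeta_var[p]
        pg <- pairs$pairing[p]
        if (forward) {
          rows <- tryCatch({
            fit <- suppressWarnings(fitLongitudinal(dat, "meg", abv))
            fit_l <- permIf(fit, "interaction",
              cellSeed("fwd", m, b, pg, "i"))
            fit_c <- suppressWarnings(selectModel(fit, alpha = alpha_gate))
            fit_c <- permIf(fit_c, "main", cellSeed("fwd", m, b, pg, "m"))
            list(
              lon = .cellRow(m, b, pg, fit_l, "pred:time", primary),
              cs = .cellRow(m, b, pg, fit_c, "pred", primary)
            )
          }, error = function(e) {
            r <- .errorRow(m, b, pg, primary, e)
            list(lon = r, cs = r)
          })
          lon <- rbind(lon, rows$lon)
          cs <- rbind(cs, rows$cs)
        }
        if (reverse) {
          rows <- tryCatch({
            fit <- suppressWarnings(fitLongitudinal(dat, abv, "meg"))
            fit_l <- permIf(fit, "interaction",
              cellSeed("rev", m, b, pg, "i"))
            fit_c <- suppressWarnings(selectModel(fit, alpha = alpha_gate))
            fit_c <- permIf(fit_c, "main", cellSeed("rev", m, b, pg, "m"))
            list(
              lon = .cellRow(m, b, pg, fit_l, "pred:time", primary),
              cs = .cellRow(m, b, pg, fit_c, "pred", primary)
            )
          }, error = function(e) {
            r <- .errorRow(m, b, pg, primary, e)
            list(lon = r, cs = r)
          })
          rlon <- rbind(rlon, rows$lon)
          rcs <- rbind(rcs, rows$cs)
        }
      }
    }
    if (forward) {
      res$cross_sectional <- .addFdr(cs)
      res$longitudinal <- .addFdr(lon)
    }
    if (reverse) {
      res$reverse_cross_sectional <- .addFdr(rcs)
      res$reverse_longitudinal <- .addFdr(rlon)
    }
  }

  if ("change" %in% directions) {
    ch <- NULL
    for (g in seq_len(nrow(grid))) {
      m <- grid$measure[g]
      b <- grid$band[g]
      primary <- .isPrimary(m, b)
      for (p in seq_len(nrow(pairs))) {
        level <- if (m == "rel_power") {
          pairs$meg_level_power[p]
        } else {
          pairs$meg_level_conn[p]
        }
        dat <- .mergeOutcome(measures, cohort, m, b, level)
        abv <- pairs$abeta_var[p]
        pg <- pairs$pairing[p]
        row <- tryCatch({
          chtab <- annualChange(dat, c(abv, "meg"))
          screened <- detectOutliers(chtab,
            variables = paste0("change_", abv), threshold = outlier_z
          )
          if (!is.null(screened$excluded)) {
            exclusions[[paste(m, b, pg, sep = ":")]] <- screened$excluded
          }
          fit <- suppressWarnings(fitChangeModel(
            screened$kept, "change_meg", paste0("change_", abv)
          ))
          fit <- permIf(fit, "main", cellSeed("chg", m, b, pg))
          .cellRow(m, b, pg, fit, "pred", primary)
        }, error = function(e) .errorRow(m, b, pg, primary, e))
        ch <- rbind(ch, row)
      }
    }
    res$change <- .addFdr(ch)
  }

  res$exclusions <- exclusions
  res$settings <- list(
    B = B, seed = seed, alpha_gate = alpha_gate, outlier_z = outlier_z,
    directions = directions
  )
  res
}
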