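#' Permutation p-value for a mixed-model effect
#'
#' Builds a null distribution of the t-statistic by randomly shuffling
#' the participant-level (baseline) predictor values across individuals
#' while preserving the outcomes and covariates: both visits of a
#' participant carry the same shuffled value, and the model is refitted
#' for every permutation. The two-sided p-value uses the add-one
#' estimator `(1 + #{|t*| >= |t_obs|}) / (B + 1)`, so its minimum is
#' `1/(B + 1)` and it can never be zero. The observed-data scaling of
#' the variables is reused inside the loop by default.
#'
#' @param fit a `"FitResult"` from [fitLongitudinal()] (or a reduced fit
#'   from [selectModel()]).
#' @param B number of permutations (default 1000).
#' @param effect `"main"` (the predictor main effect) or `"interaction"`
#'   (predictor-by-time; requires the interaction model).
#' @param seed integer seed; the permutation stream is independent of
#'   other generator substreams.
#' @param unit `"individual"` (default: shuffle across individuals,
#'   ignoring family ties) or `"family"` (shuffle whole families, a
#'   sensitivity variant that respects twin exchangeability).
#' @return The fit with `p_perm`, `perm_effect`, `B`, `t_obs`,
#'   `n_perm_failed` fields added. Non-converged permutations are
#'   dropped and counted; more than 10\% failures is an error.
#' @export
permutationPvalue <- function(fit, B = 1000L, effect = c("main",
                                "interaction"),
                              seed = 1L, unit = c("individual", "family")) {
  effect <- match.arg(effect)
  unit <- match.arg(unit)
  B <- as.integer(B)
  if (B < 1L) stop("B must be >= 1")
  term <- if (effect == "main") "pred" else "pred:time"
  co <- fit$coefficients
  if (!term %in% co$term) {
    stop("effect '", effect, "' not present in the fitted model")
  }
  t_obs <- co$t[co$term == term]
  d <- fit$prepared
  interaction <- fit$interaction_retained

  ids <- unique(d$participant_id)
  pred_of <- d$pred[match(ids, d$participant_id)]
  row_of <- match(d$participant_id, ids)
  fam_of <- d$family_id[match(ids, d$participant_id)]

  t_star <- rep(NA_real_, B)
  .withSeed(.substreamSeed(seed, "permutations"), {
    for (b in seq_len(B)) {
      if (unit == "individual") {
        shuffled <- pred_of[sample.int(length(ids))]
      } else {
        fams <- unique(fam_of)
        fmap <- fams[sample.int(length(fams))]
        # swap the predictor sets of whole families
        shuffled <- pred_of
        for (fi in seq_along(fams)) {
          src <- which(fam_of == fmap[fi])
          dst <- which(fam_of == fams[fi])
          k <- min(length(src), length(dst))
          shuffled[dst[seq_len(k)]] <- pred_of[src[seq_len(k)]]
        }
      }
      dp <- d
      dp$pred <- shuffled[row_of]
      X <- fit$xbuilder(dp)
      res <- tryCatch(.fitModular(X, fit$structure), error = function(e) NULL)
      if (!is.null(res) && res$converged) {
        t_star[b] <- res$t[[term]]
      }
    }
  })
  failed <- sum(is.na(t_star))
  if (failed > 0.1 * B) {
    stop(failed, " of ", B, " permutation refits failed to converge")
  }
  t_ok <- t_star[!is.na(t_star)]
  fit$p_perm <- (1 + sum(abs(t_ok) >= abs(t_obs))) / (length(t_ok) + 1)
  fit$perm_effect <- effect
  fit$B <- B
  fit$t_obs <- t_obs
  fit$n_perm_failed <- failed
  fit
}
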