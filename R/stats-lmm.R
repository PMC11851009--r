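# Longitudinal mixed models: outcome ~ predictor + time + predictor:time
# + age + sex, random intercepts for subject nested in family, REML.
# Scaling convention: outcome, predictor and age are z-scaled on the
# analyzed rows; time stays in years; sex is 0/1 (F = 1).

.prepareLongData <- function(data, outcome, predictor,
                             baseline_predictor = TRUE) {
  need <- c(
    outcome, predictor, "participant_id", "family_id", "visit",
    "time_since_baseline", "age", "sex"
  )
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("data lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  d <- data.frame(
    participant_id = data$participant_id,
    family_id = data$family_id,
    y = data[[outcome]],
    pred = data[[predictor]],
    time = data$time_since_baseline,
    age = data$age,
    sex = as.numeric(data$sex %in% c("F", "f", 1)),
    stringsAsFactors = FALSE
  )
  if (baseline_predictor) {
    base <- d[data$visit == "baseline", c("participant_id", "pred")]
    d$pred <- base$pred[match(d$participant_id, base$participant_id)]
  }
  keep <- stats::complete.cases(d)
  excluded <- unique(d$participant_id[!keep])
  d <- d[keep, , drop = FALSE]
  d <- zScale(d, c("y", "pred", "age"))
  list(data = d, excluded = excluded)
}

# Fixed-effects design matrix; permutations only swap the pred column
# (and hence the interaction column) across individuals.
.longX <- function(d, interaction = TRUE) {
  if (interaction) {
    cbind(
      `(Intercept)` = 1, pred = d$pred, time = d$time,
      age = d$age, sex = d$sex, `pred:time` = d$pred * d$time
    )
  } else {
    cbind(
      `(Intercept)` = 1, pred = d$pred, time = d$time,
      age = d$age, sex = d$sex
    )
  }
}

# Fit an LMM by REML from a design matrix and pre-parsed random-effect
# terms, using the modular lme4 interface (one parse, many refits).
.fitModular <- function(X, structure) {
  devfun <- lme4::mkLmerDevfun(structure$fr, X, structure$reTrms,
    REML = TRUE
  )
  opt <- lme4::optimizeLmer(devfun,
    control = lme4::lmerControl(calc.derivs = FALSE)$optCtrl
  )
  mod <- lme4::mkMerMod(
    environment(devfun), opt, structure$reTrms, fr = structure$fr
  )
  beta <- lme4::fixef(mod)
  se <- sqrt(diag(as.matrix(stats::vcov(mod))))
  list(
    beta = beta, se = se, t = beta / se,
    singular = lme4::isSingular(mod),
    converged = is.null(mod@optinfo$conv$lme4$messages) ||
      !any(grepl("failed to converge", mod@optinfo$conv$lme4$messages)),
    sigma = stats::sigma(mod), model = mod
  )
}

.longStructure <- function(d, random = "~(1 | family_id / participant_id)") {
  fake <- stats::as.formula(paste("y ~ 1 +", sub("^~", "", random)))
  parsed <- lme4::lFormula(fake,
    data = d,
    control = lme4::lmerControl(
      check.nobs.vs.nlev = "ignore", check.nobs.vs.nRE = "ignore"
    )
  )
  list(fr = parsed$fr, reTrms = parsed$reTrms)
}

.coefTable <- function(fit, n, p_fixed) {
  df <- n - p_fixed
  data.frame(
    term = names(fit$beta),
    beta = as.numeric(fit$beta),
    se = as.numeric(fit$se),
    t = as.numeric(fit$t),
    p = 2 * stats::pt(-abs(as.numeric(fit$t)), df = df),
    stringsAsFactors = FALSE
  )
}

#' Fit the longitudinal amyloid-MEG mixed model
#'
#' Fits, by restricted maximum likelihood,
#' `z(outcome) ~ z(predictor_baseline) + time + z(predictor):time +
#' z(age) + sex` with random intercepts for subject nested within family
#' (a twin pair forms one family). The predictor entering the model is
#' the participant's baseline value carried to both visits; time is in
#' years since baseline. Parametric p-values use the t-statistic with
#' residual-based degrees of freedom (`n - n_fixed`).
#'
#' @param data long-format table: one row per participant-visit with the
#'   outcome, the predictor, `participant_id`, `family_id`, `visit`,
#'   `time_since_baseline`, `age`, `sex`. Rows with missing values are
#'   dropped listwise.
#' @param outcome,predictor column names.
#' @param interaction include the predictor-by-time interaction
#'   (default `TRUE`).
#' @return A list with class `"FitResult"`: `coefficients` (term, beta,
#'   se, t, p on the standardized scale), `n_used`, `excluded_ids`,
#'   `singular`, `interaction_retained`, `model_note`, plus the prepared
#'   data and design structure used by [permutationPvalue()] and
#'   [selectModel()].
#' @examples
#' cohort <- simulateMeasure(generateCohort(cohortConfig(seed = 3)),
#'   effect_cross = 0.3
#' )
#' fit <- fitLongitudinal(cohort, "outcome", "abeta_whole_brain")
#' fit$coefficients
#' @export
fitLongitudinal <- function(data, outcome, predictor, interaction = TRUE) {
  prep <- .prepareLongData(data, outcome, predictor)
  d <- prep$data
  if (nrow(d) < 6L) stop("too few complete rows to fit the model")
  structure_ <- .longStructure(d)
  X <- .longX(d, interaction = interaction)
  fit <- .fitModular(X, structure_)
  if (!fit$converged) {
    stop("mixed model failed to converge: ",
      paste(unlist(fit$model@optinfo$conv$lme4$messages), collapse = "; "))
  }
  if (fit$singular) {
    warning("singular mixed-model fit (a variance component is zero)",
      call. = FALSE)
  }
  res <- list(
    coefficients = .coefTable(fit, nrow(d), ncol(X)),
    n_used = length(unique(d$participant_id)),
    n_rows = nrow(d),
    excluded_ids = prep$excluded,
    singular = fit$singular,
    interaction_retained = interaction,
    model_note = if (interaction) "full model with interaction" else
      "model without interaction term",
    prepared = d,
    structure = structure_,
    xbuilder = function(dd) .longX(dd, interaction = interaction)
  )
  class(res) <- "FitResult"
  res
}

#' @export
print.FitResult <- function(x, ...) {
  cat("Linear mixed model (", x$model_note, "), n = ", x$n_used,
    " participants, ", x$n_rows, " rows\n",
    sep = ""
  )
  print(x$coefficients, row.names = FALSE, digits = 3)
  if (!is.null(x$p_perm)) {
    cat(sprintf(
      "permutation p (%s effect, B = %d): %.4g\n",
      x$perm_effect, x$B, x$p_perm
    ))
  }
  if (x$singular) cat("note: singular fit\n")
  invisible(x)
}

#' Gate on the interaction term and refit if warranted
#'
#' If the predictor-by-time interaction is not significant at `alpha`,
#' the model is refitted without it and the cross-sectional association
#' is read from the reduced model's predictor main effect; otherwise the
#' full-model fit is returned unchanged. The gate uses the parametric
#' p-value by default; a permutation p can be supplied instead.
#'
#' @param fit a `"FitResult"` from [fitLongitudinal()] with interaction.
#' @param alpha gate level (default 0.05).
#' @param gate_p optional p-value to gate on (e.g. a permutation p);
#'   defaults to the parametric interaction p.
#' @return A `"FitResult"`; `$model_note` records the provenance.
#' @export
selectModel <- function(fit, alpha = 0.05, gate_p = NULL) {
  co <- fit$coefficients
  if (!"pred:time" %in% co$term) {
    return(fit) # already reduced
  }
  p_int <- if (is.null(gate_p)) co$p[co$term == "pred:time"] else gate_p
  if (p_int < alpha) {
    fit$model_note <- paste0(
      "full model retained (interaction p = ", signif(p_int, 3), ")"
    )
    return(fit)
  }
  d <- fit$prepared
  X <- .longX(d, interaction = FALSE)
  red <- .fitModular(X, fit$structure)
  out <- fit
  out$coefficients <- .coefTable(red, nrow(d), ncol(X))
  out$singular <- red$singular
  out$interaction_retained <- FALSE
  out$xbuilder <- function(dd) .longX(dd, interaction = FALSE)
  out$model_note <- paste0(
    "interaction dropped (p = ", signif(p_int, 3),
    "); cross-sectional association from reduced model"
  )
  out
}
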