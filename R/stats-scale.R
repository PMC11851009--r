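#' Z-scale variables within an analysis table
#'
#' Centres and scales the named columns to mean 0 and standard deviation
#' 1, computed on the rows entering the model -- the convention used for
#' predictor and outcome variables so standardized effect sizes are
#' comparable across models.
#'
#' @param table a `data.frame`.
#' @param variables character vector of column names to scale.
#' @return The table with the named columns scaled.
#' @export
zScale <- function(table, variables) {
  for (v in variables) {
    x <- table[[v]]
    if (is.null(x)) stop("variable '", v, "' not found")
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      stop("variable '", v, "' has zero variance among analyzed rows")
    }
    table[[v]] <- (x - mean(x, na.rm = TRUE)) / s
  }
  table
}

#' Benjamini-Hochberg q-values for a family of tests
#'
#' Step-up false discovery rate correction; a thin validated wrapper
#' around [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values, same order as `p`.
#' @examples
#' fdrCorrect(c(0.01, 0.02, 0.03)) # all 0.03
#' @export
fdrCorrect <- function(p) {
  if (!length(p)) stop("empty p-value family")
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}
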