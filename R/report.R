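#' Significance marker for a p-value
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, `#` for
#' p < 0.1, empty otherwise.
#'
#' @param p p-value (scalar or vector).
#' @return Character marker(s).
#' @examples
#' sigMarker(0.004) # "**"
#' sigMarker(0.07) # "#"
#' @export
sigMarker <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return("")
    if (pi < 0.001) "***" else if (pi < 0.01) "**" else if (pi < 0.05) {
      "*"
    } else if (pi < 0.1) "#" else ""
  }, character(1))
}

# For primary measures the cell shows "<p marker>/<q marker>", e.g.
# "**/*" for p < 0.01 and q < 0.05; a non-significant q prints "n.s.".
.cellMarker <- function(p, q, primary) {
  pm <- sigMarker(p)
  out <- pm
  idx <- which(primary & pm != "")
  if (length(idx)) {
    qm <- sigMarker(q[idx])
    qm[qm == ""] <- "n.s."
    out[idx] <- paste0(pm[idx], "/", qm)
  }
  out
}

.renderTable <- function(tab, title, p_col) {
  pairs <- unique(tab$pairing)
  lines <- c(title, strrep("-", nchar(title)))
  header <- sprintf("%-18s %s", "Outcome", paste(sprintf("%-28s", pairs),
    collapse = " "))
  lines <- c(lines, header)
  keys <- unique(tab[, c("measure", "band")])
  for (k in seq_len(nrow(keys))) {
    row <- tab[tab$measure == keys$measure[k] & tab$band == keys$band[k], ]
    row <- row[match(pairs, row$pairing), ]
    marker <- .cellMarker(row[[p_col]], row$q, row$primary)
    cells <- ifelse(
      is.na(row$beta), "--",
      sprintf("%.3g (%.2g)%s", row$beta, row$se, marker)
    )
    lines <- c(lines, sprintf(
      "%-18s %s", paste(keys$measure[k], keys$band[k]),
      paste(sprintf("%-28s", cells), collapse = " ")
    ))
  }
  c(lines, "")
}

#' Render the analysis-grid results as a human-readable report
#'
#' One 9-outcome by 3-pairing grid per result table, cells formatted as
#' `beta (SE)` with significance markers (`*` p < 0.05, `**` p < 0.01,
#' `***` p < 0.001, `#` p < 0.1); primary measures additionally show the
#' FDR q marker after a slash (`**/*` means p < 0.01 and q < 0.05).
#' Permutation p-values are used for the markers when present,
#' parametric p otherwise. Missing cells render as `--`.
#'
#' @param results a result list from [runGrid()].
#' @return Character vector of report lines.
#' @export
renderReport <- function(results) {
  titles <- c(
    cross_sectional = "Cross-sectional associations (amyloid -> MEG)",
    longitudinal = "Baseline amyloid vs longitudinal MEG (interaction)",
    reverse_cross_sectional = "Cross-sectional associations (MEG -> amyloid)",
    reverse_longitudinal = "Baseline MEG vs longitudinal amyloid (interaction)",
    change = "Annual change in amyloid vs annual change in MEG"
  )
  lines <- character(0)
  for (nm in names(titles)) {
    tab <- results[[nm]]
    if (is.null(tab)) next
    tab$p_used <- ifelse(is.na(tab$p_perm), tab$p, tab$p_perm)
    lines <- c(lines, .renderTable(tab, titles[[nm]], "p_used"))
  }
  if (length(results$exclusions)) {
    ex <- unique(do.call(rbind, results$exclusions))
    lines <- c(lines, "Excluded fast accumulators (annual-change models):")
    lines <- c(lines, sprintf(
      "  %s (%s, z = %.1f)", ex$participant_id, ex$variable, ex$z
    ))
  }
  lines
}
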