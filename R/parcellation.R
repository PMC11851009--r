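# AAL-90 parcellation: 45 bilateral region names in conventional atlas
# order (odd = left, even = right). Six bilateral deep grey structures are
# classed sub-cortical; the remaining 39 pairs are cortical (78 + 12 = 90).
.aal_pairs <- c(
  "Precentral", "Frontal_Sup", "Frontal_Sup_Orb", "Frontal_Mid",
  "Frontal_Mid_Orb", "Frontal_Inf_Oper", "Frontal_Inf_Tri",
  "Frontal_Inf_Orb", "Rolandic_Oper", "Supp_Motor_Area", "Olfactory",
  "Frontal_Sup_Medial", "Frontal_Med_Orb", "Rectus", "Insula",
  "Cingulum_Ant", "Cingulum_Mid", "Cingulum_Post", "Hippocampus",
  "ParaHippocampal", "Amygdala", "Calcarine", "Cuneus", "Lingual",
  "Occipital_Sup", "Occipital_Mid", "Occipital_Inf", "Fusiform",
  "Postcentral", "Parietal_Sup", "Parietal_Inf", "SupraMarginal",
  "Angular", "Precuneus", "Paracentral_Lobule", "Caudate", "Putamen",
  "Pallidum", "Thalamus", "Heschl", "Temporal_Sup", "Temporal_Pole_Sup",
  "Temporal_Mid", "Temporal_Pole_Mid", "Temporal_Inf"
)

.aal_subcortical_pairs <- c(
  "Hippocampus", "Amygdala", "Caudate", "Putamen", "Pallidum", "Thalamus"
)

#' Default 90-region source-space parcellation labels
#'
#' Region labels of the automated anatomical labelling (AAL) atlas as used
#' for whole-head source reconstruction: 78 cortical and 12 sub-cortical
#' regions, left/right interleaved.
#'
#' @param which `"all"` (default), `"cortical"` or `"subcortical"`.
#' @return Character vector of region labels (`"<name>_L"` / `"<name>_R"`).
#' @examples
#' length(aalLabels()) # 90
#' length(aalLabels("cortical")) # 78
#' @export
aalLabels <- function(which = c("all", "cortical", "subcortical")) {
  which <- match.arg(which)
  pairs <- switch(which,
    all = .aal_pairs,
    cortical = setdiff(.aal_pairs, .aal_subcortical_pairs),
    subcortical = .aal_subcortical_pairs
  )
  if (which == "all") {
    as.vector(t(outer(pairs, c("_L", "_R"), paste0)))
  } else {
    # preserve atlas order within the subset
    labs <- as.vector(t(outer(.aal_pairs, c("_L", "_R"), paste0)))
    keep <- sub("_[LR]$", "", labs) %in% pairs
    labs[keep]
  }
}

#' Region-of-interest definition
#'
#' Bundles a name with a set of member region labels. The shipped default
#' (`earlyADRoi()`) is the early Alzheimer's disease composite: bilateral
#' posterior cingulate cortex plus the orbitofrontal cortex, the regions of
#' earliest amyloid-beta deposition.
#'
#' @param name ROI name.
#' @param members character vector of member region labels.
#' @return A list with class `"ROIDefinition"` (`name`, `members`).
#' @export
roiDefinition <- function(name, members) {
  members <- as.character(members)
  if (length(members) == 0L) stop("ROI '", name, "' has no member regions")
  if (anyDuplicated(members)) stop("ROI '", name, "' has duplicate members")
  structure(list(name = name, members = members), class = "ROIDefinition")
}

#' @export
print.ROIDefinition <- function(x, ...) {
  cat(sprintf(
    "ROI '%s': %d regions (%s)\n", x$name, length(x$members),
    paste(utils::head(x$members, 4L), collapse = ", ")
  ))
  invisible(x)
}

#' Early Alzheimer's disease composite ROI
#'
#' Bilateral posterior cingulate plus orbitofrontal regions. The exact
#' orbitofrontal label subset under the 90-region parcellation is
#' configurable; the default takes all orbital-cortex labels (superior,
#' middle, inferior and medial orbital gyri plus gyrus rectus).
#'
#' @param orbitofrontal character vector of orbitofrontal region name
#'   stems (without `_L`/`_R`).
#' @return A `ROIDefinition` with 12 member labels under the default.
#' @examples
#' earlyADRoi()
#' @export
earlyADRoi <- function(orbitofrontal = c(
                         "Frontal_Sup_Orb", "Frontal_Mid_Orb",
                         "Frontal_Inf_Orb", "Frontal_Med_Orb", "Rectus"
                       )) {
  stems <- c("Cingulum_Post", orbitofrontal)
  bad <- setdiff(stems, .aal_pairs)
  if (length(bad)) {
    stop("unknown parcellation regions: ", paste(bad, collapse = ", "))
  }
  labs <- as.vector(t(outer(stems, c("_L", "_R"), paste0)))
  roiDefinition("early_ad", labs)
}
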