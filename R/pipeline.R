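#' Assemble a full pipeline run configuration
#'
#' Bundles the per-stage settings with documented defaults. Any element
#' can be overridden; unknown elements are rejected, so configs are
#' validated before any compute starts.
#'
#' @param cohort list of [cohortConfig()] overrides.
#' @param signal list of [signalConfig()] overrides.
#' @param effects list with `effect_cross`, `effect_interaction`
#'   (imposed on the theta amplitude via [attachEffects()]).
#' @param analysis list with `B` (permutations per grid cell),
#'   `directions`, `alpha_gate`, `outlier_z`.
#' @param roi an ROI definition; default [earlyADRoi()] when the region
#'   count permits, else the first quarter of the regions.
#' @param seed root seed for every stage.
#' @return List with class `"RunConfig"`.
#' @export
runConfig <- function(cohort = list(), signal = list(), effects = list(),
                      analysis = list(), roi = NULL, seed = 1L) {
  checkNames <- function(given, allowed, where) {
    bad <- setdiff(names(given), allowed)
    if (length(bad)) {
      stop(
        "unknown ", where, " setting(s): ", paste(bad, collapse = ", ")
      )
    }
  }
  checkNames(cohort, names(formals(cohortConfig)), "cohort")
  checkNames(signal, names(formals(signalConfig)), "signal")
  checkNames(effects, c("effect_cross", "effect_interaction"), "effects")
  checkNames(
    analysis, c("B", "directions", "alpha_gate", "outlier_z"), "analysis"
  )
  structure(list(
    cohort = cohort, signal = signal,
    effects = utils::modifyList(
      list(effect_cross = 0, effect_interaction = 0), effects
    ),
    analysis = utils::modifyList(
      list(
        B = 0L, directions = c("abeta_to_meg", "change"),
        alpha_gate = 0.05, outlier_z = 4
      ),
      analysis
    ),
    roi = roi, seed = as.integer(seed)
  ), class = "RunConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with any of the [runConfig()] sections.
#' @param seed optional seed overriding the file's value.
#' @return A `"RunConfig"`.
#' @export
readRunConfig <- function(path, seed = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  args <- y[intersect(
    names(y), c("cohort", "signal", "effects", "analysis")
  )]
  args$seed <- if (!is.null(seed)) seed else if (!is.null(y$seed)) y$seed
    else 1L
  do.call(runConfig, args)
}

.stableWriteTsv <- function(tab, path) {
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(x) signif(x, 10))
  utils::write.table(tab, path,
    sep = "\t", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8"
  )
}

#' Run the complete pipeline: simulate, measure, analyze, report
#'
#' Stages: (1) generate the synthetic cohort; (2) attach
#' amyloid-dependent effects and synthesize per-participant-visit source
#' recordings; (3) compute the measure table (relative band power and
#' connectivity at all analysis levels); (4) run the analysis grid;
#' (5) write result tables, a rendered report, and a JSON run manifest
#' (config hash, seeds, row counts, exclusions, output checksums).
#' Everything derives from the single root seed, so two runs from the
#' same configuration produce byte-identical outputs.
#'
#' @param config a [runConfig()] (or path to a YAML file).
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage outputs
#'   (`cohort`, `measures`, `results`, `manifest`).
#' @export
runPipeline <- function(config = runConfig(), out_dir = tempfile("run")) {
  if (is.character(config)) config <- readRunConfig(config)
  stopifnot(inherits(config, "RunConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  ccfg <- do.call(cohortConfig, utils::modifyList(
    config$cohort, list(seed = .substreamSeed(seed, "cohort-stage"))
  ))
  cohort <- generateCohort(ccfg)
  writeCohort(cohort, file.path(out_dir, "cohort.csv"))

  scfg <- do.call(signalConfig, utils::modifyList(
    config$signal, list(seed = .substreamSeed(seed, "signal-stage"))
  ))
  fx <- attachEffects(cohort, scfg,
    effect_cross = config$effects$effect_cross,
    effect_interaction = config$effects$effect_interaction
  )
  recordings <- lapply(names(fx$configs), function(key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    generateRecording(parts[1L], fx$configs[[key]], visit = parts[2L])
  })

  roi <- config$roi
  if (is.null(roi)) {
    labs <- regionLabels(recordings[[1L]])
    roi <- if (all(earlyADRoi()$members %in% labs)) {
      earlyADRoi()
    } else {
      roiDefinition("early_ad", labs[seq_len(max(1L, length(labs) %/% 4L))])
    }
  }
  measures <- buildMeasureTable(recordings, roi = roi)
  .stableWriteTsv(measures, file.path(out_dir, "measures.tsv"))

  an <- config$analysis
  results <- runGrid(measures, cohort,
    directions = an$directions, B = an$B,
    seed = .substreamSeed(seed, "analysis-stage"),
    alpha_gate = an$alpha_gate, outlier_z = an$outlier_z
  )
  table_names <- intersect(
    c(
      "cross_sectional", "longitudinal", "reverse_cross_sectional",
      "reverse_longitudinal", "change"
    ),
    names(results)
  )
  for (nm in table_names) {
    .stableWriteTsv(results[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
  }
  writeLines(renderReport(results), file.path(out_dir, "report.txt"))

  out_files <- c(
    "cohort.csv", "measures.tsv", paste0(table_names, ".tsv"), "report.txt"
  )
  checksums <- as.list(tools::md5sum(file.path(out_dir, out_files)))
  names(checksums) <- out_files
  manifest <- list(
    package_version = as.character(utils::packageVersion("megamyloid")),
    seed = seed,
    config = unclass(config[c("cohort", "signal", "effects", "analysis")]),
    n_participants = length(unique(cohort$participant_id)),
    n_recordings = length(recordings),
    n_measure_rows = nrow(measures),
    exclusions = lapply(results$exclusions, function(e) {
      list(participants = e$participant_id, z = e$z)
    }),
    checksums = checksums
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(list(
    cohort = cohort, measures = measures, results = results,
    manifest = manifest, out_dir = out_dir
  ))
}
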