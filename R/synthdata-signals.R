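#' Configuration for the synthetic source-signal generator
#'
#' Describes one participant-visit's simulated source-space recording:
#' band-limited stochastic oscillations (zero-phase filtered white noise,
#' one component per canonical band, scaled by `band_amplitudes`) plus
#' white sensor noise, with optional pairwise coupling. Defaults follow
#' the acquisition geometry the pipeline targets: 90 regions, 10 epochs
#' of 4096 samples at 312 Hz.
#'
#' Coupling modes emulate the effects the connectivity measures must
#' detect or reject:
#' \describe{
#'   \item{`shared_lagged`}{the pair shares a band-limited component
#'     inserted with a sample lag -- genuine lagged interaction, visible
#'     to phase- and entropy-based measures.}
#'   \item{`shared_zero_lag`}{the component is inserted with zero lag --
#'     pure instantaneous mixing, the signature of volume conduction /
#'     source leakage, which corrected measures must reject.}
#'   \item{`none`}{no shared component.}
#' }
#'
#' @param n_regions number of source regions.
#' @param sampling_rate sampling rate (Hz); must exceed twice the top
#'   band edge (96 Hz).
#' @param n_epochs number of epochs.
#' @param epoch_len samples per epoch (>= 64).
#' @param band_amplitudes named vector of relative band component
#'   amplitudes (standard deviations); names must be bands of `bands`.
#' @param coupling `data.frame` with columns `region_i`, `region_j`
#'   (1-based indices), `mode` (`"shared_lagged"`, `"shared_zero_lag"`,
#'   `"none"`), `strength` in `[0, 1]`, `lag` (samples), `band`.
#' @param noise_sd white-noise standard deviation.
#' @param bands band definition, see [bandSet()].
#' @param filter_order Butterworth order for band synthesis.
#' @param seed integer seed.
#' @return A list with class `"SignalConfig"`.
#' @examples
#' cfg <- signalConfig(n_regions = 4, n_epochs = 2, epoch_len = 512)
#' rec <- generateRecording("P001", cfg)
#' dim(rec@data)
#' @export
signalConfig <- function(n_regions = 90L,
                         sampling_rate = 312,
                         n_epochs = 10L,
                         epoch_len = 4096L,
                         band_amplitudes = c(
                           delta = 1.0, theta = 0.8, alpha1 = 1.2,
                           alpha2 = 1.0, beta = 0.7, gamma = 0.3
                         ),
                         coupling = NULL,
                         noise_sd = 0.5,
                         bands = bandSet(),
                         filter_order = 4L,
                         seed = 1L) {
  cfg <- list(
    n_regions = as.integer(n_regions),
    sampling_rate = sampling_rate,
    n_epochs = as.integer(n_epochs),
    epoch_len = as.integer(epoch_len),
    band_amplitudes = band_amplitudes,
    coupling = coupling,
    noise_sd = noise_sd,
    bands = bands,
    filter_order = as.integer(filter_order),
    seed = as.integer(seed)
  )
  class(cfg) <- "SignalConfig"
  validateSignalConfig(cfg)
  cfg
}

#' Validate a signal configuration
#' @param cfg a `SignalConfig`.
#' @return `cfg` invisibly; errors name the offending field.
#' @export
validateSignalConfig <- function(cfg) {
  if (cfg$epoch_len < 64L) {
    stop("invalid signal configuration: epoch_len must be >= 64")
  }
  top <- max(vapply(cfg$bands, `[`, numeric(1), 2L))
  if (cfg$sampling_rate <= 2 * top) {
    stop(
      "invalid signal configuration: sampling_rate must exceed twice the ",
      "top band edge (", 2 * top, " Hz)"
    )
  }
  unknown <- setdiff(names(cfg$band_amplitudes), names(cfg$bands))
  if (length(unknown)) {
    stop("unknown band name(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(cfg$coupling)) {
    cp <- cfg$coupling
    need <- c("region_i", "region_j", "mode", "strength", "lag", "band")
    missing_cols <- setdiff(need, names(cp))
    if (length(missing_cols)) {
      stop("coupling table lacks column(s): ",
        paste(missing_cols, collapse = ", "))
    }
    if (any(!cp$mode %in% c("shared_lagged", "shared_zero_lag", "none"))) {
      stop("unknown coupling mode")
    }
    if (any(cp$strength < 0 | cp$strength > 1)) {
      stop("coupling strengths must lie in [0, 1]")
    }
    if (any(cp$lag >= cfg$epoch_len)) {
      stop("coupling lag must be smaller than epoch_len")
    }
    if (any(!cp$band %in% names(cfg$bands))) {
      stop("unknown band name in coupling table")
    }
    if (any(cp$region_i > cfg$n_regions | cp$region_j > cfg$n_regions)) {
      stop("coupling region index exceeds n_regions")
    }
  }
  invisible(cfg)
}

# Band-limited unit-variance noise: zero-phase filtered white noise,
# rescaled to unit standard deviation.
.bandNoise <- function(n, band, fs, order) {
  x <- stats::rnorm(n)
  y <- bandpassFilter(x, band, fs, order = order)
  s <- stats::sd(y)
  if (s > 0) y / s else y
}

.circShift <- function(x, lag) {
  if (lag == 0L) return(x)
  n <- length(x)
  lag <- lag %% n
  c(x[(n - lag + 1L):n], x[seq_len(n - lag)])
}

#' Generate a synthetic source-space recording
#'
#' Each region is the sum of independent band-limited stochastic
#' oscillations (one per band in `band_amplitudes`, zero-phase filtered
#' white noise scaled to the configured amplitude) plus white noise.
#' For coupled pairs the own band component is partially replaced by a
#' shared component: with coupling strength `s`, the coupled band becomes
#' `sqrt(1 - s^2) * own + s * shared`, preserving band variance, with the
#' shared part inserted lagged (`shared_lagged`, circular shift by `lag`
#' samples) or at zero lag (`shared_zero_lag`, instantaneous mixing as
#' produced by volume conduction). Deterministic for a fixed seed.
#'
#' @param participant_id identifier stored in the recording.
#' @param cfg a [signalConfig()] object.
#' @param visit `"baseline"` or `"followup"`.
#' @return A [SourceRecording-class] object.
#' @export
generateRecording <- function(participant_id, cfg, visit = "baseline") {
  validateSignalConfig(cfg)
  nr <- cfg$n_regions
  ne <- cfg$n_epochs
  len <- cfg$epoch_len
  fs <- cfg$sampling_rate
  amps <- cfg$band_amplitudes
  bnames <- names(amps)
  cp <- cfg$coupling
  seed <- .substreamSeed(cfg$seed, paste0("signals:", participant_id, visit))
  dat <- .withSeed(seed, {
    arr <- array(0, dim = c(ne, nr, len))
    for (e in seq_len(ne)) {
      sig <- matrix(stats::rnorm(nr * len, sd = cfg$noise_sd),
        nrow = nr, ncol = len
      )
      # own components, kept so coupling can partially replace them
      own <- vector("list", length(bnames))
      names(own) <- bnames
      for (b in bnames) {
        comp <- matrix(0, nrow = nr, ncol = len)
        for (r in seq_len(nr)) {
          comp[r, ] <- .bandNoise(len, cfg$bands[[b]], fs, cfg$filter_order)
        }
        own[[b]] <- comp
      }
      if (!is.null(cp) && nrow(cp)) {
        for (k in seq_len(nrow(cp))) {
          if (cp$mode[k] == "none" || cp$strength[k] == 0) next
          b <- cp$band[k]
          if (!b %in% bnames) next
          s <- cp$strength[k]
          shared <- .bandNoise(len, cfg$bands[[b]], fs, cfg$filter_order)
          i <- cp$region_i[k]
          j <- cp$region_j[k]
          w <- sqrt(1 - s^2)
          own[[b]][i, ] <- w * own[[b]][i, ] + s * shared
          shifted <- if (cp$mode[k] == "shared_lagged") {
            .circShift(shared, as.integer(cp$lag[k]))
          } else {
            shared
          }
          own[[b]][j, ] <- w * own[[b]][j, ] + s * shifted
        }
      }
      for (b in bnames) sig <- sig + amps[[b]] * own[[b]]
      arr[e, , ] <- sig
    }
    arr
  })
  sourceRecording(dat,
    sampling_rate = fs,
    participant_id = participant_id, visit = visit
  )
}
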