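#' Configure a synthetic spiking raster with planted circuits
#'
#' Describes a binary spike raster (trials x bins x neurons, spike/no
#' spike per coarse time bin) in which designated driver groups influence
#' designated target neurons through known circuit functions, providing
#' ground truth for the multiplet search. Non-circuit neurons fire i.i.d.
#' at the baseline rate.
#'
#' Circuit types:
#' \describe{
#'   \item{`xor_parity`}{the target's next-bin firing odds are tilted by
#'     the parity of the drivers' current bins — a purely higher-order
#'     (synergistic) influence.}
#'   \item{`majority`}{tilt by the drivers' majority vote.}
#'   \item{`redundant_broadcast`}{drivers all reflect a shared latent
#'     binary source, and the target follows the same source one bin
#'     later — every driver carries the same information (redundant).}
#' }
#' The tilt acts multiplicatively on the firing odds: a coupling `c` in
#' `[0, 1]` multiplies the odds by `exp(±4c)` depending on the circuit
#' function's output, and the resulting probability is clipped to
#' `[0.01, 0.99]`. Coupling 0 leaves the raster fully i.i.d.
#'
#' @param n_neurons Number of neurons (raster columns).
#' @param n_trials,trial_length Trial structure, in trials and bins.
#' @param baseline_rate Spike probability per bin for unforced bins
#'   (default 0.3, typical of cortical rates at 100 ms binning).
#' @param circuits List of planted circuits, each a list with elements
#'   `drivers` (neuron indices), `target` (a single neuron index, not
#'   among the drivers, unique across circuits), `type`, and `coupling`.
#' @param class_labels Optional per-neuron labels (e.g. `"H"`, `"M"`,
#'   `"L"` for decision-information classes); metadata only.
#' @param seed Optional integer seed.
#' @return An object of class `synthetic_spiking_config`.
#' @export
synthetic_spiking_config <- function(n_neurons, n_trials, trial_length,
                                     baseline_rate = 0.3,
                                     circuits = list(),
                                     class_labels = NULL,
                                     seed = NULL) {
  n_neurons <- as.integer(n_neurons)
  if (baseline_rate <= 0 || baseline_rate >= 1) {
    stop("`baseline_rate` must be a probability in (0, 1)")
  }
  targets <- integer(0)
  for (ci in circuits) {
    stopifnot(is.list(ci), all(c("drivers", "target", "type", "coupling") %in% names(ci)))
    if (!ci$type %in% c("xor_parity", "majority", "redundant_broadcast")) {
      stop(sprintf("unknown circuit type '%s'", ci$type))
    }
    if (ci$coupling < 0 || ci$coupling > 1) {
      stop("circuit coupling must lie in [0, 1]")
    }
    if (ci$target %in% ci$drivers) {
      stop("a circuit's target must be disjoint from its drivers")
    }
    if (any(c(ci$drivers, ci$target) > n_neurons)) {
      stop("circuit neuron index out of range")
    }
    if (ci$target %in% targets) {
      stop("overlapping targets across circuits: ground truth would be ambiguous")
    }
    targets <- c(targets, ci$target)
  }
  if (!is.null(class_labels) && length(class_labels) != n_neurons) {
    stop("`class_labels` must have one label per neuron")
  }
  structure(list(n_neurons = n_neurons,
                 n_trials = as.integer(n_trials),
                 trial_length = as.integer(trial_length),
                 baseline_rate = baseline_rate,
                 circuits = circuits,
                 class_labels = class_labels,
                 seed = seed),
            class = "synthetic_spiking_config")
}

.odds_tilt <- function(base, f, coupling) {
  p <- stats::plogis(stats::qlogis(base) + 4 * coupling * (2 * f - 1))
  pmin(pmax(p, 0.01), 0.99)
}

#' Generate a synthetic spiking raster with planted circuits
#'
#' @param config A [synthetic_spiking_config()].
#' @return A list with `series` (an [multivariate_series()] with trial
#'   bounds; binary 0/1 raster) and `manifest`, a ground-truth record of
#'   the planted circuits (serializable to JSON via
#'   [jsonlite::toJSON()]).
#' @examples
#' cfg <- synthetic_spiking_config(6, n_trials = 4, trial_length = 50,
#'   circuits = list(list(drivers = 1:3, target = 4,
#'                        type = "xor_parity", coupling = 0.5)),
#'   seed = 1)
#' r <- generate_spiking(cfg)
#' dim(r$series)
#' @export
generate_spiking <- function(config) {
  stopifnot(inherits(config, "synthetic_spiking_config"))
  .seeded(config$seed, {
    nt <- config$n_trials
    L <- config$trial_length
    total <- nt * L
    base <- config$baseline_rate
    raster <- matrix(stats::rbinom(total * config$n_neurons, 1, base),
                     nrow = total, ncol = config$n_neurons)
    starts <- seq.int(1L, total, by = L)

    for (ci in config$circuits) {
      if (ci$type == "redundant_broadcast") {
        latent <- stats::rbinom(total, 1, 0.5)
        for (d in ci$drivers) {
          raster[, d] <- stats::rbinom(total, 1,
                                       .odds_tilt(base, latent, ci$coupling))
        }
        for (s in starts) {
          t_now <- s:(s + L - 2L)
          raster[t_now + 1L, ci$target] <-
            stats::rbinom(L - 1L, 1, .odds_tilt(base, latent[t_now], ci$coupling))
        }
      } else {
        f_fun <- if (ci$type == "xor_parity") {
          function(drv) rowSums(drv) %% 2
        } else {
          function(drv) as.numeric(rowSums(drv) > length(ci$drivers) / 2)
        }
        for (s in starts) {
          t_now <- s:(s + L - 2L)
          f <- f_fun(raster[t_now, ci$drivers, drop = FALSE])
          raster[t_now + 1L, ci$target] <-
            stats::rbinom(L - 1L, 1, .odds_tilt(base, f, ci$coupling))
        }
      }
    }

    labels <- config$class_labels
    manifest <- list(
      n_neurons = config$n_neurons,
      n_trials = nt,
      trial_length = L,
      baseline_rate = base,
      seed = config$seed,
      class_labels = labels,
      circuits = lapply(config$circuits, function(ci) {
        list(drivers = as.integer(ci$drivers), target = as.integer(ci$target),
             type = ci$type, coupling = ci$coupling)
      })
    )
    series <- multivariate_series(
      raster,
      names = sprintf("n%02d", seq_len(config$n_neurons)),
      trial_bounds = starts)
    list(series = series, manifest = manifest)
  })
}

#' Write a generated raster, its trial bounds, and its manifest
#'
#' @param generated A [generate_spiking()] result.
#' @param raster_file Output path for the tab-separated raster.
#' @param trial_file Output path for the 0-based trial-boundary file.
#' @param manifest_file Output path for the ground-truth manifest (JSON).
#' @return `raster_file`, invisibly.
#' @export
write_spiking <- function(generated, raster_file, trial_file, manifest_file) {
  write_series(generated$series, raster_file, trial_file)
  jsonlite::write_json(generated$manifest, manifest_file,
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(raster_file)
}
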