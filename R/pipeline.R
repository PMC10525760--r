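#' Default pipeline configuration
#'
#' All tunables of the classifier with their standard values: 30 s epochs
#' of five 6 s subsections, evaluation at 10 Hz with 2 Hz half-bandwidth,
#' DPSS concentration threshold 0.98, cluster-count sweep 2..14. Values
#' supplied in `...` or via a YAML file override the defaults (flags beat
#' file beats defaults).
#'
#' @param config_file optional YAML file of overrides.
#' @param ... named overrides applied last.
#' @return named list of parameters.
#' @export
pipeline_config <- function(config_file = NULL, ...) {
  cfg <- list(
    channels = NULL,          # include-list of channel labels
    sample_rate = NULL,       # override the file's rate if set
    f = 10, W = 2,
    epoch_s = 30, subsection_s = 6, n_subsections = 5,
    energy_threshold = 0.98, n_tapers = NULL,
    notch_base = 60, notch_half_width = 1, apply_notch = TRUE,
    k_min = 2, k_max = 14, max_iter = 500,
    density_variant = "standard",   # or "as_printed"
    aic_sum_over = "assigned",      # or "all"
    split_fraction = 0.5, n_reps = 50,
    seed = 1
  )
  if (!is.null(config_file)) {
    file_cfg <- yaml::read_yaml(config_file)
    cfg[names(file_cfg)] <- file_cfg
  }
  dots <- list(...)
  dots <- dots[!vapply(dots, is.null, logical(1))]
  cfg[names(dots)] <- dots
  cfg
}

#' Classify a night of iEEG from an EDF file
#'
#' The full pipeline: EDF input, optional channel selection, zero-phase
#' power-line notch, 30 s epoching with per-subsection centering, DPSS
#' eigencoefficient features at 10 Hz, likelihood K-means with the AIC
#' cluster-count sweep, and REM-cluster identification. If a hypnogram is
#' supplied the decision is also scored against it.
#'
#' @param edf_paths one or more EDF files of a single night.
#' @param hypnogram_path optional plain-text hypnogram for scoring.
#' @param config a [pipeline_config()].
#' @return as [classify_features()], plus `truth`, `basis` and `n_epochs`.
#' @export
classify_edf <- function(edf_paths, hypnogram_path = NULL,
                         config = pipeline_config()) {
  fx <- extract_features_edf(edf_paths, config)
  truth <- if (!is.null(hypnogram_path)) {
    labs <- read_hypnogram(hypnogram_path)
    if (length(labs) < fx$n_epochs)
      stop_invalid("hypnogram shorter than the recording",
                   "invalid_parameter")
    labs[seq_len(fx$n_epochs)]
  } else NULL
  res <- classify_features(fx$features, truth = truth,
                           k_min = config$k_min, k_max = config$k_max,
                           seed = config$seed, max_iter = config$max_iter,
                           variant = config$density_variant,
                           sum_over = config$aic_sum_over)
  res$truth <- truth
  res$basis <- fx$basis
  res$n_epochs <- fx$n_epochs
  res
}

#' Eigencoefficient features straight from EDF files
#'
#' The preprocessing and spectral half of the pipeline: EDF input, channel
#' selection, optional notch, epoching, DPSS basis, feature matrices.
#'
#' @inheritParams classify_edf
#' @return list with `features`, `basis`, `n_epochs`, `contact_ids`.
#' @export
extract_features_edf <- function(edf_paths, config = pipeline_config()) {
  raw <- read_edf(edf_paths, channels = config$channels)
  if (!is.null(config$sample_rate))
    raw$sample_period <- 1 / config$sample_rate
  if (isTRUE(config$apply_notch)) {
    if (config$notch_base < 1 / (2 * raw$sample_period)) {
      raw <- notch_filter(raw, config$notch_base, config$notch_half_width)
    } else {
      warning("line frequency at or above Nyquist; notch filter skipped")
    }
  }
  ep <- segment(raw, config$epoch_s,
                n_subsections = config$n_subsections)
  basis <- make_dpss(ep$N, nw = config$subsection_s * config$W,
                     energy_threshold = config$energy_threshold,
                     delta = ep$delta, n_tapers = config$n_tapers)
  list(features = build_feature_set(ep, basis, f = config$f),
       basis = basis, n_epochs = ep$n_epochs,
       contact_ids = ep$contact_ids)
}

#' Export a classification result
#'
#' Writes the JSON report (chosen cluster count, AIC trace, REM cluster,
#' reliability flag, spectral ranks, figures of merit, REM epochs, and the
#' performance metrics when truth was available) and a per-epoch CSV
#' (`epoch_index`, `cluster`, `is_rem`).
#'
#' @param result value of [classify_features()] or [classify_edf()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
export_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sel <- result$selection
  dec <- result$decision
  labels <- sel$labelings[[as.character(sel$chosen_k)]]$labels
  report <- list(
    chosen_k = sel$chosen_k,
    aic_by_k = as.list(sel$aic_by_k),
    rem_cluster = dec$rem_cluster,
    reliable = dec$reliable,
    spectral_ranks = dec$spectral_ranks,
    fom1 = dec$fom1,
    fom2 = dec$fom2,
    rem_epochs = dec$rem_epochs
  )
  if (!is.null(result$report)) report$metrics <- as.list(result$report)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  csv_path <- file.path(dir, "epochs.csv")
  write.csv(data.frame(epoch_index = seq_along(labels), cluster = labels,
                       is_rem = labels == dec$rem_cluster),
            csv_path, row.names = FALSE)
  invisible(c(json = json_path, csv = csv_path))
}
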