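#' Configuration for the synthetic night generator
#'
#' Describes a multichannel iEEG-like night with a known hypnogram and a
#' stage-dependent alpha rhythm: during wakefulness the 8-12 Hz component
#' is strong, during REM it is weak, with NREM-like stages in between.
#' Each contact records the sum of a narrowband alpha process (a mixture
#' of one night-wide component shared across contacts and an independent
#' per-contact component, mixed by `contact_coupling`) scaled per epoch by
#' the stage's alpha amplitude, plus first-order autoregressive broadband
#' background noise independent across contacts.
#'
#' @param n_contacts number of electrode contacts (default 12).
#' @param sample_rate sampling rate in Hz (default 200; the alpha band
#'   sits far below Nyquist at any clinical rate, so the default favours a
#'   rate that keeps simulations light -- the generator accepts 2000 Hz
#'   for full-rate runs).
#' @param stage_sequence character vector of per-epoch stage labels. The
#'   default is a plausible 100-epoch night: wake at lights-off and
#'   lights-on, two REM periods mid-night, NREM elsewhere.
#' @param alpha_amp named per-stage alpha amplitudes in microvolts. The
#'   default `c(W = 4, N2 = 2, N3 = 2, REM = 1)` encodes the 4:1
#'   Wake-to-REM alpha contrast with NREM intermediate.
#' @param alpha_freq alpha centre frequency in Hz.
#' @param alpha_halfwidth half-width of the alpha band in Hz.
#' @param background list with `ar` (AR(1) pole, default 0.95) and `sd`
#'   (standard deviation in microvolts, default 5).
#' @param contact_coupling correlation share of the alpha component common
#'   to all contacts, in `[0, 1)`.
#' @param seed integer seed; the night is bit-reproducible given the seed.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_contacts = 12, sample_rate = 200,
                         stage_sequence = NULL,
                         alpha_amp = c(W = 4, N2 = 2, N3 = 2, REM = 1),
                         alpha_freq = 10, alpha_halfwidth = 2,
                         background = list(ar = 0.95, sd = 5),
                         contact_coupling = 0.5, seed = 1) {
  if (is.null(stage_sequence))
    stage_sequence <- rep(c("W", "N2", "N3", "N2", "REM", "N2", "REM", "W"),
                          times = c(8, 20, 10, 10, 12, 15, 13, 12))
  if (n_contacts < 1)
    stop_invalid("need at least one contact", "invalid_parameter")
  if (any(alpha_amp < 0))
    stop_invalid("alpha amplitudes must be non-negative", "invalid_parameter")
  if (contact_coupling < 0 || contact_coupling >= 1)
    stop_invalid("contact_coupling must lie in [0, 1)", "invalid_parameter")
  missing <- setdiff(unique(stage_sequence), names(alpha_amp))
  if (length(missing))
    stop_invalid(paste("no alpha amplitude for stage:",
                       paste(missing, collapse = ", ")),
                 "invalid_parameter")
  structure(list(n_contacts = n_contacts, sample_rate = sample_rate,
                 stage_sequence = stage_sequence, alpha_amp = alpha_amp,
                 alpha_freq = alpha_freq, alpha_halfwidth = alpha_halfwidth,
                 background = background,
                 contact_coupling = contact_coupling, seed = seed),
            class = "synth_config")
}

# unit-variance narrowband noise in (f0-hw, f0+hw)
narrowband <- function(n, f0, hw, fs) {
  b <- signal::butter(4, c(f0 - hw, f0 + hw) / (fs / 2), type = "pass")
  x <- signal::filtfilt(b, rnorm(n))
  x / sd(x)
}

#' Generate a synthetic night
#'
#' @param config a [synth_config()].
#' @param epoch_s epoch duration in seconds (default 30).
#' @return list with `recording` (a [raw_recording()]) and `truth`
#'   (character stage labels, one per epoch).
#' @export
generate_night <- function(config, epoch_s = 30) {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$sample_rate
  spe <- round(epoch_s * fs)
  n_epochs <- length(config$stage_sequence)
  n <- n_epochs * spe
  amp <- rep(config$alpha_amp[config$stage_sequence], each = spe)
  cpl <- config$contact_coupling
  with_seed(config$seed, {
    common <- narrowband(n, config$alpha_freq, config$alpha_halfwidth, fs)
    X <- matrix(0, n, config$n_contacts)
    for (cc in seq_len(config$n_contacts)) {
      own <- narrowband(n, config$alpha_freq, config$alpha_halfwidth, fs)
      alpha <- sqrt(cpl) * common + sqrt(1 - cpl) * own
      bg <- as.numeric(stats::filter(rnorm(n), config$background$ar,
                                     method = "recursive"))
      bg <- bg / sd(bg) * config$background$sd
      X[, cc] <- amp * alpha + bg
    }
    list(recording = raw_recording(X, 1 / fs),
         truth = config$stage_sequence)
  })
}

#' Generate per-epoch feature matrices with a known hypnogram
#'
#' Two modes. `"signal"` composes the full pipeline on a generated night:
#' [generate_night()], optional notch filtering, [segment()], a DPSS basis
#' at the standard parameters (6 s subsections, 2 Hz half-bandwidth, 0.98
#' concentration threshold), and [build_feature_set()]. `"features"` skips
#' the signal path and draws the complex feature-matrix columns directly
#' from per-stage Gaussians -- the exact sampling model the clustering
#' module assumes -- which is the right fixture for oracle tests of the
#' cluster module.
#'
#' @param config a [synth_config()] (signal mode) or a list for feature
#'   mode with `stage_sequence`, `n_contacts`, `Nr`, `means` (complex
#'   `n_contacts x n_stages` matrix, columns named by stage), `sd`
#'   (per-column real/imaginary noise standard deviation, scalar or named
#'   per stage) and `seed`.
#' @param mode `"signal"` or `"features"`.
#' @param apply_notch run the power-line notch in signal mode (default
#'   `FALSE`: the generator plants no line interference).
#' @param f evaluation frequency (signal mode), default 10 Hz.
#' @param W spectral half-bandwidth in Hz (signal mode), default 2.
#' @param subsection_s,n_subsections epoch subdivision (signal mode).
#' @param energy_threshold DPSS concentration cutoff (signal mode).
#' @return list with `features` (list of `eigen_features`), `truth`
#'   (stage labels), and in signal mode `basis` and `recording`.
#' @export
generate_feature_set <- function(config, mode = c("signal", "features"),
                                 apply_notch = FALSE, f = 10, W = 2,
                                 subsection_s = 6, n_subsections = 5,
                                 energy_threshold = 0.98) {
  mode <- match.arg(mode)
  if (mode == "signal") {
    night <- generate_night(config,
                            epoch_s = subsection_s * n_subsections)
    rec <- night$recording
    if (apply_notch) rec <- notch_filter(rec)
    ep <- segment(rec, epoch_s = subsection_s * n_subsections,
                  n_subsections = n_subsections)
    basis <- make_dpss(ep$N, nw = subsection_s * W,
                       energy_threshold = energy_threshold,
                       delta = ep$delta)
    list(features = build_feature_set(ep, basis, f = f),
         truth = night$truth, basis = basis, recording = night$recording)
  } else {
    stages <- config$stage_sequence
    means <- config$means
    Nc <- config$n_contacts
    Nr <- config$Nr
    sdv <- config$sd
    if (length(sdv) == 1 && is.null(names(sdv)))
      sdv <- stats::setNames(rep(sdv, ncol(means)), colnames(means))
    with_seed(config$seed, {
      features <- lapply(seq_along(stages), function(e) {
        st <- stages[e]
        mu <- means[, st]
        s <- sdv[[st]]
        Y <- matrix(complex(real = rnorm(Nc * Nr, 0, s),
                            imaginary = rnorm(Nc * Nr, 0, s)),
                    Nc, Nr) + mu
        structure(list(Y = Y, f = NA_real_, epoch_index = e,
                       column_map = data.frame(q = seq_len(Nr),
                                               m = NA_integer_,
                                               k = NA_integer_)),
                  class = "eigen_features")
      })
      list(features = features, truth = stages)
    })
  }
}

#' Deterministic well-separated feature-space configuration
#'
#' Builds a feature-mode configuration for [generate_feature_set()] whose
#' per-stage mean vectors are pairwise at least `separation` noise
#' standard deviations apart (axis-aligned placement, alternating real and
#' imaginary axes when stages outnumber contacts).
#'
#' @param stage_sequence per-epoch stage labels.
#' @param n_contacts feature-matrix rows.
#' @param Nr feature-matrix columns.
#' @param separation pairwise mean distance in units of the column noise
#'   standard deviation.
#' @param sd column noise standard deviation (real and imaginary parts).
#' @param seed integer seed.
#' @return list usable as `config` with `mode = "features"`.
#' @export
planted_feature_config <- function(stage_sequence, n_contacts = 3, Nr = 10,
                                   separation = 8, sd = 1, seed = 1) {
  stages <- unique(stage_sequence)
  means <- matrix(0i, n_contacts, length(stages),
                  dimnames = list(NULL, stages))
  for (j in seq_along(stages)) {
    axis <- (j - 1) %% n_contacts + 1
    phase <- 1i^((j - 1) %/% n_contacts)
    means[axis, j] <- separation * sd * phase
  }
  list(stage_sequence = stage_sequence, n_contacts = n_contacts, Nr = Nr,
       means = means, sd = sd, seed = seed)
}

#' Feature-space configuration with planted alpha-power ordering
#'
#' Like [planted_feature_config()] but the per-stage mean vectors are
#' `amps[stage] * sd` on every contact, so the expected per-contact power
#' reproduces a chosen alpha-amplitude ordering (e.g. Wake high, REM
#' lowest on every contact) -- the geometry the REM-identification stage
#' assumes. Stages separated by `d` amplitude units sit
#' `d * sqrt(n_contacts)` noise standard deviations apart.
#'
#' @param stage_sequence per-epoch stage labels.
#' @param n_contacts feature-matrix rows.
#' @param Nr feature-matrix columns.
#' @param amps named per-stage mean amplitude in noise-sd units; the REM
#'   entry should be the smallest.
#' @param sd column noise standard deviation.
#' @param seed integer seed.
#' @return list usable as `config` with `mode = "features"`.
#' @export
planted_alpha_config <- function(stage_sequence, n_contacts = 12, Nr = 110,
                                 amps = c(W = 6, N2 = 3, REM = 0), sd = 1,
                                 seed = 1) {
  stages <- unique(stage_sequence)
  missing <- setdiff(stages, names(amps))
  if (length(missing))
    stop_invalid(paste("no amplitude for stage:",
                       paste(missing, collapse = ", ")),
                 "invalid_parameter")
  means <- outer(rep(1 + 0i, n_contacts), amps[stages] * sd)
  colnames(means) <- stages
  list(stage_sequence = stage_sequence, n_contacts = n_contacts, Nr = Nr,
       means = means, sd = sd, seed = seed)
}
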