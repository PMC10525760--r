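#' Construct a raw multichannel recording
#'
#' Container for a multichannel iEEG segment: a samples-by-contacts matrix
#' of electric potential (microvolts), a common sample period, and contact
#' labels.
#'
#' @param samples numeric matrix, one column per contact (a vector is
#'   treated as a single contact).
#' @param sample_period sample period \eqn{\Delta} in seconds.
#' @param contact_ids character labels, unique, one per column.
#' @param start_time optional POSIXct start time.
#' @return object of class `raw_recording`.
#' @export
raw_recording <- function(samples, sample_period,
                          contact_ids = NULL, start_time = NULL) {
  samples <- as.matrix(samples)
  if (!is.numeric(sample_period) || sample_period <= 0)
    stop_invalid("sample_period must be positive", "invalid_parameter")
  if (is.null(contact_ids))
    contact_ids <- paste0("ch", seq_len(ncol(samples)))
  if (anyDuplicated(contact_ids) || length(contact_ids) != ncol(samples))
    stop_invalid("contact_ids must be unique, one per channel",
                 "invalid_parameter")
  colnames(samples) <- contact_ids
  structure(list(samples = samples, sample_period = sample_period,
                 contact_ids = contact_ids, start_time = start_time),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("raw_recording: %d contacts, %d samples at %g Hz (%.1f s)\n",
              ncol(x$samples), nrow(x$samples), 1 / x$sample_period,
              nrow(x$samples) * x$sample_period))
  invisible(x)
}

#' Zero-phase FIR power-line notch filter
#'
#' Suppresses the power-line fundamental and every harmonic below Nyquist
#' with a single linear-phase multiband FIR band-stop kernel (Hamming
#' windowed, designed with [signal::fir1()]), applied by FFT convolution
#' with the group delay removed, so the net filter has exactly zero phase.
#' Edges are handled by signal reflection.
#'
#' The stopbands are `base_freq*h` with `h = 1, 2, ...` while
#' `base_freq*h + notch_half_width` stays below Nyquist. The kernel length
#' scales with the sample rate so the transition width is fixed in Hz;
#' attenuation inside each notch is below -40 dB while the 10 Hz analysis
#' band is left untouched to well under 0.1 dB.
#'
#' @param raw a `raw_recording`.
#' @param base_freq power-line fundamental in Hz (default 60).
#' @param notch_half_width half-width of each stopband in Hz (default 1).
#' @return filtered `raw_recording` of identical shape.
#' @export
notch_filter <- function(raw, base_freq = 60, notch_half_width = 1) {
  stopifnot(inherits(raw, "raw_recording"))
  fs <- 1 / raw$sample_period
  nyq <- fs / 2
  if (base_freq >= nyq)
    stop_invalid("base_freq must be below the Nyquist frequency",
                 "invalid_parameter")
  harmonics <- base_freq * seq_len(floor((nyq - notch_half_width) /
                                           base_freq))
  harmonics <- harmonics[harmonics - notch_half_width > 0]
  if (length(harmonics) == 0) return(raw)
  edges <- sort(as.vector(rbind(harmonics - notch_half_width,
                                harmonics + notch_half_width))) / nyq
  ntaps <- 2 * ceiling(2 * fs / notch_half_width)  # even -> odd length
  b <- signal::fir1(ntaps, edges, "DC-1")
  half <- (length(b) - 1) / 2
  n <- nrow(raw$samples)
  if (n <= half)
    stop_invalid("recording shorter than the filter kernel", "empty_data")
  out <- raw$samples
  for (cc in seq_len(ncol(out))) {
    x <- out[, cc]
    # reflect at both ends, convolve, drop the group delay
    pad <- c(2 * x[1] - x[(half + 1):2], x, 2 * x[n] - x[(n - 1):(n - half)])
    y <- fft_convolve(pad, b)
    out[, cc] <- y[(2 * half + 1):(2 * half + n)]
  }
  raw$samples <- out
  raw
}

# linear convolution by FFT, returns length(x) + length(b) - 1 values,
# here trimmed by the caller
fft_convolve <- function(x, b) {
  n <- length(x) + length(b) - 1L
  nfft <- stats::nextn(n, 2)
  Re(fft(fft(c(x, rep(0, nfft - length(x)))) *
           fft(c(b, rep(0, nfft - length(b)))), inverse = TRUE))[1:n] / nfft
}

#' Partition a recording into centered 30 s epochs of 6 s subsections
#'
#' Cuts the recording into non-overlapping epochs of `epoch_s` seconds
#' (a trailing partial epoch is discarded), divides each epoch into
#' `n_subsections` equal non-overlapping subsections that tile it exactly,
#' and subtracts each subsection's own sample mean (the "centered sample"
#' entering the eigencoefficient transform).
#'
#' @param raw a `raw_recording`.
#' @param epoch_s epoch duration in seconds (default 30, the sleep-scoring
#'   unit).
#' @param n_subsections subsections per epoch (default 5, i.e. 6 s each).
#' @return object of class `epoched_data`: list with 4-d array `d` indexed
#'   `[sample, subsection, epoch, contact]`, plus `N` (samples per
#'   subsection), `delta`, `n_epochs`, `n_contacts`, `n_subsections`,
#'   `epoch_s`, `subsection_s`, `contact_ids`, and `means` (the removed
#'   per-subsection means, same layout minus the sample axis).
#' @export
segment <- function(raw, epoch_s = 30, n_subsections = 5) {
  stopifnot(inherits(raw, "raw_recording"))
  delta <- raw$sample_period
  spe <- round(epoch_s / delta)          # samples per epoch
  if (spe %% n_subsections != 0)
    stop_invalid("epoch length not divisible into equal subsections",
                 "invalid_parameter")
  n_total <- nrow(raw$samples)
  n_epochs <- n_total %/% spe
  if (n_epochs < 1)
    stop_invalid("recording shorter than one epoch", "empty_data")
  N <- spe %/% n_subsections
  Nc <- ncol(raw$samples)
  d <- array(raw$samples[seq_len(n_epochs * spe), , drop = FALSE],
             dim = c(N, n_subsections, n_epochs, Nc))
  mu <- apply(d, c(2, 3, 4), mean)
  d <- d - rep(mu, each = N)
  structure(list(
    d = d, means = mu, N = as.integer(N), delta = delta,
    n_epochs = as.integer(n_epochs), n_contacts = as.integer(Nc),
    n_subsections = as.integer(n_subsections),
    epoch_s = epoch_s, subsection_s = epoch_s / n_subsections,
    contact_ids = raw$contact_ids
  ), class = "epoched_data")
}

#' @export
print.epoched_data <- function(x, ...) {
  cat(sprintf(
    "epoched_data: %d epochs of %g s (%d x %g s subsections), %d contacts\n",
    x$n_epochs, x$epoch_s, x$n_subsections, x$subsection_s, x$n_contacts))
  invisible(x)
}

#' Read / write plain-text hypnograms
#'
#' One sleep-stage label per line, one line per 30 s epoch, alphabet
#' `W, N1, N2, N3, REM, U` (`U` = unscored).
#'
#' @param path file path.
#' @return `read_hypnogram`: character vector of stage labels.
#' @export
read_hypnogram <- function(path) {
  labs <- trimws(readLines(path, warn = FALSE))
  labs <- labs[nzchar(labs)]
  bad <- setdiff(unique(labs), c("W", "N1", "N2", "N3", "REM", "U"))
  if (length(bad))
    stop_invalid(paste("unknown stage labels:", paste(bad, collapse = ", ")),
                 "invalid_parameter")
  labs
}

#' @rdname read_hypnogram
#' @param labels character vector of stage labels.
#' @export
write_hypnogram <- function(labels, path) {
  writeLines(as.character(labels), path)
  invisible(path)
}
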