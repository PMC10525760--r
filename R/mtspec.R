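#' Discrete prolate spheroidal (Slepian) taper basis
#'
#' Computes the DPSS tapers of length `N` for dimensionless time-bandwidth
#' product `nw` together with their spectral concentrations, and keeps the
#' tapers whose concentration exceeds `energy_threshold`.
#'
#' The tapers solve Slepian's concentration problem: the order-0 sequence
#' maximises, among all unit-energy length-`N` sequences, the fraction of
#' spectral energy falling in the band (-W, W); each subsequent order is
#' maximally concentrated subject to orthogonality with the lower orders.
#' They are obtained as eigenvectors of the commuting symmetric tridiagonal
#' matrix; the concentrations \eqn{\lambda_k \in (0,1)} are then evaluated
#' exactly as the quadratic form of each taper with the band-limiting sinc
#' kernel (computed by FFT), not taken from the tridiagonal eigenvalues,
#' which are on a different scale.
#'
#' Roughly `2*nw` tapers have concentration near 1; beyond that the
#' concentrations collapse rapidly towards 0. Only `max_tapers` candidate
#' tapers are computed (default `ceiling(2*nw) + 8`, ample for any
#' threshold that is numerically meaningful).
#'
#' @param N subsection length in samples (at least 2).
#' @param nw dimensionless time-bandwidth product \eqn{N W \Delta}, in
#'   (0, N/2). For a 6 s subsection with 2 Hz half-bandwidth, `nw = 12`
#'   regardless of sample rate.
#' @param energy_threshold keep tapers with concentration strictly above
#'   this value (default 0.98). Ignored when `n_tapers` is given.
#' @param delta sample period in seconds; only stored for bookkeeping
#'   (lets the basis report `W = nw / (N * delta)` in Hz).
#' @param n_tapers optional fixed taper count, overriding the threshold
#'   rule. Published multitaper analyses frequently use the convention
#'   `K = 2*nw - 2`; pass that here to reproduce such feature dimensions
#'   exactly (the threshold rule and the convention can disagree by one
#'   taper because the last concentration may sit within a few 1e-4 of a
#'   round threshold).
#' @param max_tapers number of candidate tapers to compute before
#'   thresholding.
#'
#' @return An object of class `dpss_basis`: list with `tapers` (an
#'   `N x K` matrix, one unit-norm taper per column, decreasing
#'   concentration order), `concentrations`, `N`, `nw`, `K`, `W`, `delta`,
#'   `energy_threshold`.
#' @export
#' @examples
#' b <- make_dpss(256, nw = 4)
#' b$K
#' zapsmall(crossprod(b$tapers))[1:3, 1:3]
make_dpss <- function(N, nw, energy_threshold = 0.98, delta = NULL,
                      n_tapers = NULL, max_tapers = NULL) {
  if (N < 2) stop_invalid("N must be at least 2", "invalid_parameter")
  if (nw <= 0 || nw >= N / 2)
    stop_invalid("time-bandwidth product must lie in (0, N/2)",
                 "invalid_parameter")
  if (is.null(n_tapers) &&
      (energy_threshold < 0 || energy_threshold >= 1))
    stop_invalid("energy_threshold must lie in [0, 1)", "invalid_parameter")
  if (is.null(max_tapers)) max_tapers <- ceiling(2 * nw) + 8
  nev <- min(N, max(max_tapers, if (is.null(n_tapers)) 1L else n_tapers))
  tapers <- .dpss_tapers(as.integer(N), as.numeric(nw), as.integer(nev))
  lambda <- dpss_concentrations(tapers, nw / N)
  if (is.null(n_tapers)) {
    K <- sum(lambda > energy_threshold)
    if (K == 0)
      stop_invalid("no taper exceeds the concentration threshold",
                   "empty_basis")
  } else {
    if (n_tapers < 1 || n_tapers > nev)
      stop_invalid("n_tapers out of range", "invalid_parameter")
    K <- as.integer(n_tapers)
  }
  structure(list(
    tapers = tapers[, seq_len(K), drop = FALSE],
    concentrations = lambda[seq_len(K)],
    N = as.integer(N), nw = nw, K = as.integer(K),
    W = if (is.null(delta)) NA_real_ else nw / (N * delta),
    delta = if (is.null(delta)) NA_real_ else delta,
    energy_threshold = energy_threshold
  ), class = "dpss_basis")
}

# exact concentrations lambda_k = v' S v with the band-limiting Toeplitz
# kernel S[t,t'] = sin(2 pi w (t-t'))/(pi (t-t')), via FFT convolution
dpss_concentrations <- function(tapers, w) {
  N <- nrow(tapers)
  m <- seq_len(N - 1)
  kern <- c(2 * w, sin(2 * pi * w * m) / (pi * m))
  nfft <- stats::nextn(2L * N - 1L, 2)
  # full symmetric kernel laid out for circular convolution
  kf <- fft(c(kern, rep(0, nfft - (2 * N - 1)), rev(kern[-1])))
  vapply(seq_len(ncol(tapers)), function(k) {
    v <- tapers[, k]
    u <- Re(fft(fft(c(v, rep(0, nfft - N))) * kf, inverse = TRUE)) / nfft
    sum(v * u[seq_len(N)])
  }, numeric(1))
}

#' @export
print.dpss_basis <- function(x, ...) {
  cat(sprintf("DPSS basis: N = %d, nw = %g, K = %d tapers\n",
              x$N, x$nw, x$K))
  cat(sprintf("  concentrations: %.6f .. %.6f (threshold %g)\n",
              x$concentrations[1], x$concentrations[x$K],
              x$energy_threshold))
  invisible(x)
}

#' Multitaper eigencoefficient of one data segment
#'
#' The tapered discrete-time Fourier transform
#' \deqn{Y_k(f) = \sum_{t=0}^{N-1} \nu_t^{(k)} d_t e^{-i 2 \pi f t \Delta},}
#' evaluated directly at an arbitrary frequency `f` (no FFT-grid snapping).
#' One eigencoefficient per taper per segment is the elementary feature of
#' the classifier.
#'
#' @param d numeric vector of (centered) samples.
#' @param taper taper sequence of the same length, or a matrix with one
#'   taper per column (a complex vector is then returned, one value per
#'   taper).
#' @param f evaluation frequency in Hz, within the Nyquist range.
#' @param delta sample period in seconds.
#' @return complex scalar (or vector, one per taper column).
#' @export
eigencoefficient <- function(d, taper, f, delta) {
  taper <- as.matrix(taper)
  if (length(d) != nrow(taper))
    stop_invalid("segment and taper lengths differ", "shape_error")
  if (abs(f) > 1 / (2 * delta) + 1e-12)
    stop_invalid("frequency beyond Nyquist", "invalid_parameter")
  ph <- -2 * pi * f * (seq_along(d) - 1) * delta
  x <- d * cos(ph)
  y <- d * sin(ph)
  drop(crossprod(taper, x)) + 1i * drop(crossprod(taper, y))
}

#' Per-epoch complex eigencoefficient feature matrix
#'
#' Assembles, for one 30 s epoch, the complex feature matrix `Y` with one
#' row per electrode contact and one column per (subsection, taper) pair:
#' column `q = K*(m-1) + k` holds the order-`k` eigencoefficient of
#' subsection `m` at frequency `f`. With 5 subsections and `K` tapers the
#' width is `Nr = 5*K`.
#'
#' @param epochs an `epoched_data` object (see [segment()]).
#' @param basis a `dpss_basis` whose `N` matches the subsection length.
#' @param epoch_index which epoch (1-based).
#' @param f evaluation frequency in Hz (default 10, the alpha-band centre).
#' @return object of class `eigen_features`: list with complex matrix `Y`
#'   (`Nc x Nr`), `f`, `epoch_index`, and `column_map` (data frame of
#'   `q`, `m`, `k`).
#' @export
build_features <- function(epochs, basis, epoch_index, f = 10) {
  stopifnot(inherits(epochs, "epoched_data"), inherits(basis, "dpss_basis"))
  if (epochs$n_contacts < 1)
    stop_invalid("no contacts present", "empty_data")
  if (epochs$N != basis$N)
    stop_invalid("subsection length does not match taper length",
                 "shape_error")
  e <- as.integer(epoch_index)
  if (e < 1 || e > epochs$n_epochs)
    stop_invalid("epoch index out of range", "invalid_parameter")
  M <- epochs$n_subsections
  K <- basis$K
  Nc <- epochs$n_contacts
  ph <- -2 * pi * f * (seq_len(epochs$N) - 1) * epochs$delta
  cs <- cos(ph); sn <- sin(ph)
  Y <- matrix(0i, Nc, M * K)
  for (cc in seq_len(Nc)) {
    D <- epochs$d[, , e, cc, drop = FALSE]
    dim(D) <- c(epochs$N, M)
    re <- crossprod(basis$tapers, D * cs)   # K x M
    im <- crossprod(basis$tapers, D * sn)
    Y[cc, ] <- as.vector(re) + 1i * as.vector(im)  # q = K*(m-1)+k
  }
  structure(list(
    Y = Y, f = f, epoch_index = e,
    column_map = data.frame(q = seq_len(M * K),
                            m = rep(seq_len(M), each = K),
                            k = rep(seq_len(K), M))
  ), class = "eigen_features")
}

#' Feature matrices for every epoch of a recording
#'
#' Convenience wrapper running [build_features()] over all epochs.
#'
#' @inheritParams build_features
#' @return list of `eigen_features`, one per epoch.
#' @export
build_feature_set <- function(epochs, basis, f = 10) {
  lapply(seq_len(epochs$n_epochs), function(e)
    build_features(epochs, basis, e, f = f))
}

#' Multitaper spectrum estimate at the evaluation frequency
#'
#' The unweighted multitaper estimate for one contact and one epoch: the
#' mean of the squared moduli of that contact's eigencoefficients across
#' all subsections and tapers,
#' \eqn{\check S = \sum_{m,k} |Y_{m,k}|^2 / (5K)}.
#'
#' @param features an `eigen_features` object.
#' @param contact contact row index; `NULL` (default) returns the estimate
#'   for every contact.
#' @return non-negative numeric, one value per requested contact.
#' @export
spectrum_estimate <- function(features, contact = NULL) {
  stopifnot(inherits(features, "eigen_features"))
  P <- Mod(features$Y)^2
  if (is.null(contact)) rowMeans(P) else {
    if (contact < 1 || contact > nrow(P))
      stop_invalid("contact index out of range", "invalid_parameter")
    mean(P[contact, ])
  }
}

#' Per-epoch, per-contact alpha-power table
#'
#' @param features list of `eigen_features` (one per epoch).
#' @return numeric matrix, epochs in rows, contacts in columns.
#' @export
spectrum_table <- function(features) {
  Nc <- nrow(features[[1]]$Y)
  out <- matrix(0, length(features), Nc)
  for (e in seq_along(features)) out[e, ] <- spectrum_estimate(features[[e]])
  out
}
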