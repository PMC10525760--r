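#' Cluster-conditional alpha power
#'
#' For every cluster and contact, the mean over the cluster's member
#' epochs of the per-epoch multitaper alpha-power estimate.
#'
#' @param spectra numeric matrix of per-epoch, per-contact power estimates
#'   (epochs in rows; see [spectrum_table()]).
#' @param labels per-epoch cluster indices in `1..n_clusters`.
#' @param n_clusters number of clusters.
#' @return object of class `cluster_alpha_power`: list with `S`
#'   (`n_clusters x Nc` matrix) and `n_members`.
#' @export
cluster_alpha_power <- function(spectra, labels, n_clusters = max(labels)) {
  spectra <- as.matrix(spectra)
  stopifnot(nrow(spectra) == length(labels))
  S <- matrix(NA_real_, n_clusters, ncol(spectra))
  Q <- integer(n_clusters)
  for (j in seq_len(n_clusters)) {
    members <- labels == j
    Q[j] <- sum(members)
    if (Q[j] == 0)
      stop(errorCondition(sprintf("cluster %d is empty", j),
                          class = c("empty_cluster", "remalpha_error")))
    S[j, ] <- colMeans(spectra[members, , drop = FALSE])
  }
  structure(list(S = S, n_members = Q), class = "cluster_alpha_power")
}

#' Per-contact cluster ranks of alpha power
#'
#' For each contact, ranks the clusters by their cluster-conditional alpha
#' power: rank 1 is the lowest-power cluster. Ties receive average
#' (fractional) ranks, so each column of the result sums to
#' `n_clusters * (n_clusters + 1) / 2`.
#'
#' @param power a `cluster_alpha_power`.
#' @return numeric matrix of ranks, clusters in rows, contacts in columns.
#' @export
contact_ranks <- function(power) {
  stopifnot(inherits(power, "cluster_alpha_power"))
  if (nrow(power$S) < 2)
    stop_invalid("ranking needs at least 2 clusters", "invalid_parameter")
  apply(power$S, 2, rank, ties.method = "average")
}

#' Identify the REM cluster from spectral ranks
#'
#' Computes each cluster's spectral rank (the median across contacts of
#' its per-contact alpha-power rank) and selects the cluster minimising
#' it; that cluster's epochs are the REM calls. When the minimum spectral
#' rank is attained by more than one cluster the decision is flagged
#' `reliable = FALSE` (the lowest-index minimiser is still reported so
#' downstream code can proceed while excluding flagged runs).
#'
#' @param power a `cluster_alpha_power`.
#' @param labels optional per-epoch cluster labels; when given, the REM
#'   epoch indices are filled in.
#' @return object of class `rem_decision`: list with `ranks`,
#'   `spectral_ranks`, `rem_cluster`, `reliable`, `rem_epochs` (possibly
#'   `NULL`), `fom1`, `fom2`.
#' @export
select_rem_cluster <- function(power, labels = NULL) {
  r <- contact_ranks(power)
  rho <- apply(r, 1, median)
  jstar <- which.min(rho)
  reliable <- sum(abs(rho - rho[jstar]) < 1e-12) == 1
  fom <- figures_of_merit(power, jstar)
  structure(list(
    ranks = r, spectral_ranks = rho, rem_cluster = jstar,
    reliable = reliable,
    rem_epochs = if (is.null(labels)) NULL else which(labels == jstar),
    fom1 = fom$fom1, fom2 = fom$fom2
  ), class = "rem_decision")
}

#' Figures of merit for a REM-cluster decision
#'
#' `fom1` is the minimum over contacts of the alpha-power gap between the
#' two lowest-power clusters at that contact (in power units; small values
#' mean at least one contact barely separates the REM cluster from its
#' closest competitor). `fom2` is the fraction of contacts at which the
#' REM cluster's alpha power is *not* that contact's minimum.
#'
#' @param power a `cluster_alpha_power`.
#' @param rem_cluster index of the REM cluster.
#' @return list with `fom1` and `fom2`.
#' @export
figures_of_merit <- function(power, rem_cluster) {
  S <- power$S
  if (nrow(S) < 2)
    stop_invalid("figures of merit need at least 2 clusters",
                 "invalid_parameter")
  gaps <- apply(S, 2, function(x) { s <- sort(x); s[2] - s[1] })
  not_min <- apply(S, 2, function(x) x[rem_cluster] > min(x))
  list(fom1 = min(gaps), fom2 = mean(not_min))
}

#' @export
print.rem_decision <- function(x, ...) {
  cat(sprintf("REM cluster: %d (%s), spectral ranks: %s\n",
              x$rem_cluster,
              if (x$reliable) "reliable" else "UNRELIABLE: tied minimum",
              paste(format(x$spectral_ranks, digits = 3), collapse = " ")))
  cat(sprintf("FOM1 (min inter-cluster alpha gap): %.4g, FOM2 (frac not minimum): %.2f\n",
              x$fom1, x$fom2))
  if (!is.null(x$rem_epochs))
    cat(sprintf("%d epochs labelled REM\n", length(x$rem_epochs)))
  invisible(x)
}
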