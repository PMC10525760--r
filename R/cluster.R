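#' Cluster-conditional mean and covariance estimates
#'
#' Given per-epoch complex feature matrices and a cluster labelling,
#' estimates for every cluster `j` the complex mean vector (the average of
#' all `Nr` feature columns of all member epochs) and the sample covariance
#' matrices of the real and imaginary column parts about that mean, with
#' divisor `Nr*Q_j - 1` (`Q_j` = member count). Real and imaginary parts
#' are modelled with separate covariances; no cross real-imaginary terms.
#'
#' @param features list of `eigen_features`, one per epoch.
#' @param labels integer vector of cluster indices in `1..n_clusters`.
#' @param n_clusters number of clusters.
#' @return object of class `cluster_model`: list with `mu` (complex
#'   `Nc x n_clusters`), `cov_real`, `cov_imag` (arrays
#'   `Nc x Nc x n_clusters`), `n_members`.
#' @export
estimate_cluster_params <- function(features, labels,
                                    n_clusters = max(labels)) {
  Nc <- nrow(features[[1]]$Y)
  Nr <- ncol(features[[1]]$Y)
  stopifnot(length(labels) == length(features))
  mu <- matrix(0i, Nc, n_clusters)
  cr <- array(0, c(Nc, Nc, n_clusters))
  ci <- array(0, c(Nc, Nc, n_clusters))
  Q <- integer(n_clusters)
  for (j in seq_len(n_clusters)) {
    members <- which(labels == j)
    Q[j] <- length(members)
    if (Q[j] == 0)
      stop(errorCondition(sprintf("cluster %d is empty", j),
                          class = c("empty_cluster", "remalpha_error")))
    Xr <- matrix(0, Nc, Nr * Q[j])
    Xi <- matrix(0, Nc, Nr * Q[j])
    for (q in seq_along(members)) {
      Y <- features[[members[q]]]$Y
      cols <- ((q - 1) * Nr + 1):(q * Nr)
      Xr[, cols] <- Re(Y)
      Xi[, cols] <- Im(Y)
    }
    mu[, j] <- complex(real = rowMeans(Xr), imaginary = rowMeans(Xi))
    n <- Nr * Q[j]
    if (n < 2)
      stop_invalid("cluster too small for covariance estimation",
                   "degenerate_data")
    Xr <- Xr - Re(mu[, j])
    Xi <- Xi - Im(mu[, j])
    cr[, , j] <- tcrossprod(Xr) / (n - 1)
    ci[, , j] <- tcrossprod(Xi) / (n - 1)
  }
  structure(list(mu = mu, cov_real = cr, cov_imag = ci, n_members = Q),
            class = "cluster_model")
}

# Cholesky of a cluster covariance after ridge regularisation
# eps * tr(R)/Nc on the diagonal; fails with a labelled error if the
# matrix is not positive definite even then.
chol_reg <- function(R, j, eps = 1e-8) {
  Nc <- nrow(R)
  ridge <- eps * sum(diag(R)) / Nc
  U <- tryCatch(chol(R + diag(ridge, Nc)), error = function(e) NULL)
  if (is.null(U))
    stop_invalid(sprintf(
      "covariance of cluster %d is singular (degenerate data)", j),
      "degenerate_data")
  U
}

#' Cluster-conditional Gaussian log-density of a feature matrix
#'
#' The joint log-density of the `Nr` real and `Nr` imaginary columns of a
#' complex feature matrix under cluster `j`'s Gaussian model: each column
#' is an independent `Nc`-variate normal with the cluster's mean part and
#' covariance part,
#' \deqn{\ln P = -N_r N_c \ln(2\pi)
#'   - \tfrac{N_r}{2}(\ln|R_r| + \ln|R_i|)
#'   - \tfrac12 \mathrm{tr}[(Y_r-\mu_r 1')' R_r^{-1} (Y_r-\mu_r 1')]
#'   - \tfrac12 \mathrm{tr}[(Y_i-\mu_i 1')' R_i^{-1} (Y_i-\mu_i 1')].}
#'
#' `variant = "as_printed"` replaces the constant and determinant factors
#' by `-Nc ln(2pi) - (Nc/2)(ln|Rr| + ln|Ri|)`; terms constant across
#' clusters do not affect cluster assignment, so the two variants yield
#' identical labelings, but the model-selection criterion built on top
#' differs. The standard variant keeps the criterion on the likelihood
#' scale and is the default.
#'
#' @param features an `eigen_features` object (or bare complex matrix).
#' @param model a `cluster_model`.
#' @param j cluster index.
#' @param variant `"standard"` (default) or `"as_printed"`, see Details.
#' @return scalar log-density.
#' @export
log_density <- function(features, model, j, variant = c("standard",
                                                        "as_printed")) {
  variant <- match.arg(variant)
  Y <- if (inherits(features, "eigen_features")) features$Y else features
  Nc <- nrow(Y); Nr <- ncol(Y)
  Ur <- chol_reg(model$cov_real[, , j], j)
  Ui <- chol_reg(model$cov_imag[, , j], j)
  ldr <- 2 * sum(log(diag(Ur)))
  ldi <- 2 * sum(log(diag(Ui)))
  Zr <- backsolve(Ur, Re(Y) - Re(model$mu[, j]), transpose = TRUE)
  Zi <- backsolve(Ui, Im(Y) - Im(model$mu[, j]), transpose = TRUE)
  quad <- sum(Zr^2) + sum(Zi^2)
  if (variant == "standard")
    -Nr * Nc * log(2 * pi) - (Nr / 2) * (ldr + ldi) - quad / 2
  else
    -Nc * log(2 * pi) - (Nc / 2) * (ldr + ldi) - quad / 2
}

# stack the per-epoch feature columns into two Nc x (Nr * E) matrices so
# the per-iteration linear algebra runs as single BLAS calls
stack_features <- function(features) {
  Nc <- nrow(features[[1]]$Y)
  Nr <- ncol(features[[1]]$Y)
  E <- length(features)
  Xr <- matrix(0, Nc, Nr * E)
  Xi <- matrix(0, Nc, Nr * E)
  for (e in seq_len(E)) {
    cols <- ((e - 1) * Nr + 1):(e * Nr)
    Xr[, cols] <- Re(features[[e]]$Y)
    Xi[, cols] <- Im(features[[e]]$Y)
  }
  list(Xr = Xr, Xi = Xi, Nc = Nc, Nr = Nr, E = E,
       epoch_of_col = rep(seq_len(E), each = Nr))
}

estimate_params_stacked <- function(st, labels, n_clusters) {
  Nc <- st$Nc; Nr <- st$Nr
  mu <- matrix(0i, Nc, n_clusters)
  cr <- array(0, c(Nc, Nc, n_clusters))
  ci <- array(0, c(Nc, Nc, n_clusters))
  Q <- integer(n_clusters)
  col_labels <- labels[st$epoch_of_col]
  for (j in seq_len(n_clusters)) {
    Q[j] <- sum(labels == j)
    if (Q[j] == 0)
      stop(errorCondition(sprintf("cluster %d is empty", j),
                          class = c("empty_cluster", "remalpha_error")))
    sel <- col_labels == j
    Xr <- st$Xr[, sel, drop = FALSE]
    Xi <- st$Xi[, sel, drop = FALSE]
    mr <- rowMeans(Xr); mi <- rowMeans(Xi)
    mu[, j] <- complex(real = mr, imaginary = mi)
    n <- Nr * Q[j]
    if (n < 2)
      stop_invalid("cluster too small for covariance estimation",
                   "degenerate_data")
    cr[, , j] <- tcrossprod(Xr - mr) / (n - 1)
    ci[, , j] <- tcrossprod(Xi - mi) / (n - 1)
  }
  structure(list(mu = mu, cov_real = cr, cov_imag = ci, n_members = Q),
            class = "cluster_model")
}

log_density_matrix_stacked <- function(st, model, variant = "standard") {
  k <- length(model$n_members)
  Nc <- st$Nc; Nr <- st$Nr
  out <- matrix(NA_real_, st$E, k)
  for (j in seq_len(k)) {
    Ur <- chol_reg(model$cov_real[, , j], j)
    Ui <- chol_reg(model$cov_imag[, , j], j)
    ld <- 2 * (sum(log(diag(Ur))) + sum(log(diag(Ui))))
    Zr <- backsolve(Ur, st$Xr - Re(model$mu[, j]), transpose = TRUE)
    Zi <- backsolve(Ui, st$Xi - Im(model$mu[, j]), transpose = TRUE)
    quad <- rowsum(colSums(Zr^2) + colSums(Zi^2), st$epoch_of_col)[, 1]
    out[, j] <- if (variant == "standard")
      -Nr * Nc * log(2 * pi) - (Nr / 2) * ld - quad / 2
    else
      -Nc * log(2 * pi) - (Nc / 2) * ld - quad / 2
  }
  out
}

# Nepisode x n_clusters matrix of log-densities
log_density_matrix <- function(features, model, variant = "standard") {
  log_density_matrix_stacked(stack_features(features), model, variant)
}

#' Likelihood-based K-means over complex feature matrices
#'
#' The modified K-means: labels are initialised uniformly at random,
#' cluster means and real/imaginary covariances are estimated from the
#' current members, every epoch is re-assigned to the cluster maximising
#' the Gaussian log-density, and the two steps alternate until a full pass
#' changes no label (or `max_iter` passes elapse). Ties in the assignment
#' go to the lowest cluster index.
#'
#' Random-label initialisation is fragile: every cluster starts near the
#' grand mean, so early reassignment passes can empty a cluster even when
#' the requested count is well supported, and a single run can settle in a
#' poor local optimum. `n_restarts` independent initialisations are
#' therefore run and the converged fit with the highest total assigned
#' log-density is kept (the same device as `nstart` in [stats::kmeans()]).
#' Restarts that empty a cluster are discarded; if every restart does, the
#' fit fails with an `empty_cluster` condition, which the model-selection
#' sweep treats as its stopping signal -- a cluster count the data cannot
#' sustain empties a cluster under every initialisation, so the sweep
#' semantics survive the restarts.
#'
#' @param features list of `eigen_features`.
#' @param n_clusters number of clusters (at most the number of epochs).
#' @param seed integer seed making the random initialisation reproducible;
#'   `NULL` uses (and advances) the current RNG stream.
#' @param max_iter iteration cap per restart; a restart hitting it is kept
#'   only if no restart converged, flagged `converged = FALSE`.
#' @param n_restarts number of random initialisations (default 10).
#' @param variant log-density variant, see [log_density()].
#' @return list with `labeling` (class `labeling`: `labels`,
#'   `n_iterations`, `converged`, `log_density_matrix`) and `model`
#'   (the final `cluster_model`).
#' @export
fit_kmeans <- function(features, n_clusters, seed = NULL, max_iter = 500,
                       n_restarts = 10, variant = "standard") {
  n <- length(features)
  if (n_clusters < 1 || n_clusters > n)
    stop_invalid("need at least as many epochs as clusters",
                 "invalid_parameter")
  if (max_iter < 1) stop_invalid("max_iter must be >= 1", "invalid_parameter")
  st <- stack_features(features)
  with_seed(seed, {
    best <- NULL
    best_ll <- -Inf
    for (restart in seq_len(max(1, n_restarts))) {
      labels <- NULL
      for (try in 1:100) {
        cand <- sample.int(n_clusters, n, replace = TRUE)
        if (length(unique(cand)) == n_clusters) { labels <- cand; break }
      }
      if (is.null(labels)) next
      attempt <- tryCatch({
        converged <- FALSE
        iter <- 0
        model <- NULL
        D <- NULL
        while (iter < max_iter) {
          iter <- iter + 1
          model <- estimate_params_stacked(st, labels, n_clusters)
          D <- log_density_matrix_stacked(st, model, variant)
          new_labels <- max.col(D, ties.method = "first")
          if (identical(new_labels, labels)) { converged <- TRUE; break }
          labels <- new_labels
          if (length(unique(labels)) < n_clusters)
            stop(errorCondition(
              sprintf("empty cluster after reassignment (k = %d)",
                      n_clusters),
              class = c("empty_cluster", "remalpha_error")))
        }
        list(
          labeling = structure(list(labels = labels, n_iterations = iter,
                                    converged = converged,
                                    log_density_matrix = D),
                               class = "labeling"),
          model = model
        )
      }, empty_cluster = function(e) NULL)
      if (is.null(attempt)) next
      ll <- sum(attempt$labeling$log_density_matrix[
        cbind(seq_len(n), attempt$labeling$labels)])
      # converged fits always beat non-converged ones
      rank_ll <- ll + if (attempt$labeling$converged) 0 else -Inf
      if (is.null(best) ||
          (rank_ll > best_ll) ||
          (!best$labeling$converged && attempt$labeling$converged)) {
        best <- attempt
        best_ll <- rank_ll
      }
    }
    if (is.null(best))
      stop(errorCondition(
        sprintf("every initialisation emptied a cluster (k = %d)",
                n_clusters),
        class = c("empty_cluster", "remalpha_error")))
    best
  })
}

#' Approximate AIC of a clustering
#'
#' \deqn{\widetilde{AIC}(N_{cluster}) = N_{cluster}(N_c^2 + N_c)
#'   - 2 \sum \ln P(Y^{(e)} | C = j).}
#' The penalty counts the `Nc` complex mean components and the two
#' `Nc x Nc` symmetric covariances per cluster (order `Nc^2 + Nc`
#' parameters). With `sum_over = "all"` the deviance term sums the
#' log-density of every epoch under **every** cluster (the double sum as
#' the source method prints it); `"assigned"` (default) sums each epoch's
#' log-density under its assigned cluster only, i.e. the maximised
#' log-likelihood, which is the standard AIC deviance. See the methods
#' vignette for why the default is the assigned-cluster sum.
#'
#' @param labeling a `labeling` (with populated `log_density_matrix`).
#' @param n_clusters number of clusters.
#' @param n_contacts `Nc`, the feature-matrix row count.
#' @param sum_over `"assigned"` (default) or `"all"`.
#' @return scalar criterion value.
#' @export
compute_aic <- function(labeling, n_clusters, n_contacts,
                        sum_over = c("assigned", "all")) {
  sum_over <- match.arg(sum_over)
  D <- labeling$log_density_matrix
  if (is.null(D) || anyNA(D))
    stop_invalid("log-density matrix not populated", "incomplete_state")
  dev <- if (sum_over == "all") sum(D)
  else sum(D[cbind(seq_len(nrow(D)), labeling$labels)])
  n_clusters * (n_contacts^2 + n_contacts) - 2 * dev
}

#' Cluster-count sweep with AIC selection
#'
#' Runs [fit_kmeans()] for every cluster count in `k_min..k_max`, stopping
#' the sweep early when a fit aborts with an empty cluster (the larger
#' counts are then not attempted), and returns the labelling whose
#' approximate AIC is minimal among the completed fits.
#'
#' @param features list of `eigen_features`.
#' @param k_min,k_max sweep range (defaults 2 and 14).
#' @param seed integer seed for reproducibility of all initialisations.
#' @param max_iter per-fit iteration cap.
#' @param n_restarts per-fit restart budget, see [fit_kmeans()].
#' @param variant log-density variant, see [log_density()].
#' @param sum_over AIC deviance variant, see [compute_aic()].
#' @return object of class `model_selection`: list with `aic_by_k` (named
#'   numeric), `chosen_k`, `labelings` (list keyed by k), `models`,
#'   `aborted_at` (`NA` if the sweep completed).
#' @export
select_clustering <- function(features, k_min = 2, k_max = 14, seed = NULL,
                              max_iter = 500, n_restarts = 10,
                              variant = "standard",
                              sum_over = "assigned") {
  if (k_min < 2) stop_invalid("k_min must be >= 2", "invalid_parameter")
  if (k_max < k_min) stop_invalid("k_max must be >= k_min",
                                  "invalid_parameter")
  if (k_min > length(features))
    stop_invalid("fewer epochs than k_min clusters", "invalid_parameter")
  Nc <- nrow(features[[1]]$Y)
  with_seed(seed, {
    aic <- numeric(0)
    labelings <- list()
    models <- list()
    aborted_at <- NA_integer_
    for (k in k_min:min(k_max, length(features))) {
      fit <- tryCatch(
        fit_kmeans(features, k, seed = NULL, max_iter = max_iter,
                   n_restarts = n_restarts, variant = variant),
        empty_cluster = function(e) NULL)
      if (is.null(fit)) { aborted_at <- k; break }
      key <- as.character(k)
      aic[key] <- compute_aic(fit$labeling, k, Nc, sum_over)
      labelings[[key]] <- fit$labeling
      models[[key]] <- fit$model
    }
    if (length(aic) == 0)
      stop_invalid("no cluster count produced a complete fit",
                   "selection_failure")
    chosen <- as.integer(names(aic)[which.min(aic)])
    structure(list(aic_by_k = aic, chosen_k = chosen,
                   labelings = labelings, models = models,
                   aborted_at = aborted_at),
              class = "model_selection")
  })
}

#' @export
print.model_selection <- function(x, ...) {
  cat("cluster-count sweep (approximate AIC):\n")
  for (k in names(x$aic_by_k))
    cat(sprintf("  k = %2s : %s%.2f\n", k,
                if (as.integer(k) == x$chosen_k) "* " else "  ",
                x$aic_by_k[[k]]))
  if (!is.na(x$aborted_at))
    cat(sprintf("  sweep stopped at k = %d (empty cluster)\n", x$aborted_at))
  invisible(x)
}
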