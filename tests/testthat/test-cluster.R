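test_that("cluster parameter estimates: mean, divisor, degenerate cases", {
  z <- 2 - 1i
  feats <- lapply(1:3, function(e) mkf(matrix(z, 2, 4)))
  m <- estimate_cluster_params(feats, rep(1L, 3), 1)
  expect_equal(m$mu[, 1], rep(z, 2))
  expect_equal(m$cov_real[, , 1], matrix(0, 2, 2))
  expect_equal(m$cov_imag[, , 1], matrix(0, 2, 2))
  expect_equal(m$n_members, 3L)
  expect_error(estimate_cluster_params(feats, c(1L, 1L, 1L), 2),
               class = "empty_cluster")
})

test_that("covariance estimates are Monte-Carlo consistent", {
  set.seed(31)
  Nr <- 110; Q <- 100                      # Nr * Q = 11000 columns
  feats <- lapply(seq_len(Q), function(e)
    mkf(matrix(complex(real = rnorm(2 * Nr, 0, rep(c(1, 2), Nr)),
                       imaginary = rnorm(2 * Nr, 0, rep(c(1, 2), Nr))),
               2, Nr)))
  m <- estimate_cluster_params(feats, rep(1L, Q), 1)
  expect_equal(diag(m$cov_real[, , 1]), c(1, 4), tolerance = 0.05)
  expect_equal(diag(m$cov_imag[, , 1]), c(1, 4), tolerance = 0.05)
  expect_equal(m$cov_real[1, 2, 1], 0, tolerance = 0.05)
  # perfectly correlated real parts: off-diagonal = geometric mean
  feats2 <- lapply(1:20, function(e) {
    x <- rnorm(6)
    mkf(matrix(complex(real = c(rbind(x, 3 * x)),
                       imaginary = rnorm(12)), 2, 6))
  })
  m2 <- estimate_cluster_params(feats2, rep(1L, 20), 1)
  expect_equal(m2$cov_real[1, 2, 1],
               sqrt(m2$cov_real[1, 1, 1] * m2$cov_real[2, 2, 1]),
               tolerance = 1e-10)
})

test_that("log-density matches the brute-force per-column oracle", {
  set.seed(32)
  for (rep in 1:5) {
    Nc <- sample(2:3, 1); Nr <- sample(4:6, 1)
    feats <- draw_features(8, Nc, Nr, mu = complex(real = rnorm(Nc),
                                                   imaginary = rnorm(Nc)))
    m <- estimate_cluster_params(feats, rep(1L, 8), 1)
    got <- log_density(feats[[1]], m, 1)
    want <- oracle_log_density(feats[[1]]$Y, m$mu[, 1],
                               m$cov_real[, , 1], m$cov_imag[, , 1])
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("log-density closed forms: zero deviation and quadratic scaling", {
  Nc <- 3; Nr <- 7
  mu <- complex(real = 1:3, imaginary = c(-1, 0, 2))
  m <- manual_model(matrix(mu, Nc, 1), diag(Nc), diag(Nc))
  Y0 <- matrix(mu, Nc, Nr)
  expect_equal(log_density(mkf(Y0), m, 1), -Nr * Nc * log(2 * pi),
               tolerance = 1e-6)
  set.seed(33)
  Dev <- matrix(complex(real = rnorm(Nc * Nr), imaginary = rnorm(Nc * Nr)),
                Nc, Nr)
  ss <- sum(Re(Dev)^2 + Im(Dev)^2)
  d1 <- log_density(mkf(Y0 + Dev), m, 1)
  d2 <- log_density(mkf(Y0 + 2 * Dev), m, 1)
  expect_equal(d1 - d2, 1.5 * ss, tolerance = 1e-7)
})

test_that("as-printed density variant differs only by assignment constants", {
  set.seed(34)
  feats <- draw_features(6, 2, 5)
  m <- estimate_cluster_params(feats, rep(1:2, 3), 2)
  Nc <- 2; Nr <- 5
  for (j in 1:2) {
    std <- log_density(feats[[1]], m, j, variant = "standard")
    prt <- log_density(feats[[1]], m, j, variant = "as_printed")
    ld <- as.numeric(determinant(m$cov_real[, , j])$modulus +
                     determinant(m$cov_imag[, , j])$modulus)
    expect_equal(std - prt,
                 -(Nr - 1) * Nc * log(2 * pi) - (Nr - Nc) / 2 * ld,
                 tolerance = 1e-6)
  }
})

test_that("k-means: single cluster, determinism, degenerate input", {
  set.seed(35)
  feats <- draw_features(10, 2, 6)
  one <- fit_kmeans(feats, 1, seed = 1)
  expect_equal(one$labeling$labels, rep(1L, 10))
  expect_true(one$labeling$converged)
  a <- fit_kmeans(feats, 2, seed = 7)
  b <- fit_kmeans(feats, 2, seed = 7)
  expect_identical(a$labeling$labels, b$labeling$labels)
  expect_identical(a$labeling$n_iterations, b$labeling$n_iterations)
  same <- lapply(1:6, function(e) mkf(matrix(1 + 2i, 2, 6)))
  expect_error(fit_kmeans(same, 2, seed = 1), class = "degenerate_data")
  expect_error(fit_kmeans(feats, 11, seed = 1), class = "invalid_parameter")
})

test_that("k-means recovers planted well-separated clusters", {
  for (s in 1:5) {
    seqs <- rep(c("A", "B"), each = 15)
    cfg <- planted_feature_config(seqs, n_contacts = 6, Nr = 40,
                                  separation = 10, seed = s)
    fs <- generate_feature_set(cfg, mode = "features")
    fit <- fit_kmeans(fs$features, 2, seed = s)
    expect_equal(mclust::adjustedRandIndex(fit$labeling$labels, fs$truth), 1)
    expect_true(fit$labeling$converged)
    expect_lte(fit$labeling$n_iterations, 100)
  }
})

test_that("each reassignment pass never decreases the assigned log-density", {
  set.seed(36)
  cfg <- planted_feature_config(rep(c("A", "B", "C"), each = 8),
                                n_contacts = 4, Nr = 12, separation = 6,
                                seed = 2)
  feats <- generate_feature_set(cfg, mode = "features")$features
  labels <- sample(1:3, length(feats), replace = TRUE)
  labels[1:3] <- 1:3
  prev <- -Inf
  for (iter in 1:50) {
    model <- estimate_cluster_params(feats, labels, 3)
    D <- sapply(1:3, function(j)
      vapply(feats, log_density, numeric(1), model = model, j = j))
    obj <- sum(apply(D, 1, max))
    expect_gte(obj, prev - 1e-6 * abs(prev))
    prev <- obj
    new_labels <- max.col(D, ties.method = "first")
    if (identical(new_labels, labels)) break
    labels <- new_labels
    if (length(unique(labels)) < 3) break
  }
})

test_that("approximate AIC penalty and sums are as defined", {
  D <- matrix(0, 3, 2)
  lab <- structure(list(labels = c(1L, 2L, 1L), n_iterations = 1L,
                        converged = TRUE, log_density_matrix = D),
                   class = "labeling")
  Nc <- 2
  expect_equal(compute_aic(lab, 2, Nc, sum_over = "all"), 2 * (Nc^2 + Nc))
  # adding a cluster of all-zero densities adds exactly Nc^2 + Nc
  lab3 <- lab; lab3$log_density_matrix <- cbind(D, 0)
  expect_equal(compute_aic(lab3, 3, Nc, sum_over = "all") -
                 compute_aic(lab, 2, Nc, sum_over = "all"), Nc^2 + Nc)
  # hand-summed small instance, both variants
  set.seed(37)
  D2 <- matrix(rnorm(6, -50, 5), 3, 2)
  lab2 <- lab; lab2$log_density_matrix <- D2
  expect_equal(compute_aic(lab2, 2, Nc, sum_over = "all"),
               2 * (Nc^2 + Nc) - 2 * sum(D2))
  expect_equal(compute_aic(lab2, 2, Nc, sum_over = "assigned"),
               2 * (Nc^2 + Nc) - 2 * (D2[1, 1] + D2[2, 2] + D2[3, 1]))
  lab2$log_density_matrix <- NULL
  expect_error(compute_aic(lab2, 2, Nc), class = "incomplete_state")
})

test_that("cluster-count sweep returns finite AICs and the arg-min", {
  cfg <- planted_feature_config(rep(c("A", "B"), each = 12),
                                n_contacts = 4, Nr = 16, separation = 8,
                                seed = 5)
  feats <- generate_feature_set(cfg, mode = "features")$features
  sel <- select_clustering(feats, 2, 4, seed = 9)
  expect_true(all(is.finite(sel$aic_by_k)))
  expect_equal(sel$chosen_k,
               as.integer(names(which.min(sel$aic_by_k))))
  sel2 <- select_clustering(feats, 2, 4, seed = 9)
  expect_identical(sel$aic_by_k, sel2$aic_by_k)
  expect_error(select_clustering(feats, 1, 4), class = "invalid_parameter")
  expect_error(select_clustering(feats, 2, 1), class = "invalid_parameter")
  expect_error(select_clustering(feats[1:3], 4, 5),
               class = "invalid_parameter")
})
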