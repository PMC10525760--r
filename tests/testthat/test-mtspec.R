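test_that("DPSS basis is orthonormal with decreasing concentrations", {
  b <- make_dpss(128, 4, energy_threshold = 0)
  expect_lt(max(abs(crossprod(b$tapers) - diag(b$K))), 1e-8)
  expect_true(all(diff(b$concentrations) < 0))
  expect_true(all(b$concentrations > 0 & b$concentrations < 1))
  expect_equal(apply(b$tapers, 2, function(v) sum(v^2)),
               rep(1, b$K), tolerance = 1e-12)
})

test_that("taper count at threshold matches the quadrature oracle", {
  b <- make_dpss(128, 4, energy_threshold = 0, max_tapers = 12)
  lam_oracle <- vapply(seq_len(b$K), function(k)
    oracle_band_energy(b$tapers[, k], 4 / 128), numeric(1))
  expect_equal(b$concentrations, lam_oracle, tolerance = 1e-3)
  expect_equal(make_dpss(128, 4, 0.98)$K, sum(lam_oracle > 0.98))
})

test_that("make_dpss validates parameters and honours n_tapers", {
  expect_error(make_dpss(1, 0.3), class = "invalid_parameter")
  expect_error(make_dpss(128, 64), class = "invalid_parameter")
  expect_error(make_dpss(16, 0.5, energy_threshold = 0.999),
               class = "empty_basis")
  expect_equal(make_dpss(256, 4, n_tapers = 6)$K, 6L)
})

test_that("eigencoefficient is the tapered DTFT", {
  b <- make_dpss(256, 4, 0.98, delta = 1 / 128)
  expect_equal(eigencoefficient(rep(0, 256), b$tapers, 10, 1 / 128),
               rep(0 + 0i, b$K))
  # a taper against itself at f = 0 integrates to its unit energy
  expect_equal(eigencoefficient(b$tapers[, 1], b$tapers[, 1], 0, 1 / 128),
               1 + 0i, tolerance = 1e-12)
  expect_error(eigencoefficient(rep(0, 100), b$tapers, 10, 1 / 128),
               class = "shape_error")
  expect_error(eigencoefficient(rep(0, 256), b$tapers, 100, 1 / 128),
               class = "invalid_parameter")
})

test_that("white-noise eigencoefficients have E|Y|^2 = sigma^2", {
  set.seed(8)
  b <- make_dpss(64, 2, 0.9)
  sigma <- 1.7
  draws <- replicate(4000, {
    y <- eigencoefficient(rnorm(64, sd = sigma), b$tapers[, 1], 0.1, 1)
    Mod(y)^2
  })
  expect_equal(mean(draws), sigma^2, tolerance = 0.1)
})

test_that("direct DTFT equals the DFT bin when f*N*delta is an integer", {
  set.seed(9)
  N <- 1200; delta <- 1 / 200                   # 10 * 1200 / 200 = bin 60
  b <- make_dpss(N, 12, 0.98, delta = delta)
  d <- rnorm(N)
  for (k in c(1, b$K)) {
    y1 <- eigencoefficient(d, b$tapers[, k], 10, delta)
    y2 <- fft(b$tapers[, k] * d)[61]
    expect_lt(Mod(y1 - y2) / Mod(y2), 1e-9)
  }
})

test_that("feature matrix has Nc x 5K layout with the q = K(m-1)+k map", {
  set.seed(10)
  fs <- 100
  rr <- raw_recording(matrix(rnorm(fs * 30 * 3), ncol = 3), 1 / fs)
  ep <- segment(rr)
  b <- make_dpss(ep$N, 12, 0.98, delta = ep$delta)
  ft <- build_features(ep, b, 1)
  expect_equal(dim(ft$Y), c(3L, 5L * b$K))
  expect_equal(ft$column_map$q, seq_len(5 * b$K))
  expect_equal(ft$column_map$k, rep(seq_len(b$K), 5))
  expect_equal(ft$column_map$m, rep(1:5, each = b$K))
  # column q holds the eigencoefficient of subsection m_q under taper k_q
  for (q in c(1, b$K + 2, 5 * b$K)) {
    m <- ft$column_map$m[q]; k <- ft$column_map$k[q]
    direct <- eigencoefficient(ep$d[, m, 1, 2], b$tapers[, k], 10, ep$delta)
    expect_equal(ft$Y[2, q], direct, tolerance = 1e-12)
  }
  # permuting contacts permutes rows identically
  rr2 <- raw_recording(rr$samples[, c(3, 1, 2)], 1 / fs)
  ft2 <- build_features(segment(rr2), b, 1)
  expect_equal(ft2$Y, ft$Y[c(3, 1, 2), ])
})

test_that("spectrum estimate is the mean squared modulus across columns", {
  Y <- matrix(1 + 0i, 2, 10)
  expect_equal(spectrum_estimate(mkf(Y)), c(1, 1))
  expect_equal(spectrum_estimate(mkf(matrix(0i, 2, 10))), c(0, 0))
  set.seed(12)
  Z <- matrix(complex(real = rnorm(30), imaginary = rnorm(30)), 3, 10)
  expect_equal(spectrum_estimate(mkf(Z)), rowMeans(Mod(Z)^2))
  expect_equal(spectrum_estimate(mkf(Z), contact = 2), mean(Mod(Z[2, ])^2))
})

test_that("multitaper estimate of unit white noise is unbiased", {
  set.seed(13)
  fs <- 100
  rr <- raw_recording(matrix(rnorm(fs * 30 * 40), ncol = 40), 1 / fs)
  ep <- segment(rr)
  b <- make_dpss(ep$N, 12, 0.98, delta = ep$delta)
  svals <- spectrum_estimate(build_features(ep, b, 1, f = 10))
  expect_equal(mean(svals), 1, tolerance = 0.05)   # 40 x 5K averages
})
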