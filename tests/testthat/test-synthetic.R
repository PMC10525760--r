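test_that("generated nights are reproducible and well-formed", {
  cfg <- synth_config(n_contacts = 3, sample_rate = 100,
                      stage_sequence = rep(c("W", "REM"), each = 3),
                      seed = 71)
  a <- generate_night(cfg)
  b <- generate_night(cfg)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_equal(dim(a$recording$samples), c(6 * 30 * 100, 3))
  expect_equal(a$truth, cfg$stage_sequence)
  expect_error(synth_config(n_contacts = 0), class = "invalid_parameter")
  expect_error(synth_config(alpha_amp = c(W = -1, REM = 1),
                            stage_sequence = c("W", "REM")),
               class = "invalid_parameter")
  expect_error(synth_config(contact_coupling = 1),
               class = "invalid_parameter")
})

test_that("wake epochs carry more 10 Hz power than REM epochs", {
  cfg <- synth_config(n_contacts = 4, sample_rate = 100,
                      stage_sequence = rep(c("W", "REM"), each = 50),
                      seed = 72)
  fs <- generate_feature_set(cfg, mode = "signal")
  svals <- rowMeans(spectrum_table(fs$features))
  expect_gt(mean(svals[fs$truth == "W"]), mean(svals[fs$truth == "REM"]))
  # and the contrast is large, not marginal
  expect_gt(mean(svals[fs$truth == "W"]) / mean(svals[fs$truth == "REM"]), 3)
})

test_that("power far outside the alpha band is stage-independent", {
  cfg <- synth_config(n_contacts = 4, sample_rate = 100,
                      stage_sequence = rep(c("W", "REM"), each = 50),
                      seed = 73)
  night <- generate_night(cfg)
  ep <- segment(night$recording)
  basis <- make_dpss(ep$N, 12, 0.98, delta = ep$delta)
  f40 <- build_feature_set(ep, basis, f = 40)
  s40 <- rowMeans(spectrum_table(f40))
  ratio <- mean(s40[night$truth == "W"]) / mean(s40[night$truth == "REM"])
  expect_equal(ratio, 1, tolerance = 0.1)
})

test_that("stage power follows amplitude-squared scaling", {
  a <- 2
  cfg <- synth_config(n_contacts = 3, sample_rate = 100,
                      stage_sequence = rep(c("N2", "W", "REM"), each = 40),
                      alpha_amp = c(N2 = 0, W = a, REM = 2 * a),
                      seed = 74)
  fs <- generate_feature_set(cfg, mode = "signal")
  svals <- rowMeans(spectrum_table(fs$features))
  bg <- mean(svals[fs$truth == "N2"])              # amplitude-zero stage
  kappa <- (mean(svals[fs$truth == "W"]) - bg) / a^2
  predicted <- bg + 4 * a^2 * kappa
  expect_equal(mean(svals[fs$truth == "REM"]), predicted, tolerance = 0.1)
})

test_that("feature-space mode plants exactly the Gaussian model", {
  cfg <- planted_feature_config(rep(c("A", "B"), each = 10),
                                n_contacts = 2, Nr = 200,
                                separation = 5, sd = 1.5, seed = 75)
  fs <- generate_feature_set(cfg, mode = "features")
  expect_length(fs$features, 20)
  Ya <- do.call(cbind, lapply(fs$features[1:10], function(f) f$Y))
  expect_equal(Re(rowMeans(Ya)), Re(cfg$means[, "A"]), tolerance = 0.1)
  expect_equal(sd(Re(Ya - rowMeans(Ya))), 1.5, tolerance = 0.05)
  # reproducible
  fs2 <- generate_feature_set(cfg, mode = "features")
  expect_identical(fs$features[[3]]$Y, fs2$features[[3]]$Y)
})

test_that("statistically identical stages yield chance-level precision", {
  set.seed(76)
  prec <- vapply(1:8, function(s) {
    cfg <- planted_alpha_config(sample(rep(c("W", "REM"), c(20, 10))),
                                n_contacts = 3, Nr = 20,
                                amps = c(W = 0, REM = 0), seed = s)
    fs <- generate_feature_set(cfg, mode = "features")
    res <- classify_features(fs$features, truth = fs$truth, k_max = 3,
                             seed = s)
    res$report$frac_rem_labels_correct
  }, numeric(1))
  expect_equal(mean(prec, na.rm = TRUE), 1 / 3, tolerance = 0.2)
})

test_that("end-to-end: planted REM is recovered from the signal path", {
  cfg <- synth_config(n_contacts = 6, sample_rate = 100,
                      stage_sequence = rep(c("W", "N2", "REM", "N2", "W"),
                                           times = c(8, 12, 10, 8, 6)),
                      seed = 77)
  fs <- generate_feature_set(cfg, mode = "signal")
  res <- classify_features(fs$features, truth = fs$truth, seed = 77)
  rem_true <- which(fs$truth == "REM")
  expect_gt(length(res$decision$rem_epochs), 0)
  expect_gte(res$report$frac_rem_labels_correct, 0.9)
  baseline <- matched_alpha_detector(res$spectra,
                                     length(res$decision$rem_epochs))
  expect_length(baseline, length(res$decision$rem_epochs))
})
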