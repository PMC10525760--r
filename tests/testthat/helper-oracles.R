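# shared fixtures and independent oracles

# wrap a bare complex matrix as an eigen_features object
mkf <- function(Y) {
  structure(list(Y = Y, f = NA_real_, epoch_index = NA_integer_,
                 column_map = data.frame(q = seq_len(ncol(Y)),
                                         m = NA_integer_, k = NA_integer_)),
            class = "eigen_features")
}

# draw a list of feature matrices around a complex mean, identity-sd noise
draw_features <- function(n, Nc, Nr, mu = 0 + 0i, sd = 1) {
  lapply(seq_len(n), function(e)
    mkf(matrix(complex(real = rnorm(Nc * Nr, 0, sd),
                       imaginary = rnorm(Nc * Nr, 0, sd)), Nc, Nr) + mu))
}

# brute-force oracle: sum of generic multivariate-normal log-pdfs over the
# real columns and the imaginary columns, by direct determinant + solve
oracle_log_density <- function(Y, mu, Rr, Ri) {
  Nc <- nrow(Y)
  tot <- 0
  for (q in seq_len(ncol(Y))) {
    for (part in 1:2) {
      x <- if (part == 1) Re(Y[, q]) else Im(Y[, q])
      m <- if (part == 1) Re(mu) else Im(mu)
      R <- if (part == 1) Rr else Ri
      tot <- tot - Nc / 2 * log(2 * pi) -
        0.5 * as.numeric(determinant(R)$modulus) -
        0.5 * drop(t(x - m) %*% solve(R) %*% (x - m))
    }
  }
  tot
}

# independent band-energy oracle: numerically integrate |V(f)|^2 over
# (-w, w) cycles/sample on a fine zero-padded FFT grid
oracle_band_energy <- function(taper, w, pad = 2^18) {
  P <- Mod(fft(c(taper, rep(0, pad - length(taper)))))^2
  f <- (seq_len(pad) - 1) / pad
  f[f >= 0.5] <- f[f >= 0.5] - 1
  sum(P[abs(f) < w]) / pad
}

# build a cluster_model by hand
manual_model <- function(mu, cov_real, cov_imag, n_members = 1L) {
  k <- ncol(as.matrix(mu))
  Nc <- nrow(as.matrix(mu))
  structure(list(mu = as.matrix(mu),
                 cov_real = array(cov_real, c(Nc, Nc, k)),
                 cov_imag = array(cov_imag, c(Nc, Nc, k)),
                 n_members = rep(n_members, k)),
            class = "cluster_model")
}
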