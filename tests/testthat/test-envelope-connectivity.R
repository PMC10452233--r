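# Orthogonalized power-envelope connectivity: analytic signal,
# orthogonalization identities, envelope recovery, leakage rejection,
# ROI aggregation.

test_that("analytic signal recovers unit tones, Hilbert pairs and AM envelopes", {
  fs <- 256
  t <- (0:(4 * fs - 1)) / fs
  interior <- seq(fs, 3 * fs)
  z <- analytic_signal(cos(2 * pi * 10 * t))
  expect_lt(max(abs(Mod(z)[interior] - 1)), 0.01)
  expect_equal(Re(z), cos(2 * pi * 10 * t), tolerance = 1e-10)
  expect_lt(max(abs(Im(z)[interior] - sin(2 * pi * 10 * t)[interior])), 0.01)

  a <- 1.5 + cos(2 * pi * 0.5 * t)          # slow positive modulator
  am <- a * cos(2 * pi * 20 * t)
  za <- analytic_signal(am)
  expect_lt(max(abs(Mod(za)[interior] - a[interior]) / a[interior]), 0.02)

  expect_error(analytic_signal(rnorm(16)), "32 samples")
})

test_that("orthogonalization removes shared zero-lag components exactly", {
  set.seed(1)
  X <- complex(real = rnorm(100), imaginary = rnorm(100))
  expect_equal(orthogonalize(2.5 * X, X), rep(0, 100), tolerance = 1e-12)
  expect_equal(orthogonalize(1i * X, X), Mod(X), tolerance = 1e-12)
  Y <- complex(real = rnorm(100), imaginary = rnorm(100))
  expect_equal(orthogonalize(Y, rep(1 + 0i, 100)), Im(Y), tolerance = 1e-14)
  # zero-magnitude guard
  X0 <- X; X0[5] <- 0
  expect_equal(orthogonalize(Y, X0)[5], 0)
})

test_that("log-power envelope obeys log identities", {
  z1 <- complex(modulus = rep(1, 64), argument = seq(0, 6, length.out = 64))
  expect_lt(max(abs(log_power_envelope(z1))), 1e-6)
  z2 <- complex(modulus = rep(exp(1), 64), argument = rep(0.3, 64))
  expect_equal(log_power_envelope(z2), rep(2, 64), tolerance = 1e-6)
  set.seed(2)
  z <- complex(real = rnorm(64), imaginary = rnorm(64))
  expect_equal(log_power_envelope(3 * z) - log_power_envelope(z),
               rep(2 * log(3), 64), tolerance = 1e-6)
  expect_error(log_power_envelope(rep(0 + 0i, 10)), "all-zero")
})

test_that("planted envelope couplings are recovered and ordered by rho", {
  est <- sapply(c(0.2, 0.5, 0.8), function(rho) {
    cfg <- coupled_pair_config(rho)
    mean(sapply(1:20, function(k) {
      sig <- generate_source_signals(cfg, 500 + k, n_samples = 15360)
      pec_pair(sig$roi_signals[1, ], sig$roi_signals[2, ], fs = 256,
               band = c(13, 30))
    }))
  })
  expect_lt(max(abs(est - c(0.2, 0.5, 0.8))), 0.05)
  expect_true(all(diff(est) > 0))      # monotone in planted rho
})

test_that("an exact zero-lag duplicate has PEC 0 but raw envelope correlation 1", {
  cfg <- coupled_pair_config(0.5)
  sig <- generate_source_signals(cfg, 41, n_samples = 8192)
  s <- sig$roi_signals[1, ]
  expect_equal(pec_pair(s, s, 256, c(13, 30)), 0)
  expect_equal(pec_pair(s, 3 * s, 256, c(13, 30)), 0)   # real-gain copy
  expect_equal(raw_envelope_correlation(s, s, 256, c(13, 30)), 1,
               tolerance = 1e-12)
})

test_that("noisy common-source leakage stays far below the raw envelope correlation", {
  cfg <- coupled_pair_config(0)
  res <- sapply(1:10, function(k) {
    sig <- generate_source_signals(cfg, 900 + k, n_samples = 15360)
    s <- sig$roi_signals[1, , drop = FALSE]
    y <- mix_to_sensors(s, matrix(1, 2, 1), snr = 5, seed = k)
    y <- bandpass(unclass(y), 256, 13, 30)   # keep the shared band content
    c(pec = pec_pair(y[1, ], y[2, ], 256, c(13, 30)),
      raw = raw_envelope_correlation(y[1, ], y[2, ], 256, c(13, 30)))
  })
  # residual reference-noise bias is small but nonzero at finite snr; the
  # un-orthogonalized correlation stays near 1 (see the methods vignette)
  expect_lt(mean(abs(res["pec", ])), 0.1)
  expect_true(all(abs(res["pec", ]) < 0.2))
  expect_true(all(res["raw", ] > 0.8))
  expect_gt(min(res["raw", ] - abs(res["pec", ])), 0.6)
})

test_that("independent nodes have PEC near zero and PEC matrices are symmetric", {
  cfg <- coupled_pair_config(0)
  sig <- generate_source_signals(cfg, 33, n_samples = 15360)
  p <- pec_pair(sig$roi_signals[1, ], sig$roi_signals[2, ], 256, c(13, 30))
  expect_lt(abs(p), 0.15)

  x <- array(sig$roi_signals, dim = c(2, 15360, 1))
  set.seed(3)
  x3 <- array(0, dim = c(3, 2048, 2))
  for (e in 1:2) x3[, , e] <- bandpass(matrix(rnorm(3 * 2048), 3), 256, 13, 30)
  P <- pec_matrix(x3, fs = 256, band = c(13, 30))
  expect_identical(P, t(P))
  expect_true(all(is.na(diag(P))))
  expect_true(all(abs(P[upper.tri(P)]) <= 1))
})

test_that("epoched and pooled computation handles short task epochs", {
  cfg <- coupled_pair_config(0.8)
  sig <- generate_source_signals(cfg, 77, n_samples = 155 * 60)
  x <- array(0, dim = c(2, 155, 60))
  for (e in 1:60)
    x[, , e] <- sig$roi_signals[, ((e - 1) * 155 + 1):(e * 155)]
  p <- pec_pair(x[1, , ], x[2, , ], fs = 256, band = c(13, 30))
  expect_gt(p, 0.5)     # strong planted coupling survives epoching
})

test_that("ROI aggregation averages dipole pairs and yields 2278 features at 68 ROIs", {
  set.seed(4)
  V <- matrix(rnorm(36), 6, 6)
  V <- (V + t(V)) / 2
  diag(V) <- NA
  # one dipole per ROI: aggregate equals the vertex matrix
  r1 <- roi_aggregate(V, 1:6)
  expect_equal(r1$matrix[upper.tri(V)], V[upper.tri(V)], tolerance = 1e-14)
  expect_equal(length(r1$upper_tri), 15)
  # all dipole-level values equal c: every off-diagonal entry is c
  Vc <- matrix(0.37, 6, 6)
  rc <- roi_aggregate(Vc, c(1, 1, 2, 2, 3, 3))
  expect_true(all(abs(rc$matrix[upper.tri(rc$matrix)] - 0.37) < 1e-14))
  # 68 ROIs give the canonical 2278-length feature vector
  n <- 68
  W <- matrix(rnorm(n * n), n, n)
  W <- (W + t(W)) / 2
  r68 <- roi_aggregate(W, 1:68)
  expect_equal(length(r68$upper_tri), 2278)
  expect_error(roi_aggregate(V, c(1, 1, 2, 2, 4, 4)), "no dipole")
})

test_that("upper-triangle vectorization is row-major and invertible", {
  M <- matrix(0, 4, 4)
  M[upper.tri(M)] <- 1   # column-major fill
  M <- M + t(M)
  A <- matrix(seq_len(16), 4, 4)
  v <- upper_tri_vec(A)
  expect_equal(v, c(A[1, 2], A[1, 3], A[1, 4], A[2, 3], A[2, 4], A[3, 4]))
  idx <- upper_tri_index(4)
  expect_equal(A[idx], v)
})
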