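# Synthetic cohort generator: determinism, planted-coupling fidelity,
# sensor mixing, group effects.

test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(band = c(13, 30), fs = 50), "aliasing")
  expect_error(sim_config(coupling_spec = data.frame(roi_i = 1, roi_j = 2,
                                                     rho = 1.2)), "rho")
  expect_error(sim_config(n_rois = 4,
                          coupling_spec = data.frame(roi_i = 1, roi_j = 9,
                                                     rho = 0.5)), "n_rois")
  expect_error(sim_config(coupling_spec = data.frame(roi_i = 2, roi_j = 2,
                                                     rho = 0.5)), "distinct")
  expect_error(sim_config(n_subjects_per_group = 0), "at least one subject")
  expect_error(sim_config(snr = 0), "snr")
})

test_that("same seed reproduces identical source signals and cohorts", {
  cfg <- coupled_pair_config(0.5)
  a <- generate_source_signals(cfg, 11, n_samples = 2048)
  b <- generate_source_signals(cfg, 11, n_samples = 2048)
  expect_identical(a$sources, b$sources)
  expect_identical(a$latent_log_envelopes, b$latent_log_envelopes)

  cc <- sim_config(n_subjects_per_group = 2, groups = c("HC", "CS"),
                   n_rois = 3, dipoles_per_roi = 1, n_sensors = 6,
                   n_epochs = 4, band = c(13, 30), seed = 5)
  x <- generate_cohort(cc)
  y <- generate_cohort(cc)
  expect_identical(x$subjects[[3]]$epochs$data, y$subjects[[3]]$epochs$data)
})

test_that("uncoupled ROIs have near-zero latent log-envelope correlations", {
  cfg <- sim_config(n_rois = 6, dipoles_per_roi = 1, n_sensors = 8,
                    band = c(13, 30), seed = 2)
  Tn <- 8192
  sig <- generate_source_signals(cfg, 7, n_samples = Tn)
  C <- cor(t(sig$latent_log_envelopes))
  off <- abs(C[upper.tri(C)])
  expect_lte(mean(off), 3 / sqrt(Tn))
})

test_that("planted couplings are realized on the latent log-envelopes", {
  for (rho in c(0.2, 0.8)) {
    cfg <- coupled_pair_config(rho)
    sig <- generate_source_signals(cfg, 21, n_samples = 15360)
    expect_lt(abs(sig$ground_truth$rho_realized - rho), 0.02)
    direct <- cor(sig$latent_log_envelopes[1, ], sig$latent_log_envelopes[2, ])
    expect_equal(sig$ground_truth$rho_realized, direct, tolerance = 1e-12)
  }
})

test_that("sources are band-limited with log-normal envelopes", {
  cfg <- coupled_pair_config(0, band = c(8, 12))
  sig <- generate_source_signals(cfg, 3, n_samples = 8192)
  x <- sig$roi_signals[1, ]
  sp <- Mod(fft(x))^2
  f <- (seq_along(x) - 1) * 256 / length(x)
  # constant-modulus carriers spread FM-like sidebands past the band edges;
  # the bulk of the power must still sit in the band plus envelope sidebands
  in_band <- f >= 6 & f <= 14
  half <- f <= 128
  expect_gt(sum(sp[in_band & half]) / sum(sp[half]), 0.9)
})

test_that("sensor mixing is instantaneous and respects the requested snr", {
  cfg <- coupled_pair_config(0.3)
  sig <- generate_source_signals(cfg, 9, n_samples = 4096)
  # identity mixing, no noise: sensors equal sources
  y <- mix_to_sensors(sig$sources, diag(2), snr = Inf)
  expect_equal(unclass(y)[, ], sig$sources[, ], tolerance = 1e-14,
               ignore_attr = TRUE)
  # snr = 1: empirical signal/noise power ratio within 5%
  y1 <- mix_to_sensors(sig$sources, diag(2), snr = 1, seed = 4)
  noise <- attr(y1, "noise")
  clean <- unclass(y1) - noise
  expect_lt(abs(mean(clean^2) / mean(noise^2) - 1), 0.05)
  # two sensors seeing one source: raw sensor correlation ~ 1
  y2 <- mix_to_sensors(sig$sources[1, , drop = FALSE],
                       matrix(1, 2, 1), snr = Inf)
  expect_gt(cor(y2[1, ], y2[2, ]), 0.999)
  expect_error(mix_to_sensors(sig$sources, diag(2), snr = -1), "snr")
  expect_error(mix_to_sensors(sig$sources, diag(3)), "dimensions")
})

test_that("cohorts carry correct group structure and per-group effects", {
  spec <- data.frame(roi_i = 1, roi_j = 2, rho = 0.8)
  cc <- sim_config(n_subjects_per_group = 5, groups = c("HC", "CS", "SS"),
                   n_rois = 2, dipoles_per_roi = 1, n_sensors = 4,
                   n_epochs = 3, band = c(13, 30), coupling_spec = spec,
                   group_effects = list(CS = list(edges = 1, rho_scale = 0.5)),
                   seed = 8)
  coh <- generate_cohort(cc)
  expect_length(coh$subjects, 15)
  expect_identical(coh$labels, rep(c("HC", "CS", "SS"), each = 5))
  rho_by_group <- tapply(
    vapply(coh$subjects, function(s) s$ground_truth$rho_realized, numeric(1)),
    coh$labels, mean)
  expect_lt(abs(rho_by_group[["HC"]] - 0.8), 0.05)
  expect_lt(abs(rho_by_group[["CS"]] - 0.4), 0.05)
  expect_lt(abs(rho_by_group[["SS"]] - 0.8), 0.05)
})

test_that("feature-level generator plants group means where requested", {
  ef <- generate_edge_features(10, groups = c("A", "B"), n_edges = 50,
                               planted_edges = 1:5,
                               group_means = list(B = 0.8),
                               base_mean = 0.2, noise_sd = 0.05, seed = 3)
  expect_equal(dim(ef$values), c(20, 50))
  mB <- colMeans(ef$values[ef$group == "B", 1:5])
  mA <- colMeans(ef$values[ef$group == "A", 1:5])
  expect_true(all(abs(mB - 0.8) < 0.1))
  expect_true(all(abs(mA - 0.2) < 0.1))
  m_null <- colMeans(ef$values[, 6:50])
  expect_lt(max(abs(m_null - 0.2)), 0.1)
})
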