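# Synthetic task-EEG cohort generator.
#
# Each ROI carries a band-limited oscillatory signal whose amplitude follows
# a log-normal envelope: a smooth standard-normal process (Gaussian low-pass
# filtered white noise, cutoff = band centre / 10) is exponentiated and
# multiplies a constant-modulus random-phase carrier derived from band-passed
# white noise. Planted couplings are correlations between ROI *log*-envelopes,
# so the log transform applied by the connectivity stage sees exactly Gaussian
# envelopes with the requested correlation structure. Carrier phases are
# independent across ROIs (no zero-lag carrier correlation), so any raw
# zero-lag correlation downstream comes from lead-field mixing alone.

#' Simulation configuration for a synthetic task-EEG cohort
#'
#' @param n_subjects_per_group Subjects per group.
#' @param groups Group labels (default HC, CS, SS).
#' @param n_sensors Sensor count.
#' @param n_rois ROI (network node) count, default 68.
#' @param dipoles_per_roi Source dipoles per ROI (default 3); each carries the
#'   ROI signal plus small private band-limited noise.
#' @param fs Sampling rate in Hz (default 256); must exceed twice the upper
#'   band edge.
#' @param n_epochs Stimulus epochs per subject.
#' @param epoch_window Epoch window in ms (default `c(-100, 500)`).
#' @param band Carrier band in Hz (default beta, `c(13, 30)`).
#' @param coupling_spec Data frame with columns `roi_i`, `roi_j`, `rho`
#'   (1-based ROI indices, `rho` in \[0, 1\]) listing planted log-envelope
#'   correlations; `NULL` for none.
#' @param group_effects Named list, one entry per affected group, each a list
#'   with `edges` (row indices into `coupling_spec`) and `rho_scale`
#'   (multiplier applied to those planted correlations for that group).
#' @param snr Sensor signal-to-noise power ratio (`Inf` for noiseless).
#' @param private_noise Amplitude of per-dipole private noise relative to the
#'   ROI signal RMS (default 0.1).
#' @param isi_ms Inter-stimulus-interval range in ms (default `c(800, 1200)`).
#' @param seed Master seed; fixed seed reproduces the cohort exactly.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_subjects_per_group = 5L,
                       groups = c("HC", "CS", "SS"),
                       n_sensors = 32L,
                       n_rois = 68L,
                       dipoles_per_roi = 3L,
                       fs = 256,
                       n_epochs = 30L,
                       epoch_window = c(-100, 500),
                       band = c(13, 30),
                       coupling_spec = NULL,
                       group_effects = NULL,
                       snr = 5,
                       private_noise = 0.1,
                       isi_ms = c(800, 1200),
                       seed = 1L) {
  if (length(groups) < 1L || n_subjects_per_group < 1L)
    stop("cohort must contain at least one subject in at least one group")
  if (fs <= 2 * band[2])
    stop("fs must exceed twice the upper band edge (aliasing)")
  if (!is.null(coupling_spec)) {
    coupling_spec <- as.data.frame(coupling_spec)
    stopifnot(all(c("roi_i", "roi_j", "rho") %in% names(coupling_spec)))
    if (any(coupling_spec$rho < 0 | coupling_spec$rho > 1))
      stop("planted rho must lie in [0, 1]")
    if (any(coupling_spec$roi_i < 1 | coupling_spec$roi_i > n_rois |
            coupling_spec$roi_j < 1 | coupling_spec$roi_j > n_rois))
      stop("coupling ROI indices must lie in 1..n_rois")
    if (any(coupling_spec$roi_i == coupling_spec$roi_j))
      stop("coupling pairs must join distinct ROIs")
  }
  if (!is.null(group_effects)) {
    stopifnot(!is.null(names(group_effects)),
              all(names(group_effects) %in% groups))
  }
  if (snr <= 0) stop("snr must be positive")
  structure(list(
    n_subjects_per_group = as.integer(n_subjects_per_group), groups = groups,
    n_sensors = as.integer(n_sensors), n_rois = as.integer(n_rois),
    dipoles_per_roi = as.integer(dipoles_per_roi), fs = fs,
    n_epochs = as.integer(n_epochs), epoch_window = epoch_window,
    band = band, coupling_spec = coupling_spec, group_effects = group_effects,
    snr = snr, private_noise = private_noise, isi_ms = isi_ms,
    seed = as.integer(seed)), class = "sim_config")
}

# smooth standard-normal process: Gaussian low-pass filtered white noise,
# re-standardized to zero mean / unit variance
.smooth_normal <- function(n_series, n_samples, fs, cutoff) {
  z <- matrix(stats::rnorm(n_series * n_samples), nrow = n_series)
  z <- .gaussian_lowpass_rows(z, fs, cutoff)
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  z <- (z - rowMeans(z)) / apply(z, 1L, stats::sd)
  z
}

# constant-modulus random-phase carrier: band-passed white noise, analytic
# signal, modulus normalized to 1; the phase trajectory spans the band
.phase_carrier <- function(n_series, n_samples, fs, band) {
  w <- matrix(stats::rnorm(n_series * n_samples), nrow = n_series)
  w <- bandpass(w, fs, band[1], band[2])
  if (is.null(dim(w))) w <- matrix(w, nrow = 1L)
  a <- .analytic_rows(w)
  Re(a / pmax(Mod(a), 1e-300))
}

#' Generate one subject's dipole source signals with planted envelope couplings
#'
#' Builds per-ROI log-normal amplitude envelopes whose log-envelope
#' correlation matrix equals the (possibly group-perturbed) coupling spec
#' (identity off the planted pairs), modulates independent constant-modulus
#' band-limited carriers, and replicates each ROI signal onto its dipoles
#' with small private noise.
#'
#' @param config A [sim_config()].
#' @param subject_seed Integer seed for this subject.
#' @param n_samples Number of samples to generate (defaults to enough for the
#'   configured epochs; can be set directly for continuous-signal studies).
#' @param coupling Optional coupling spec overriding `config$coupling_spec`
#'   (used internally for group effects).
#' @return List with `sources` (dipoles x samples), `roi_signals` (ROIs x
#'   samples, the coupled signals before dipole replication and private
#'   noise), `roi_labels` (dipole -> ROI index), `latent_log_envelopes`
#'   (ROIs x samples), `onsets` (stimulus sample indices), and
#'   `ground_truth` (data frame of planted pairs with realized latent
#'   correlations).
#' @export
generate_source_signals <- function(config, subject_seed,
                                    n_samples = NULL, coupling = NULL) {
  stopifnot(inherits(config, "sim_config"))
  oldseed <- .snapshot_rng()
  on.exit(.restore_rng(oldseed))
  set.seed(subject_seed)
  fs <- config$fs
  if (is.null(coupling)) coupling <- config$coupling_spec
  if (is.null(n_samples)) {
    isi <- stats::runif(config$n_epochs, config$isi_ms[1], config$isi_ms[2])
    onsets <- round(cumsum(isi) * fs / 1000) + fs  # 1 s lead-in
    n_samples <- max(onsets) + fs                   # 1 s tail
  } else {
    onsets <- integer(0)
  }
  R <- config$n_rois
  centre <- mean(config$band)
  env_cut <- centre / 10

  # target log-envelope correlation matrix: identity + planted rho
  C <- diag(R)
  if (!is.null(coupling) && nrow(coupling) > 0L) {
    for (k in seq_len(nrow(coupling)))
      C[coupling$roi_i[k], coupling$roi_j[k]] <-
        C[coupling$roi_j[k], coupling$roi_i[k]] <- coupling$rho[k]
  }
  ch <- tryCatch(chol(C), error = function(e)
    stop("coupling spec is not realizable as a correlation matrix"))
  z <- .smooth_normal(R, n_samples, fs, env_cut)
  # empirical whitening: plant the *sample* correlation structure exactly,
  # so realized latent couplings equal the requested rho (not just in
  # expectation) whenever enough samples are available
  if (n_samples > 2L * R) {
    S <- tcrossprod(z) / n_samples
    z <- solve(t(chol(S)), z)
  }
  log_env <- t(ch) %*% z                       # rows correlated per C
  carriers <- .phase_carrier(R, n_samples, fs, config$band)
  roi_sig <- exp(log_env) * carriers

  D <- config$dipoles_per_roi
  roi_labels <- rep(seq_len(R), each = D)
  sources <- roi_sig[roi_labels, , drop = FALSE]
  if (config$private_noise > 0) {
    priv <- .phase_carrier(R * D, n_samples, fs, config$band)
    rms <- sqrt(rowMeans(sources^2))
    sources <- sources + config$private_noise * rms * priv
  }

  gt <- NULL
  if (!is.null(coupling) && nrow(coupling) > 0L) {
    gt <- coupling
    gt$rho_realized <- vapply(seq_len(nrow(coupling)), function(k)
      stats::cor(log_env[coupling$roi_i[k], ], log_env[coupling$roi_j[k], ]),
      numeric(1))
  }
  list(sources = sources, roi_signals = roi_sig, roi_labels = roi_labels,
       latent_log_envelopes = log_env, onsets = onsets,
       ground_truth = gt, fs = fs, band = config$band)
}

#' Synthetic lead field with random orthogonal orientation triads
#'
#' Builds a sensors x (dipoles * 3) gain matrix: per dipole, a random
#' sensor profile smoothed across the sensor index, orthonormalized into a
#' 3-column triad and scaled by a random depth-like gain, plus a fixed random
#' unit orientation used when projecting scalar source activity to sensors.
#'
#' @param n_sensors,n_dipoles Dimensions.
#' @param seed Seed.
#' @return A `lead_field` object (list with `gain`, `orientation`,
#'   `n_dipoles`).
#' @export
synthetic_leadfield <- function(n_sensors, n_dipoles, seed = 1L) {
  oldseed <- .snapshot_rng()
  on.exit(.restore_rng(oldseed))
  set.seed(seed)
  gain <- matrix(0, n_sensors, 3L * n_dipoles)
  orientation <- matrix(0, n_dipoles, 3L)
  for (d in seq_len(n_dipoles)) {
    M <- matrix(stats::rnorm(n_sensors * 3L), n_sensors, 3L)
    # smooth across the sensor index so nearby sensors see similar gains
    M <- apply(M, 2L, function(col) as.numeric(stats::filter(
      col, rep(1 / 3, 3), sides = 2, circular = TRUE)))
    qr_ <- qr(M)
    Q <- qr.Q(qr_)
    g <- exp(stats::rnorm(1L, 0, 0.3))
    gain[, (3L * (d - 1L) + 1L):(3L * d)] <- Q * g
    v <- stats::rnorm(3L)
    orientation[d, ] <- v / sqrt(sum(v^2))
  }
  lead_field(gain, orientation)
}

#' Lead-field container
#'
#' @param gain Sensors x (dipoles * 3) matrix; three consecutive columns per
#'   dipole (free orientation).
#' @param orientation Optional dipoles x 3 matrix of true source orientations
#'   (used only when mixing synthetic scalar sources to sensors).
#' @return A `lead_field` object.
#' @export
lead_field <- function(gain, orientation = NULL) {
  stopifnot(is.matrix(gain), all(is.finite(gain)))
  if (ncol(gain) %% 3L != 0L)
    stop("lead-field column count must be divisible by 3 (free orientation)")
  n_dipoles <- ncol(gain) / 3L
  if (!is.null(orientation))
    stopifnot(nrow(orientation) == n_dipoles, ncol(orientation) == 3L)
  structure(list(gain = gain, orientation = orientation,
                 n_dipoles = n_dipoles), class = "lead_field")
}

#' @export
print.lead_field <- function(x, ...) {
  cat(sprintf("<lead_field> %d sensors x %d dipoles (x3 orientations)\n",
              nrow(x$gain), x$n_dipoles))
  invisible(x)
}

#' Project scalar dipole sources to sensors and epoch
#'
#' Instantaneous (zero-lag) mixing `sensors = G_eff sources` with
#' `G_eff[, d] = gain_block_d orientation_d`, plus white Gaussian sensor
#' noise scaled so that total signal power / total noise power equals `snr`.
#'
#' @param sources Dipoles x samples matrix (e.g. from
#'   [generate_source_signals()]).
#' @param leadfield A `lead_field` with `orientation` set, or a plain
#'   sensors x dipoles effective-gain matrix.
#' @param snr Signal-to-noise power ratio (`Inf` disables noise).
#' @param seed Seed for the sensor noise.
#' @param onsets Optional stimulus onsets; when given the continuous sensor
#'   record is epoched with [epoch_and_baseline()].
#' @param fs Sampling rate (needed when epoching).
#' @param epoch_window,baseline Epoch windows in ms.
#' @return A `sensor_epochs` object when `onsets` is given, otherwise the
#'   continuous sensors x samples matrix (with attribute `"noise"` holding
#'   the realized noise matrix for power checks).
#' @export
mix_to_sensors <- function(sources, leadfield, snr = 5, seed = 1L,
                           onsets = NULL, fs = NULL,
                           epoch_window = c(-100, 500),
                           baseline = c(-100, 0)) {
  if (snr <= 0) stop("snr must be positive")
  if (inherits(leadfield, "lead_field")) {
    if (is.null(leadfield$orientation))
      stop("lead_field needs `orientation` to mix scalar sources")
    G <- effective_gain(leadfield)
  } else {
    G <- leadfield
  }
  if (ncol(G) != nrow(sources)) stop("lead field / source dimensions disagree")
  y <- G %*% sources
  noise <- matrix(0, nrow(y), ncol(y))
  if (is.finite(snr)) {
    oldseed <- .snapshot_rng()
    on.exit(.restore_rng(oldseed))
    set.seed(seed)
    noise <- matrix(stats::rnorm(length(y)), nrow(y))
    p_sig <- mean(y^2)
    noise <- noise * sqrt(p_sig / (snr * mean(noise^2)))
    y <- y + noise
  }
  if (is.null(onsets) || length(onsets) == 0L) {
    attr(y, "noise") <- noise
    return(y)
  }
  stopifnot(!is.null(fs))
  epoch_and_baseline(y, fs, onsets, epoch_window, baseline)
}

#' Sensors x dipoles effective gain of a synthetic lead field
#'
#' Collapses each dipole's 3 orientation columns onto its true orientation.
#'
#' @param leadfield A `lead_field` with `orientation`.
#' @return Sensors x dipoles matrix.
#' @export
effective_gain <- function(leadfield) {
  stopifnot(inherits(leadfield, "lead_field"),
            !is.null(leadfield$orientation))
  G <- matrix(0, nrow(leadfield$gain), leadfield$n_dipoles)
  for (d in seq_len(leadfield$n_dipoles))
    G[, d] <- leadfield$gain[, (3L * (d - 1L) + 1L):(3L * d)] %*%
      leadfield$orientation[d, ]
  G
}

#' Generate a full synthetic cohort
#'
#' Applies per-group effects to the coupling spec, derives per-subject seeds
#' deterministically from the master seed, and produces epoched sensor
#' recordings plus ground truth for every subject.
#'
#' @param config A [sim_config()].
#' @param leadfield Optional shared `lead_field`; defaults to a
#'   [synthetic_leadfield()] drawn from the master seed.
#' @param keep_sources Keep each subject's dipole source matrix (memory-heavy;
#'   default FALSE).
#' @return A `cohort` object: list with `subjects` (each: `id`, `group`,
#'   `seed`, `epochs` (sensor_epochs), `ground_truth`), `labels`, `config`,
#'   `leadfield`, `roi_labels`.
#' @export
generate_cohort <- function(config, leadfield = NULL, keep_sources = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(leadfield))
    leadfield <- synthetic_leadfield(config$n_sensors,
                                     config$n_rois * config$dipoles_per_roi,
                                     seed = config$seed)
  subjects <- list()
  labels <- character(0)
  k <- 0L
  for (g in config$groups) {
    coup <- config$coupling_spec
    eff <- config$group_effects[[g]]
    if (!is.null(eff) && !is.null(coup)) {
      rows <- if (is.null(eff$edges)) seq_len(nrow(coup)) else eff$edges
      coup$rho[rows] <- pmin(1, pmax(0, coup$rho[rows] * eff$rho_scale))
    }
    for (s in seq_len(config$n_subjects_per_group)) {
      k <- k + 1L
      sseed <- .derive_seed(config$seed, k)
      sig <- generate_source_signals(config, sseed, coupling = coup)
      epochs <- mix_to_sensors(sig$sources, leadfield, snr = config$snr,
                               seed = .derive_seed(sseed, 1L),
                               onsets = sig$onsets, fs = config$fs,
                               epoch_window = config$epoch_window)
      subj <- list(id = sprintf("%s%02d", g, s), group = g, seed = sseed,
                   epochs = epochs, ground_truth = sig$ground_truth)
      if (keep_sources) subj$sources <- sig$sources
      subjects[[k]] <- subj
      labels[k] <- g
    }
  }
  structure(list(subjects = subjects, labels = labels, config = config,
                 leadfield = leadfield,
                 roi_labels = rep(seq_len(config$n_rois),
                                  each = config$dipoles_per_roi)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects (%s), %d sensors, %d ROIs x %d dipoles\n",
              length(x$subjects),
              paste(table(x$labels), names(table(x$labels)), collapse = ", "),
              x$config$n_sensors, x$config$n_rois, x$config$dipoles_per_roi))
  invisible(x)
}

#' Feature-level cohort generator for statistical calibration studies
#'
#' Draws subject x edge connectivity feature tables directly at the estimated
#' PEC level: each edge value is its group mean plus Gaussian estimation
#' noise. Used for scaled-down null-calibration and recovery studies of the
#' statistics and classification stages, where running the full
#' signal-to-connectivity chain per replicate would add nothing but cost.
#'
#' @param n_per_group Subjects per group.
#' @param groups Group labels.
#' @param n_edges Number of edge features.
#' @param planted_edges Indices of edges carrying a group effect.
#' @param group_means Named list: for each group, the mean PEC on planted
#'   edges (unlisted groups use `base_mean`).
#' @param base_mean Mean PEC on unplanted edges / unaffected groups.
#' @param noise_sd Estimation noise SD (default 0.1, the sampling scale of a
#'   pooled-epoch PEC estimate).
#' @param seed Seed.
#' @return List with `values` (subjects x edges), `group` (factor),
#'   `planted_edges`.
#' @export
generate_edge_features <- function(n_per_group, groups = c("HC", "CS", "SS"),
                                   n_edges = 2278L, planted_edges = integer(0),
                                   group_means = list(), base_mean = 0.2,
                                   noise_sd = 0.1, seed = 1L) {
  oldseed <- .snapshot_rng()
  on.exit(.restore_rng(oldseed))
  set.seed(seed)
  n <- n_per_group * length(groups)
  grp <- factor(rep(groups, each = n_per_group), levels = groups)
  mu <- matrix(base_mean, n, n_edges)
  for (g in names(group_means))
    mu[grp == g, planted_edges] <- group_means[[g]]
  values <- mu + matrix(stats::rnorm(n * n_edges, sd = noise_sd), n, n_edges)
  colnames(values) <- paste0("edge", seq_len(n_edges))
  list(values = values, group = grp, planted_edges = planted_edges)
}
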