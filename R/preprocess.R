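#' Canonical EEG frequency bands
#'
#' Fixed band table used throughout the pipeline: delta (1-4 Hz), theta
#' (4-7 Hz), alpha (8-12 Hz), beta (13-30 Hz).
#'
#' @param name Optional band name; if given, the single matching row is
#'   returned as a list with elements `name`, `lo`, `hi`.
#' @return A data.frame of all bands, or a list for one band.
#' @export
#' @examples
#' band_specs()
#' band_specs("alpha")$lo
band_specs <- function(name = NULL) {
  tab <- data.frame(
    name = c("delta", "theta", "alpha", "beta"),
    lo   = c(1, 4, 8, 13),
    hi   = c(4, 7, 12, 30),
    stringsAsFactors = FALSE
  )
  if (is.null(name)) return(tab)
  row <- tab[tab$name == name, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown band: ", name)
  as.list(row)
}

#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) 4th-order Butterworth band-pass per pass,
#' applied to each channel. Zero-phase filtering avoids group-delay
#' distortion of the amplitude envelopes that the connectivity stage relies
#' on.
#'
#' @param x Numeric matrix, channels x samples (a vector is treated as one
#'   channel).
#' @param fs Sampling rate in Hz.
#' @param lo,hi Band edges in Hz; requires `0 < lo < hi < fs/2`.
#' @param order Butterworth order per pass (default 4; effective order is
#'   doubled by the forward-backward application).
#' @return Filtered matrix of the same shape as `x`.
#' @export
bandpass <- function(x, fs, lo, hi, order = 4L) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1L)
  if (!(lo > 0 && lo < hi)) stop("require 0 < lo < hi")
  if (hi >= fs / 2) stop("upper band edge must be below the Nyquist frequency fs/2")
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  pad <- round(3 * fs / lo)             # ~3 time constants of the slow edge
  out <- t(apply(x, 1L, function(ch) .filtfilt_padded(bf, ch, pad)))
  if (vec) out <- drop(out)
  out
}

# zero-phase filtering with mirrored end extensions, so startup transients
# decay inside the padding rather than inside the data
.filtfilt_padded <- function(bf, ch, pad) {
  n <- length(ch)
  pad <- min(pad, n - 1L)
  if (pad > 0L) {
    ext <- c(2 * ch[1L] - ch[(pad + 1L):2L], ch,
             2 * ch[n] - ch[(n - 1L):(n - pad)])
    y <- signal::filtfilt(bf, ext)
    y[(pad + 1L):(pad + n)]
  } else {
    signal::filtfilt(bf, ch)
  }
}

#' Zero-phase low-pass filter (anti-aliasing helper)
#'
#' @inheritParams bandpass
#' @param cutoff Cut-off frequency in Hz.
#' @return Filtered matrix of the same shape as `x`.
#' @export
lowpass <- function(x, fs, cutoff, order = 8L) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1L)
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  pad <- round(3 * fs / cutoff)
  out <- t(apply(x, 1L, function(ch) .filtfilt_padded(bf, ch, pad)))
  if (vec) out <- drop(out)
  out
}

#' Downsample a multichannel series
#'
#' Anti-alias low-pass filtering (zero-phase Butterworth at 0.45 * fs_out)
#' followed by cubic-spline interpolation onto the new sampling grid. The
#' identity is returned when `fs_in == fs_out`.
#'
#' @param x Channels x samples matrix or vector.
#' @param fs_in,fs_out Input and output sampling rates (Hz); `fs_out` must
#'   not exceed `fs_in`.
#' @return Channels x ceil(n * fs_out / fs_in) matrix (or vector).
#' @export
downsample <- function(x, fs_in, fs_out = 256) {
  if (fs_out > fs_in) stop("fs_out must not exceed fs_in")
  if (fs_out == fs_in) return(x)
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1L)
  xf <- lowpass(x, fs_in, 0.45 * fs_out)
  if (is.null(dim(xf))) xf <- matrix(xf, nrow = 1L)
  n_in <- ncol(x)
  t_in <- (seq_len(n_in) - 1L) / fs_in
  n_out <- floor((n_in - 1L) * fs_out / fs_in) + 1L
  t_out <- (seq_len(n_out) - 1L) / fs_out
  out <- t(apply(xf, 1L, function(ch) stats::spline(t_in, ch, xout = t_out)$y))
  if (vec) out <- drop(out)
  out
}

#' Common-average re-referencing
#'
#' Subtracts, at every sample, the instantaneous mean over channels, so the
#' channel mean is zero at each time point. Idempotent.
#'
#' @param x Channels x samples matrix with at least two channels.
#' @return Re-referenced matrix.
#' @export
average_reference <- function(x) {
  if (is.null(dim(x)) || nrow(x) < 2L)
    stop("average referencing needs at least 2 channels")
  sweep(x, 2L, colMeans(x), "-")
}

#' Segment a continuous recording into baseline-corrected epochs
#'
#' Epochs are cut on the closed window `[window[1], window[2]]` ms around
#' each stimulus onset, with boundaries at nearest-sample rounding: with
#' `fs = 256` and the default window, samples `round(-0.1*256) = -26` through
#' `round(0.5*256) = 128` give 155 samples per epoch. Per channel and epoch,
#' the mean over the baseline window is subtracted. Onsets whose window falls
#' outside the recording are dropped with a warning.
#'
#' @param x Channels x samples matrix.
#' @param fs Sampling rate (Hz).
#' @param onsets Integer sample indices (1-based) of stimulus onsets.
#' @param window Epoch window in ms relative to onset, default `c(-100, 500)`.
#' @param baseline Baseline window in ms, default `c(-100, 0)`.
#' @param channel_names Optional channel labels.
#' @param band Band label carried in the result (default "broadband").
#' @return A `sensor_epochs` object: list with `data` (channels x samples x
#'   epochs), `fs`, `epoch_times` (ms), `channel_names`, `band`, `onsets`.
#' @export
epoch_and_baseline <- function(x, fs, onsets, window = c(-100, 500),
                               baseline = c(-100, 0), channel_names = NULL,
                               band = "broadband") {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  n <- ncol(x)
  s0 <- round(window[1] * fs / 1000)
  s1 <- round(window[2] * fs / 1000)
  keep <- onsets + s0 >= 1L & onsets + s1 <= n
  if (any(!keep))
    warning(sum(!keep), " epoch(s) dropped: window outside recording")
  onsets <- onsets[keep]
  if (length(onsets) == 0L) stop("no epochs fit within the recording")
  len <- s1 - s0 + 1L
  times <- (s0:s1) * 1000 / fs
  b_idx <- which(times >= baseline[1] & times <= baseline[2])
  dat <- array(0, dim = c(nrow(x), len, length(onsets)))
  for (e in seq_along(onsets)) {
    seg <- x[, (onsets[e] + s0):(onsets[e] + s1), drop = FALSE]
    seg <- seg - rowMeans(seg[, b_idx, drop = FALSE])
    dat[, , e] <- seg
  }
  sensor_epochs(dat, fs, epoch_times = times, channel_names = channel_names,
                band = band, onsets = onsets)
}

#' Construct a sensor_epochs container
#'
#' @param data Channels x samples x epochs numeric array.
#' @param fs Sampling rate (Hz).
#' @param epoch_times Per-sample time in ms relative to stimulus onset.
#' @param channel_names Optional channel labels.
#' @param band Band label.
#' @param onsets Optional onset sample indices.
#' @return A `sensor_epochs` list object.
#' @export
sensor_epochs <- function(data, fs, epoch_times = NULL, channel_names = NULL,
                          band = "broadband", onsets = NULL) {
  stopifnot(length(dim(data)) == 3L)
  if (any(!is.finite(data))) stop("non-finite values in epoch data")
  if (is.null(epoch_times))
    epoch_times <- (seq_len(dim(data)[2]) - 1L) * 1000 / fs
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(dim(data)[1]))
  structure(list(data = data, fs = fs, epoch_times = epoch_times,
                 channel_names = channel_names, band = band, onsets = onsets),
            class = "sensor_epochs")
}

#' @export
print.sensor_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<sensor_epochs> %d channels x %d samples x %d epochs @ %g Hz, band=%s\n",
              d[1], d[2], d[3], x$fs, x$band))
  invisible(x)
}

#' Split epoched data into the four canonical bands
#'
#' Applies [bandpass()] epoch-wise for each band of [band_specs()]. Filtering
#' short epochs incurs edge effects; in the standard pipeline the band filter
#' is applied to the continuous record *before* epoching (see
#' [preprocess_subject()]), and this helper exists for already-epoched input.
#'
#' @param epochs A `sensor_epochs` object.
#' @param bands Band names (default all four).
#' @return Named list of `sensor_epochs`, one per band.
#' @export
band_split <- function(epochs, bands = band_specs()$name) {
  stopifnot(inherits(epochs, "sensor_epochs"))
  out <- lapply(bands, function(b) {
    sp <- band_specs(b)
    dat <- epochs$data
    for (e in seq_len(dim(dat)[3]))
      dat[, , e] <- bandpass(dat[, , e, drop = TRUE], epochs$fs, sp$lo, sp$hi)
    sensor_epochs(dat, epochs$fs, epochs$epoch_times, epochs$channel_names,
                  band = b, onsets = epochs$onsets)
  })
  names(out) <- bands
  out
}

#' Amplitude-threshold epoch rejection
#'
#' Automatic stand-in for manual visual inspection: an epoch is rejected if
#' any sample of any channel exceeds `k` times that channel's MAD (computed
#' over all epochs pooled).
#'
#' @param epochs A `sensor_epochs` object.
#' @param k Rejection multiplier (default 8).
#' @return The `sensor_epochs` with rejected epochs removed; attribute
#'   `"rejected"` holds the rejected epoch indices.
#' @export
reject_epochs <- function(epochs, k = 8) {
  stopifnot(inherits(epochs, "sensor_epochs"))
  d <- dim(epochs$data)
  flat <- matrix(epochs$data, nrow = d[1])
  thr <- k * apply(flat, 1L, stats::mad)
  bad <- logical(d[3])
  for (e in seq_len(d[3]))
    bad[e] <- any(abs(epochs$data[, , e]) > thr)
  if (all(bad)) stop("all epochs rejected at k = ", k)
  if (any(bad)) warning(sum(bad), " epoch(s) rejected by amplitude threshold")
  out <- sensor_epochs(epochs$data[, , !bad, drop = FALSE], epochs$fs,
                       epochs$epoch_times, epochs$channel_names, epochs$band,
                       epochs$onsets[!bad])
  attr(out, "rejected") <- which(bad)
  out
}

#' Full preprocessing chain for one continuous recording
#'
#' Broadband filter (1-40 Hz), downsample to `fs_out`, common-average
#' reference, band filter on the continuous record, then epoch with baseline
#' correction — the standard order for task EEG (filtering before epoching
#' avoids filter edge effects inside short epochs).
#'
#' @param x Channels x samples continuous recording.
#' @param fs Input sampling rate (Hz).
#' @param onsets Stimulus onset sample indices at the *input* rate.
#' @param band Band name from [band_specs()], or "broadband" to skip the
#'   band-specific filter.
#' @param fs_out Target rate (default 256 Hz).
#' @param window,baseline Epoching windows in ms.
#' @return A `sensor_epochs` object at `fs_out` for the requested band.
#' @export
preprocess_subject <- function(x, fs, onsets, band = "broadband",
                               fs_out = 256, window = c(-100, 500),
                               baseline = c(-100, 0)) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  hi_broad <- min(40, 0.98 * fs_out / 2)
  x <- bandpass(x, fs, 1, hi_broad)
  if (fs != fs_out) {
    x <- downsample(x, fs, fs_out)
    onsets <- pmax(1L, round((onsets - 1L) * fs_out / fs) + 1L)
  }
  if (nrow(x) >= 2L) x <- average_reference(x)
  if (!identical(band, "broadband")) {
    sp <- band_specs(band)
    x <- bandpass(x, fs_out, sp$lo, sp$hi)
  }
  epoch_and_baseline(x, fs_out, onsets, window, baseline, band = band)
}
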