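# Shared numeric helpers: FFT-based analytic signal and zero-phase Gaussian
# low-pass, both with mirror padding so short epochs keep clean edges.

# Mirror-pad each row of a matrix on both sides, choosing the total length
# as the next 2-3-5-smooth integer >= 2n so the FFT stays O(n log n)
# (mixed-radix FFTs degrade badly on lengths with large prime factors).
.mirror_pad <- function(x) {
  n <- ncol(x)
  total <- stats::nextn(2L * n, c(2L, 3L, 5L))
  padl <- max(0L, min((total - n) %/% 2L, n - 1L))
  padr <- max(0L, min(total - n - padl, n - 1L))
  left <- if (padl > 0L) x[, padl:1, drop = FALSE] else x[, 0, drop = FALSE]
  right <- if (padr > 0L) x[, n:(n - padr + 1L), drop = FALSE]
           else x[, 0, drop = FALSE]
  list(x = cbind(left, x, right), pad = padl)
}

# Analytic signal of each row via FFT: real part is the input, imaginary part
# its Hilbert transform. Mirror padding suppresses wrap-around edge effects.
.analytic_rows <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  n0 <- ncol(x)
  mp <- .mirror_pad(x)
  n <- ncol(mp$x)
  X <- t(stats::mvfft(t(mp$x)))
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2 + 1L] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  Z <- t(stats::mvfft(t(X * rep(h, each = nrow(x))), inverse = TRUE)) / n
  Z[, (mp$pad + 1L):(mp$pad + n0), drop = FALSE]
}

# Zero-phase Gaussian low-pass on each row (|H(f)| = exp(-ln2 (f/cutoff)^2),
# half power at `cutoff`), FFT-applied after mirror padding. Numerically
# stable at arbitrarily low cutoffs, unlike high-order IIR designs.
.gaussian_lowpass_rows <- function(x, fs, cutoff) {
  if (is.null(dim(x))) {
    out <- .gaussian_lowpass_rows(matrix(x, nrow = 1L), fs, cutoff)
    return(drop(out))
  }
  n0 <- ncol(x)
  mp <- .mirror_pad(x)
  n <- ncol(mp$x)
  f <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1L):-1L) * fs / n
  H <- exp(-log(2) * (f / cutoff)^2)
  X <- t(stats::mvfft(t(mp$x)))
  Y <- Re(t(stats::mvfft(t(X * rep(H, each = nrow(x))), inverse = TRUE)) / n)
  Y[, (mp$pad + 1L):(mp$pad + n0), drop = FALSE]
}

#' Row-major upper-triangle vector of a square matrix
#'
#' Extracts the strictly-upper-triangular entries in row-major order:
#' (1,2), (1,3), ..., (1,N), (2,3), ..., (N-1,N). For N = 68 nodes this is
#' the 2278-element connectivity feature vector.
#'
#' @param M Square matrix.
#' @return Numeric vector of length `N (N - 1) / 2`.
#' @export
upper_tri_vec <- function(M) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  tM <- t(M)
  tM[lower.tri(tM)]
}

#' Indices (i, j) corresponding to [upper_tri_vec()] positions
#'
#' @param n Node count.
#' @return Two-column integer matrix, one row per feature, row-major order.
#' @export
upper_tri_index <- function(n) {
  idx <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  cbind(i = idx[, "col"], j = idx[, "row"])[order(idx[, "col"], idx[, "row"]), ,
                                            drop = FALSE]
}

# deterministic per-subject seed derivation, kept < 2^31
.derive_seed <- function(master, k) {
  as.integer((as.numeric(master) + 7919 * as.numeric(k)) %% 2147483629)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream:
# the global .Random.seed is saved and restored, so seeded internals never
# silently reset a user's simulation sequence.
.with_seed <- function(seed, expr) {
  old <- .snapshot_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  expr
}

.snapshot_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    rm(".Random.seed", envir = globalenv())
}
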