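#' Time-delay embedding of a scalar series
#'
#' Reconstructs the m-dimensional phase-space trajectory of a scalar series
#' by delay coordinates (Takens): point k has coordinates
#' (u_k, u_{k+tau}, ..., u_{k+(m-1)tau}), giving N = L - (m-1) tau points.
#'
#' @param series Numeric vector (length L), or an [fhr_record].
#' @param m Embedding dimension, integer >= 2.
#' @param tau Delay in samples, integer >= 1.
#' @return An N x m numeric matrix of class `phase_trajectory` (one row per
#'   phase-space point), with `m` and `tau` attributes.
#' @export
#' @examples
#' embed_delay(1:5, m = 2, tau = 1)
embed_delay <- function(series, m, tau) {
  if (is_fhr_record(series)) series <- series$samples
  m <- check_count(m, "m", lower = 2L)
  tau <- check_count(tau, "tau", lower = 1L)
  L <- length(series)
  N <- L - (m - 1L) * tau
  min_len <- (m - 1L) * tau + 2L
  if (N < 2L)
    abort(sprintf("series too short: need at least %d samples for m=%d, tau=%d",
                  min_len, m, tau))
  traj <- vapply(seq_len(m) - 1L,
                 function(d) series[(1L + d * tau):(N + d * tau)],
                 numeric(N))
  structure(traj, m = m, tau = tau, class = c("phase_trajectory", "matrix"))
}

#' Per-point k-nearest-neighbour recurrence thresholds
#'
#' For each phase-space point, the threshold epsilon_i is the Euclidean
#' distance to its k-th nearest neighbour among the other N-1 points (self
#' excluded, ties resolved by sorted distance order). Fixing the neighbour
#' count per point (the FAN criterion) makes every row of the recurrence
#' matrix contain the same number of recurrences.
#'
#' @param traj A [embed_delay()] trajectory (N x m matrix).
#' @param k Neighbour count, 1 <= k <= N - 1.
#' @return Numeric vector of N thresholds.
#' @export
knn_epsilon <- function(traj, k) {
  traj <- as.matrix(traj)
  N <- nrow(traj)
  k <- check_count(k, "k")
  if (k > N - 1L) abort(sprintf("k must be <= N - 1 = %d", N - 1L))
  d <- as.matrix(stats::dist(traj))
  vapply(seq_len(N), function(i) sort(d[i, -i], partial = k)[k], numeric(1))
}

#' Recurrence matrix
#'
#' Binary matrix R with R\[i, j\] = Theta(epsilon_i - ||x_i - x_j||) where
#' Theta is the strict Heaviside step (Theta(0) = 0) and the norm is
#' Euclidean. With per-point thresholds the matrix is generally asymmetric;
#' with a single global epsilon it is symmetric.
#'
#' @param traj A trajectory matrix (N x m).
#' @param epsilon Either one global threshold or a vector of N per-point
#'   thresholds (row i is thresholded at `epsilon[i]`).
#' @return An N x N integer matrix of class `recurrence_matrix` with the
#'   thresholds attached as the `epsilon` attribute.
#' @export
#' @examples
#' tr <- embed_delay(c(0, 1, 2, 3, 4), m = 2, tau = 1)
#' recurrence_matrix(tr, knn_epsilon(tr, 1))
recurrence_matrix <- function(traj, epsilon) {
  traj <- as.matrix(traj)
  N <- nrow(traj)
  if (!length(epsilon) %in% c(1L, N))
    abort(sprintf("`epsilon` must have length 1 or N = %d", N))
  d <- as.matrix(stats::dist(traj))
  R <- matrix(0L, N, N)
  R[d < rep(epsilon, length.out = N)] <- 1L  # column recycling: thresholds by row
  structure(R, epsilon = as.numeric(epsilon), class = c("recurrence_matrix", "matrix"))
}

# Fractional-overlap resampling weights: W is size x N, W[a, i] = overlap of
# pixel a (covering [a*N/size, (a+1)*N/size) in cell units) with cell i.
# Columns sum to 1, so area-weighted resampling preserves mean intensity.
resample_weights <- function(N, size) {
  scale <- size / N
  W <- matrix(0, size, N)
  for (i in seq_len(N)) {
    lo <- (i - 1) * scale; hi <- i * scale
    for (a in seq.int(floor(lo), min(size - 1, ceiling(hi) - 1))) {
      ov <- min(hi, a + 1) - max(lo, a)
      if (ov > 0) W[a + 1L, i] <- ov
    }
  }
  W
}

#' Render a recurrence matrix as a fixed-size intensity image
#'
#' Maps recurrences (1) to white and non-recurrences (0) to black. When the
#' matrix size N differs from the requested image size, the binary matrix is
#' resampled by exact area averaging: each pixel's intensity is the
#' area-weighted mean of the binary cells it covers, so the image mean equals
#' the recurrence rate of the matrix and no re-thresholding occurs
#' (integer-ratio upsampling reduces to pixel replication).
#'
#' @param R A [recurrence_matrix()] (or any numeric square matrix in \[0,1\]).
#' @param size Output image side length in pixels (default 64).
#' @return A `size` x `size` numeric matrix of class `rp_image` with
#'   intensities in \[0, 1\]; row 1 is trajectory index 1. The 3-channel form
#'   consumed by the classifier is materialised later by channel replication
#'   (see [images_to_batch()]).
#' @export
render_rp <- function(R, size = 64) {
  size <- check_count(size, "size")
  R <- unclass(R); attr(R, "epsilon") <- NULL
  N <- nrow(R)
  if (is.null(N) || N != ncol(R)) abort("`R` must be a square matrix")
  if (N == size) {
    img <- R * 1.0
  } else {
    W <- resample_weights(N, size)
    # W carries pixel-unit overlaps, so this is already the area-weighted
    # mean over each pixel's footprint
    img <- W %*% R %*% t(W)
    # clip floating-point fuzz at the [0, 1] boundaries
    img[img < 0] <- 0; img[img > 1] <- 1
  }
  structure(img, class = c("rp_image", "matrix"))
}

#' Recurrence-plot image straight from a signal
#'
#' Fused pipeline `embed_delay()` -> `knn_epsilon()` -> `recurrence_matrix()`
#' -> `render_rp()`, computed in C++ without materialising the N x N matrix,
#' so 13-minute records (N ~ 3000) convert in well under a second. Agrees
#' with the four-step composition to floating-point accuracy.
#'
#' @param record An [fhr_record] (preprocessed) or numeric vector.
#' @param m,tau,k Embedding dimension, delay (samples) and neighbour count.
#' @param size Image side length (default 64).
#' @param mode `"per-point"` (default) thresholds row i at the distance to
#'   point i's k-th nearest neighbour; `"global"` uses the mean of those
#'   thresholds everywhere, giving a symmetric plot.
#' @return An `rp_image` with the generating parameters attached as the
#'   `params` attribute.
#' @export
#' @examples
#' rec <- generate_fhr(synth_config("normal", duration_s = 120, seed = 5,
#'                                  dropout_rate = 0, spike_rate = 0))
#' img <- signal_to_rp(rec, m = 2, tau = 1, k = 6)
#' mean(img)
signal_to_rp <- function(record, m = 2, tau = 1, k = 6, size = 64,
                         mode = c("per-point", "global")) {
  mode <- match.arg(mode)
  u <- if (is_fhr_record(record)) record$samples else as.numeric(record)
  m <- check_count(m, "m", lower = 2L)
  tau <- check_count(tau, "tau", lower = 1L)
  k <- check_count(k, "k")
  size <- check_count(size, "size")
  N <- length(u) - (m - 1L) * tau
  if (N < 2L)
    abort(sprintf("series too short: need at least %d samples for m=%d, tau=%d",
                  (m - 1L) * tau + 2L, m, tau))
  if (k > N - 1L) abort(sprintf("k must be <= N - 1 = %d", N - 1L))
  img <- cpp_signal_rp(u, m, tau, k, size, mode == "global")
  img[img < 0] <- 0; img[img > 1] <- 1
  structure(img, params = list(m = m, tau = tau, k = k, mode = mode),
            class = c("rp_image", "matrix"))
}

#' Recurrence rate of a matrix or image
#'
#' Fraction of recurrent (white) area; invariant under the area-averaging
#' resampling used by [render_rp()].
#'
#' @param x A `recurrence_matrix` or `rp_image`.
#' @return A single number in \[0, 1\].
#' @export
recurrence_rate <- function(x) mean(unclass(x))

#' @export
print.rp_image <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("<rp_image> %d x %d, mean intensity %.4f", nrow(x), ncol(x),
              mean(unclass(x))))
  if (!is.null(p))
    cat(sprintf("  (m=%d, tau=%d, k=%d, %s)", p$m, p$tau, p$k, p$mode))
  cat("\n")
  invisible(x)
}
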