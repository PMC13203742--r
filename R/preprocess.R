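#' Preprocessing configuration
#'
#' @param accumulation_window Sliding-window length m in frames. The
#'   default of 13 frames matches the minimum reported astrocytic event
#'   duration (about 333 ms) at 40 Hz.
#' @param accumulation_stride Sliding interval in frames.
#' @param gaussian_sigma Spatial smoothing width in pixels.
#' @param use_gat Insert a generalized Anscombe transform between frame
#'   accumulation and background subtraction.
#' @param gat_gain,gat_read_noise_sigma Poisson gain and read-noise sigma
#'   used by the transform (normally the simulator's noise parameters).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(accumulation_window = 13L,
                              accumulation_stride = 1L,
                              gaussian_sigma = 1.0,
                              use_gat = FALSE,
                              gat_gain = 0.020,
                              gat_read_noise_sigma = 15) {
  cfg <- list(accumulation_window = as.integer(accumulation_window),
              accumulation_stride = as.integer(accumulation_stride),
              gaussian_sigma = gaussian_sigma,
              use_gat = isTRUE(use_gat),
              gat_gain = gat_gain,
              gat_read_noise_sigma = gat_read_noise_sigma)
  if (cfg$accumulation_window < 1L) stop("accumulation_window must be >= 1")
  if (cfg$accumulation_stride < 1L) stop("accumulation_stride must be >= 1")
  if (cfg$gaussian_sigma <= 0) stop("gaussian_sigma must be > 0")
  class(cfg) <- "preprocess_config"
  cfg
}

#' Promote an 8-bit sequence to 16-bit
#'
#' Values are unchanged; only the declared bit depth widens, so that
#' subsequent m-frame sums (at most 255 * m) cannot saturate.
#'
#' @param seq An 8-bit [frame_sequence].
#' @return The same sequence declared 16-bit.
#' @export
promote_bit_depth <- function(seq) {
  stopifnot(inherits(seq, "frame_sequence"))
  if (seq$bit_depth == 16L) {
    warning("sequence is already 16-bit; returning it unchanged")
    return(seq)
  }
  fs_replace(seq, seq$frames, bit_depth = 16L)
}

#' Sliding-window frame accumulation
#'
#' Output frame j is the sum of input frames `(j-1)*stride + 1` through
#' `(j-1)*stride + m`; with stride 1 this is a length-m sliding sum that
#' boosts a persistent signal by m while i.i.d. noise grows only by
#' sqrt(m). Output length is `floor((T - m) / stride) + 1`.
#'
#' @param seq A 16-bit [frame_sequence] with at least m frames.
#' @param m Window length in frames.
#' @param stride Sliding interval in frames.
#' @return A 16-bit [frame_sequence] of accumulated frames.
#' @export
accumulate_frames <- function(seq, m = 13L, stride = 1L) {
  stopifnot(inherits(seq, "frame_sequence"))
  m <- as.integer(m); stride <- as.integer(stride)
  n_t <- n_frames(seq)
  if (n_t < m)
    stop(sprintf("sequence has %d frames but accumulation needs at least %d",
                 n_t, m))
  if (seq$bit_depth == 8L && m > 1L)
    stop("promote the sequence to 16-bit before accumulating")
  d <- dim(seq$frames)
  n_out <- (n_t - m) %/% stride + 1L
  out <- array(0L, c(d[1], d[2], n_out))
  if (stride == 1L) {
    acc <- rowSums(seq$frames[, , seq_len(m), drop = FALSE], dims = 2)
    out[, , 1L] <- as.integer(acc)
    if (n_out > 1L) for (j in 2L:n_out) {
      acc <- acc - seq$frames[, , j - 1L] + seq$frames[, , j + m - 1L]
      out[, , j] <- as.integer(acc)
    }
  } else {
    for (j in seq_len(n_out)) {
      i0 <- (j - 1L) * stride + 1L
      out[, , j] <- as.integer(
        rowSums(seq$frames[, , i0:(i0 + m - 1L), drop = FALSE], dims = 2))
    }
  }
  fs_replace(seq, out, bit_depth = 16L)
}

#' Generalized Anscombe transform
#'
#' Variance-stabilizing map for mixed Poisson-Gaussian data:
#' `2 * sqrt(max(0, x / gain + 3/8 + (sigma / gain)^2))`, rescaled min-max
#' to the 16-bit range. Monotone in x, so intensity ordering within a
#' frame is preserved.
#'
#' @param seq A nonnegative [frame_sequence].
#' @param gain Poisson gain (> 0).
#' @param read_noise_sigma Gaussian read-noise standard deviation.
#' @return A 16-bit [frame_sequence].
#' @export
generalized_anscombe <- function(seq, gain, read_noise_sigma = 0) {
  stopifnot(inherits(seq, "frame_sequence"))
  if (gain <= 0) stop("gain must be > 0")
  # the transform is monotone, so the stack extrema map to the extrema of
  # the transformed stack; rescale frame by frame
  lo <- gat_raw(min(seq$frames), gain, read_noise_sigma)
  hi <- gat_raw(max(seq$frames), gain, read_noise_sigma)
  d <- dim(seq$frames)
  out <- array(0L, d)
  if (hi > lo) {
    f <- 65535 / (hi - lo)
    for (t in seq_len(d[3]))
      out[, , t] <- as.integer(round_half_up(
        (gat_raw(seq$frames[, , t], gain, read_noise_sigma) - lo) * f))
  }
  fs_replace(seq, out, bit_depth = 16L)
}

gat_raw <- function(x, gain, read_noise_sigma) {
  2 * sqrt(pmax(0, x / gain + 3 / 8 + (read_noise_sigma / gain)^2))
}

#' Static background image
#'
#' Per-pixel temporal mean over all frames, the estimate of the static
#' cellular-skeleton component.
#'
#' @param seq A [frame_sequence].
#' @return An `H x W` numeric matrix.
#' @export
estimate_static_background <- function(seq) {
  stopifnot(inherits(seq, "frame_sequence"))
  rowSums(seq$frames, dims = 2) / n_frames(seq)
}

#' Background subtraction and normalization
#'
#' Per frame, `residual = max(0, frame - background)`; the residual stack
#' is then min-max normalized as a whole (not per frame) to the 16-bit
#' range, preserving inter-frame amplitude relations. An all-zero residual
#' stack maps to all zeros.
#'
#' @param seq A [frame_sequence].
#' @param background An `H x W` background image (defaults to
#'   [estimate_static_background()] of `seq`).
#' @return A 16-bit [frame_sequence].
#' @export
subtract_background_normalize <- function(seq,
                                          background =
                                            estimate_static_background(seq)) {
  stopifnot(inherits(seq, "frame_sequence"))
  d <- dim(seq$frames)
  if (!all(d[1:2] == dim(background)))
    stop("background image shape does not match the frames")
  # two passes (global max, then scaled write) to avoid holding a second
  # double-precision copy of the whole stack
  hi <- 0
  for (t in seq_len(d[3]))
    hi <- max(hi, max(seq$frames[, , t] - background))
  out <- array(0L, d)
  if (hi > 0) {
    f <- 65535 / hi
    for (t in seq_len(d[3]))
      out[, , t] <- as.integer(round_half_up(
        pmax(seq$frames[, , t] - background, 0) * f))
  }
  fs_replace(seq, out, bit_depth = 16L)
}

#' Isotropic Gaussian smoothing with mirror boundaries
#'
#' Convolves each frame with an isotropic Gaussian kernel truncated at
#' 4 sigma, handling image boundaries by mirror reflection (which
#' preserves the frame mean up to rounding).
#'
#' @param seq A [frame_sequence].
#' @param sigma Kernel width in pixels (> 0).
#' @return A [frame_sequence] at the input bit depth.
#' @export
gaussian_smooth <- function(seq, sigma = 1.0) {
  stopifnot(inherits(seq, "frame_sequence"))
  if (sigma <= 0) stop("sigma must be > 0")
  d <- dim(seq$frames)
  kh <- gauss_reflect_matrix(d[1], sigma)
  kwt <- t(gauss_reflect_matrix(d[2], sigma))
  maxval <- bit_depth_max(seq$bit_depth)
  out <- array(0L, d)
  for (t in seq_len(d[3]))
    out[, , t] <- as.integer(pmin(pmax(
      round_half_up(kh %*% seq$frames[, , t] %*% kwt), 0), maxval))
  fs_replace(seq, out)
}

#' Full preprocessing pipeline
#'
#' Bit promotion, sliding-window frame accumulation, optional generalized
#' Anscombe transform, static background subtraction with sequence-global
#' normalization, and Gaussian smoothing, in that order. The output is the
#' 16-bit statistics-stabilized sequence the detection core consumes.
#'
#' @param seq An 8-bit [frame_sequence].
#' @param config A [preprocess_config()].
#' @return A 16-bit [frame_sequence] of length
#'   `floor((T - m) / stride) + 1`.
#' @export
preprocess_video <- function(seq, config = preprocess_config()) {
  stopifnot(inherits(seq, "frame_sequence"),
            inherits(config, "preprocess_config"))
  if (seq$bit_depth != 8L)
    stop("preprocess_video expects the raw 8-bit acquisition")
  x <- promote_bit_depth(seq)
  x <- accumulate_frames(x, config$accumulation_window,
                         config$accumulation_stride)
  if (config$use_gat)
    x <- generalized_anscombe(x, config$gat_gain,
                              config$gat_read_noise_sigma)
  x <- subtract_background_normalize(x)
  gaussian_smooth(x, config$gaussian_sigma)
}
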