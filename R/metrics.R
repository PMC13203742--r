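#' Block-statistics noise estimate
#'
#' Per frame, the image is tiled into non-overlapping `block_size` squares
#' (truncated at the right/bottom edges); the median of the lowest 10% of
#' block variances (rounded up to at least one block) is the frame's noise
#' estimate, and the sequence value is the mean over frames. Quiet blocks
#' are assumed to contain noise only, so the low-order statistics isolate
#' the noise floor from signal-bearing regions.
#'
#' @param seq A [frame_sequence] or `H x W x T` array.
#' @param block_size Block side length in pixels (default 16).
#' @return The noise variance estimate (a.u., on the sequence's own
#'   intensity scale).
#' @export
block_noise <- function(seq, block_size = 16L) {
  frames <- as_stack(seq)
  d <- dim(frames)
  if (d[1] < block_size || d[2] < block_size)
    stop(sprintf("frames (%d x %d) are smaller than one %d x %d block",
                 d[1], d[2], block_size, block_size))
  nbr <- d[1] %/% block_size
  nbc <- d[2] %/% block_size
  rows <- seq_len(nbr * block_size)
  cols <- seq_len(nbc * block_size)
  n_low <- max(1L, as.integer(ceiling(0.1 * nbr * nbc)))
  bn <- block_size * block_size
  per_frame <- vapply(seq_len(d[3]), function(t) {
    x <- frames[rows, cols, t]
    dim(x) <- c(block_size, nbr, block_size, nbc)
    s <- colSums(x)           # (nbr, block_size, nbc): partial col sums
    s2 <- colSums(x^2)
    bs <- colSums(aperm(s, c(2, 1, 3)))   # (nbr, nbc): block sums
    bs2 <- colSums(aperm(s2, c(2, 1, 3)))
    v <- bs2 / bn - (bs / bn)^2           # population block variances
    median(sort.int(v, partial = n_low)[seq_len(n_low)])
  }, numeric(1))
  mean(per_frame)
}

#' Wavelet-MAD noise estimate
#'
#' Per frame, a one-level 2-D Haar decomposition; the noise standard
#' deviation is estimated as `median(|diagonal detail|) / 0.6745` (the
#' classical Gaussian-consistent robust estimator on the zero-mean detail
#' band). The sequence value is the mean over frames. Odd trailing
#' rows/columns are dropped by the dyadic blocking.
#'
#' @param seq A [frame_sequence] or `H x W x T` array.
#' @return The noise standard deviation estimate (a.u.).
#' @export
wavelet_noise <- function(seq) {
  frames <- as_stack(seq)
  d <- dim(frames)
  if (d[1] < 2 || d[2] < 2) stop("frames must be at least 2 x 2")
  ri <- seq_len(d[1] %/% 2L) * 2L
  ci <- seq_len(d[2] %/% 2L) * 2L
  per_frame <- vapply(seq_len(d[3]), function(t) {
    x <- frames[, , t]
    a <- x[ri - 1L, ci - 1L]; b <- x[ri - 1L, ci]
    cc <- x[ri, ci - 1L]; dd <- x[ri, ci]
    diag_detail <- (a - b - cc + dd) / 2
    median(abs(diag_detail)) / 0.6745
  }, numeric(1))
  mean(per_frame)
}

#' Local-statistics SNR
#'
#' Per frame, the signal is a local mean filtering of the frame (uniform
#' `window x window` kernel with mirror boundaries) and the residual is
#' the difference; the SNR is `10 * log10(var(signal) / var(residual))`.
#' The sequence value is the mean over frames. Suitable for real imaging
#' data without ground truth. Degenerate zero-variance frames are capped
#' at +/- 120 dB.
#'
#' @param seq A [frame_sequence] or `H x W x T` array.
#' @param window Odd window size, >= 3.
#' @return SNR in dB.
#' @export
local_snr <- function(seq, window = 3L) {
  if (window < 3L || window %% 2L == 0L) stop("window must be odd and >= 3")
  frames <- as_stack(seq)
  d <- dim(frames)
  kh <- uniform_reflect_matrix(d[1], window)
  kwt <- t(uniform_reflect_matrix(d[2], window))
  per_frame <- vapply(seq_len(d[3]), function(t) {
    x <- frames[, , t]
    s <- kh %*% x %*% kwt
    r <- x - s
    vs <- var(as.numeric(s))
    vr <- var(as.numeric(r))
    if (vs == 0) return(-120)
    if (vr == 0) return(120)
    min(max(10 * log10(vs / vr), -120), 120)
  }, numeric(1))
  mean(per_frame)
}

uniform_reflect_matrix <- function(n, window) {
  r <- (window - 1L) %/% 2L
  m <- matrix(0, n, n)
  wgt <- 1 / window
  for (i in seq_len(n)) {
    idx <- i + seq(-r, r)
    idx <- ifelse(idx < 1L, 1L - idx, idx)
    idx <- ifelse(idx > n, 2L * n + 1L - idx, idx)
    for (j in idx) m[i, j] <- m[i, j] + wgt
  }
  m
}

#' Reference SNR against ground truth
#'
#' Both stacks are min-max normalized to \[0, 1\] over the whole
#' spatiotemporal volume; per frame, the SNR is
#' `10 * log10(sum(truth^2) / sum((truth - est)^2))`, and the sequence
#' value is the mean over frames that contain ground-truth signal (the
#' ratio is undefined on signal-free frames, which are skipped, matching
#' the per-frame averaging used by the other sequence metrics). Per-frame
#' values are capped at +/- 120 dB; a perfect estimate returns +120 dB
#' and an entirely signal-free truth -120 dB.
#'
#' `per_frame = FALSE` instead pools the sums over the whole stack into a
#' single ratio.
#'
#' @param truth The ground-truth stack ([frame_sequence] or array).
#' @param est The estimated stack, same shape.
#' @param per_frame Average per-frame SNRs (default) or pool the whole
#'   stack.
#' @return SNR in dB.
#' @export
reference_snr <- function(truth, est, per_frame = TRUE) {
  ta <- as_stack(truth); ea <- as_stack(est)
  if (!all(dim(ta) == dim(ea)))
    stop("shape mismatch between truth and estimate")
  if (!per_frame) {
    s <- cpp_ref_snr_sums(ta, ea)
    if (s[1] == 0) return(-120)
    if (s[2] == 0) return(120)
    return(min(max(10 * log10(s[1] / s[2]), -120), 120))
  }
  s <- cpp_ref_snr_frame_sums(ta, ea, dim(ta)[3])
  keep <- s[1, ] > 0
  if (!any(keep)) return(-120)
  snr_t <- ifelse(s[2, keep] == 0, 120,
                  pmin(pmax(10 * log10(s[1, keep] / s[2, keep]),
                            -120), 120))
  mean(snr_t)
}

#' Dice coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)` over the full spatiotemporal volume.
#' Two empty masks agree perfectly and score 1.
#'
#' @param truth_mask,detected_mask Logical (or 0/1) arrays of equal shape.
#' @return A value in \[0, 1\].
#' @export
dice_coefficient <- function(truth_mask, detected_mask) {
  ta <- as_stack(truth_mask); da <- as_stack(detected_mask)
  if (!all(dim(ta) == dim(da))) stop("shape mismatch between masks")
  cnt <- cpp_overlap_counts(ta, da)
  if (cnt[1] + cnt[2] == 0) return(1)
  2 * cnt[3] / (cnt[1] + cnt[2])
}

#' Evaluate a detection result
#'
#' Computes the five evaluation quantities for one sequence: the two noise
#' estimates and the local SNR of `detected`, plus (when ground truth is
#' supplied) the reference SNR against the clean signal and the Dice
#' coefficient against the truth mask.
#'
#' @param detected The sequence to score ([frame_sequence] or array).
#' @param truth_signal Optional clean ground-truth signal stack, already
#'   aligned to `detected` (see [align_truth()]).
#' @param truth_mask Optional ground-truth binary mask stack, aligned.
#' @param detected_mask Optional detected mask; defaults to the nonzero
#'   support of `detected`.
#' @return A one-row data frame: `wavelet_noise`, `block_noise`,
#'   `local_snr`, `reference_snr`, `dice` (the last two `NA` without
#'   ground truth).
#' @export
evaluate_sequence <- function(detected, truth_signal = NULL,
                              truth_mask = NULL, detected_mask = NULL) {
  da <- as_stack(detected)
  ref <- if (!is.null(truth_signal)) reference_snr(truth_signal, da) else
    NA_real_
  dice <- if (!is.null(truth_mask)) {
    if (is.null(detected_mask)) detected_mask <- da > 0
    dice_coefficient(truth_mask, detected_mask)
  } else NA_real_
  data.frame(wavelet_noise = wavelet_noise(da),
             block_noise = block_noise(da),
             local_snr = local_snr(da),
             reference_snr = ref,
             dice = dice)
}

#' Align ground truth to the accumulated index range
#'
#' m-frame accumulation with stride 1 shortens a T-frame recording to
#' `T - m + 1` frames, and accumulated frame j carries the timestamp of
#' its window's last raw frame. Truth frame `j + m - 1` therefore pairs
#' with output frame `j`: the truth stack is cropped to frames
#' `m, ..., T`.
#'
#' @param truth An `H x W x T` array (clean signal or mask).
#' @param m Accumulation window length.
#' @return The cropped array with `T - m + 1` frames.
#' @export
align_truth <- function(truth, m = 13L) {
  d <- dim(truth)
  if (d[3] < m) stop("truth has fewer frames than the accumulation window")
  truth[, , m:d[3], drop = FALSE]
}

as_stack <- function(x) {
  if (inherits(x, "frame_sequence")) return(x$frames)
  if (is.matrix(x)) return(array(x, c(dim(x), 1L)))
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  stop("expected a frame_sequence, matrix, or H x W x T array")
}
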