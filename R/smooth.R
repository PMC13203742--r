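# Separable Gaussian smoothing with mirror (reflected) boundaries.
#
# The 1-D kernel is truncated at 4*sigma and renormalized; boundary handling
# folds the kernel back at the image edge (half-sample reflection), which
# preserves the frame mean exactly. Smoothing a frame is then two banded
# matrix products: K_h %*% F %*% t(K_w).

gauss_kernel_1d <- function(sigma, truncate = 4) {
  r <- max(1L, as.integer(ceiling(truncate * sigma)))
  k <- dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# n x n smoothing matrix with mirror boundary: row i holds the kernel
# centered at i with out-of-range taps reflected back inside.
gauss_reflect_matrix <- function(n, sigma, truncate = 4) {
  k <- gauss_kernel_1d(sigma, truncate)
  r <- (length(k) - 1L) %/% 2L
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- i + seq(-r, r)
    idx <- ifelse(idx < 1L, 1L - idx, idx)          # reflect at top/left
    idx <- ifelse(idx > n, 2L * n + 1L - idx, idx)  # reflect at bottom/right
    for (j in seq_along(idx)) m[i, idx[j]] <- m[i, idx[j]] + k[j]
  }
  m
}

smooth_frame <- function(frame, sigma, truncate = 4) {
  kh <- gauss_reflect_matrix(nrow(frame), sigma, truncate)
  kw <- gauss_reflect_matrix(ncol(frame), sigma, truncate)
  kh %*% frame %*% t(kw)
}

# Smooth every frame of a 3-D stack, reusing the banded matrices.
smooth_stack <- function(frames, sigma, truncate = 4) {
  d <- dim(frames)
  kh <- gauss_reflect_matrix(d[1], sigma, truncate)
  kwt <- t(gauss_reflect_matrix(d[2], sigma, truncate))
  out <- array(0, d)
  for (t in seq_len(d[3])) out[, , t] <- kh %*% frames[, , t] %*% kwt
  out
}
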