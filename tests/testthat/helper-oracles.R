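# Brute-force reference implementations used as independent oracles.
# All are written as plain double loops so they share no code path with
# the package's vectorized/C++ implementations.

bf_frame_stats <- function(frame) {
  n <- length(frame)
  mu <- sum(frame) / n
  ss <- 0
  for (v in frame) ss <- ss + (v - mu)^2
  list(mu = mu, sigma = sqrt(ss / n))
}

bf_instantaneous_mask <- function(frame, theta_g) {
  st <- bf_frame_stats(frame)
  out <- array(FALSE, dim(frame))
  for (i in seq_along(frame))
    out[i] <- frame[i] > st$mu + theta_g * st$sigma
  out
}

bf_update_counts <- function(C, inst) {
  out <- array(0L, dim(C))
  for (i in seq_along(C)) out[i] <- if (inst[i]) C[i] + 1L else 0L
  out
}

bf_jaccard <- function(a, b) {
  inter <- 0; uni <- 0
  for (i in seq_along(a)) {
    if (a[i] && b[i]) inter <- inter + 1
    if (a[i] || b[i]) uni <- uni + 1
  }
  inter / (uni + 1e-9)
}

bf_dice <- function(a, b) {
  inter <- 0; na <- 0; nb <- 0
  for (i in seq_along(a)) {
    if (a[i] != 0) na <- na + 1
    if (b[i] != 0) nb <- nb + 1
    if (a[i] != 0 && b[i] != 0) inter <- inter + 1
  }
  if (na + nb == 0) return(1)
  2 * inter / (na + nb)
}

bf_window_transform <- function(frame, mask, m) {
  denom <- min(m * 255, 65535)
  out <- array(0L, dim(frame))
  for (i in seq_along(frame)) {
    if (mask[i]) {
      v <- floor(frame[i] * 255 / denom + 0.5)
      out[i] <- as.integer(min(max(v, 0), 255))
    }
  }
  out
}

bf_segment_mask <- function(frame, L, H) {
  out <- array(FALSE, dim(frame))
  for (i in seq_along(frame)) out[i] <- frame[i] >= L && frame[i] <= H
  out
}

# 8-connected labeling by repeated flood fill (slow, simple).
bf_label8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (c0 in seq_len(w)) for (r0 in seq_len(h)) {
    if (!mask[r0, c0] || lab[r0, c0] != 0L) next
    cur <- cur + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- cur
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1] + dr; cc <- p[2] + dc
        if (rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- cur
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# Canonicalize a labeling so two labelings can be compared directly:
# relabel in order of first appearance in column-major order.
canon_labels <- function(lab) {
  seen <- integer(0)
  out <- lab
  for (i in seq_along(lab)) {
    l <- lab[i]
    if (l == 0L) next
    pos <- match(l, seen)
    if (is.na(pos)) { seen <- c(seen, l); pos <- length(seen) }
    out[i] <- pos
  }
  out
}

random_frame <- function(h = 16, w = 16, max_val = 65535L) {
  matrix(sample.int(max_val + 1L, h * w, replace = TRUE) - 1L, h, w)
}

small_sim_config <- function(seed = 1L, n_events = 5, ...) {
  simulation_config(width = 64, height = 64, duration = 5,
                    n_events = n_events, seed = seed, ...)
}
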