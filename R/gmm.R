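#' Fit a per-frame Gaussian mixture to the gray-level distribution
#'
#' Flattens the frame into a one-dimensional gray-level sample and fits
#' candidate Gaussian mixtures with K = 1, 2 and 3 components by
#' expectation-maximization (k-means-based initialization, convergence
#' when the mean log-likelihood increment drops below `tol`, at most
#' `max_iter` iterations). The component count is selected by minimum BIC
#' and components are returned sorted by ascending mean; the highest-mean
#' component is the candidate signal peak. Frames with fewer than three
#' distinct gray values fall back to K = number of distinct values, and a
#' constant frame degenerates to a single component.
#'
#' Identical repeated gray values are collapsed into a weighted sample
#' before EM; this is an exact reformulation (the likelihood and every EM
#' update depend on the data only through value-count pairs), not an
#' approximation.
#'
#' @param frame A numeric matrix or vector of gray values.
#' @param max_components Largest candidate K (default 3).
#' @param tol Convergence tolerance on the mean log-likelihood increment.
#' @param max_iter EM iteration cap.
#' @return An object of class `gmm_fit`: `K`, `weights`, `means`, `sds`,
#'   `bic` (named vector over candidate K), `loglik`, `n`.
#' @export
fit_gmm <- function(frame, max_components = 3L, tol = 1e-3,
                    max_iter = 100L) {
  if (length(frame) == 0L || anyNA(frame))
    stop("frame must be non-empty and finite")
  n <- length(frame)
  if (is.integer(frame) && min(frame) >= 0L && max(frame) <= 65535L) {
    # histogram fast path for 16-bit integer frames
    cnt <- tabulate(frame + 1L, nbins = 65536L)
    nz <- which(cnt > 0L)
    v <- as.numeric(nz - 1L)
    w <- as.numeric(cnt[nz])
  } else {
    r <- rle(sort.int(as.numeric(frame), method = "radix"))
    v <- r$values
    w <- as.numeric(r$lengths)
  }
  m <- length(v)
  spread <- v[m] - v[1]
  sd_floor <- max(1e-6, 1e-6 * spread)
  k_max <- min(as.integer(max_components), m)
  fits <- vector("list", k_max)
  bic <- rep(NA_real_, max_components)
  names(bic) <- paste0("K", seq_len(max_components))
  for (K in seq_len(k_max)) {
    fit <- if (K == 1L) gmm_fit_single(v, w, n, sd_floor) else
      gmm_fit_em(v, w, n, K, tol, max_iter, sd_floor)
    fits[[K]] <- fit
    if (!is.null(fit))
      bic[K] <- -2 * fit$loglik + (3 * K - 1) * log(n)
  }
  if (all(is.na(bic))) stop("no mixture candidate could be fitted")
  K <- unname(which.min(bic))
  fit <- fits[[K]]
  o <- order(fit$mu)
  structure(list(K = K, weights = fit$pi[o], means = fit$mu[o],
                 sds = fit$sd[o], bic = bic, loglik = fit$loglik, n = n),
            class = "gmm_fit")
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("<gmm_fit> K = %d (BIC-selected), n = %d\n", x$K, x$n))
  for (k in seq_len(x$K))
    cat(sprintf("  component %d: weight %.3f, mean %.2f, sd %.2f\n",
                k, x$weights[k], x$means[k], x$sds[k]))
  invisible(x)
}

gmm_fit_single <- function(v, w, n, sd_floor) {
  mu <- sum(w * v) / n
  sd1 <- max(sqrt(sum(w * (v - mu)^2) / n), sd_floor)
  loglik <- sum(w * dnorm(v, mu, sd1, log = TRUE))
  list(pi = 1, mu = mu, sd = sd1, loglik = loglik)
}

gmm_fit_em <- function(v, w, n, K, tol, max_iter, sd_floor) {
  init <- wkmeans_1d(v, w, K)
  if (is.null(init)) return(NULL)
  em <- cpp_gmm_em(v, w, init$pi, init$mu,
                   pmax(init$sd, sd_floor), tol, as.integer(max_iter),
                   sd_floor)
  if (!em$ok || !is.finite(em$loglik)) return(NULL)
  list(pi = em$pi, mu = em$mu, sd = em$sd, loglik = em$loglik)
}

# Deterministic weighted 1-D k-means: Lloyd iterations on value-count
# pairs from two starts (weighted quantiles and an even spread over the
# value range), keeping the solution with the lower within-cluster SSE.
# Lloyd in 1-D can stall in a local optimum from either start alone when
# component masses are very unequal.
wkmeans_1d <- function(v, w, K, iter = 25L) {
  cw <- cumsum(w) / sum(w)
  c_quant <- vapply((seq_len(K) - 0.5) / K,
                    function(p) v[which.max(cw >= p)], numeric(1))
  c_range <- seq(v[1], v[length(v)], length.out = K + 2L)[2:(K + 1L)]
  best <- NULL
  for (centers in list(c_quant, c_range)) {
    if (length(unique(centers)) < K) next
    sol <- lloyd_1d(v, w, sort(centers), iter)
    if (!is.null(sol) && (is.null(best) || sol$sse < best$sse)) best <- sol
  }
  if (is.null(best)) return(NULL)
  cl <- best$cl
  pi0 <- numeric(K); mu0 <- numeric(K); sd0 <- numeric(K)
  for (k in seq_len(K)) {
    sel <- cl == k
    wk <- sum(w[sel])
    pi0[k] <- wk / sum(w)
    mu0[k] <- sum(w[sel] * v[sel]) / wk
    sd0[k] <- sqrt(sum(w[sel] * (v[sel] - mu0[k])^2) / wk)
  }
  list(pi = pi0, mu = mu0, sd = sd0)
}

lloyd_1d <- function(v, w, centers, iter) {
  K <- length(centers)
  assign_prev <- NULL
  for (i in seq_len(iter)) {
    mids <- (centers[-K] + centers[-1]) / 2
    cl <- findInterval(v, mids) + 1L
    if (identical(cl, assign_prev)) break
    assign_prev <- cl
    for (k in seq_len(K)) {
      sel <- cl == k
      if (!any(sel)) return(NULL)
      centers[k] <- sum(w[sel] * v[sel]) / sum(w[sel])
    }
    centers <- sort(centers)
  }
  cl <- assign_prev
  sse <- sum(w * (v - centers[cl])^2)
  list(cl = cl, centers = centers, sse = sse)
}

#' Derive per-component gray-level segments from a mixture fit
#'
#' For each component k the nominal interval `mean +/- 2 sd` is truncated
#' to the gray-level range the component actually occupies: the span of
#' values whose maximum-posterior classification under the fitted mixture
#' is component k. This keeps overlapping components from claiming each
#' other's gray levels (a raw `mean - 2 sd` bound of a broad signal
#' component would otherwise reach below the background bulk and merge
#' both populations into one segment). For the signal component (k = K)
#' the upper bound is the top of the gray range: intensities above the
#' signal peak are still signal, and a two-sided bracket would carve the
#' brightest event cores out of the mask.
#'
#' Each segment also carries the intensity threshold
#' `tau_g = max(2, beta * sd)` with `beta = 0.5` for the signal component
#' and `beta = 2` for background components, and the area threshold
#' `tau_a = min_area` for the signal component and `10 * min_area` for
#' background components (background structures must be large and dominant
#' before they are treated as suppressors).
#'
#' @param fit A [fit_gmm()] result.
#' @param min_area Minimum calcium signal area in pixels.
#' @param gray_range Actual gray-level range of the frame, `c(low, high)`.
#' @return A data frame with one row per component: `component`, `weight`,
#'   `mean`, `sd`, `L`, `H`, `beta`, `tau_g`, `tau_a`, `is_signal`.
#' @export
build_segments <- function(fit, min_area = 29L, gray_range = c(0, 65535)) {
  stopifnot(inherits(fit, "gmm_fit"))
  K <- fit$K
  k <- seq_len(K)
  beta <- ifelse(k == K, 0.5, 2)
  supp <- component_support(fit, gray_range)
  L <- pmax(fit$means - 2 * fit$sds, supp$lo)
  H <- pmin(fit$means + 2 * fit$sds, supp$hi)
  H[K] <- gray_range[2]
  L <- pmin(pmax(L, gray_range[1]), gray_range[2])
  H <- pmin(pmax(H, L), gray_range[2])
  data.frame(
    component = k,
    weight = fit$weights,
    mean = fit$means,
    sd = fit$sds,
    L = L,
    H = H,
    beta = beta,
    tau_g = pmax(2, beta * fit$sds),
    tau_a = ifelse(k == K, min_area, 10 * min_area),
    is_signal = k == K)
}

# Gray-level span claimed by each component under maximum-posterior
# classification, evaluated on a dense grid over the frame's gray range.
component_support <- function(fit, gray_range, n_grid = 4096L) {
  K <- fit$K
  if (K == 1L || gray_range[2] <= gray_range[1])
    return(list(lo = rep(gray_range[1], K), hi = rep(gray_range[2], K)))
  g <- seq(gray_range[1], gray_range[2], length.out = n_grid)
  ll <- vapply(seq_len(K), function(k)
    log(fit$weights[k]) + dnorm(g, fit$means[k], fit$sds[k], log = TRUE),
    numeric(n_grid))
  cls <- max.col(ll, ties.method = "first")
  lo <- rep(gray_range[1], K)
  hi <- rep(gray_range[2], K)
  for (k in seq_len(K)) {
    sel <- cls == k
    if (any(sel)) {
      lo[k] <- min(g[sel])
      hi[k] <- max(g[sel])
    } else {
      # component claims no gray level outright; fall back to its bracket
      lo[k] <- max(fit$means[k] - 2 * fit$sds[k], gray_range[1])
      hi[k] <- min(fit$means[k] + 2 * fit$sds[k], gray_range[2])
    }
  }
  list(lo = lo, hi = hi)
}

#' Binary mask of one gray-level segment
#'
#' Pixel on iff `L <= intensity <= H` (both bounds inclusive).
#'
#' @param frame A numeric matrix.
#' @param segment One row of [build_segments()] output (or any list with
#'   `L` and `H`).
#' @return A logical matrix.
#' @export
segment_mask <- function(frame, segment) {
  frame >= segment$L & frame <= segment$H
}
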