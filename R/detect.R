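#' Detector configuration
#'
#' The three user-facing parameters of the detection core, plus the fixed
#' internals they feed. `min_area` (pixels), `min_duration` (frames) and
#' `theta_g_init` (the global-threshold initialization coefficient) are
#' the only knobs intended for routine tuning; the defaults (29 px, 5
#' frames, 2.0) are the study's operating point at 40 Hz.
#'
#' The local threshold `theta_l` evolves multiplicatively inside
#' \[0.2, 0.5\] and is converted to a frame count through
#' `duration_reference` (default `min_duration`), so the effective
#' consecutive-activation requirement adapts between 1 and
#' `round(0.5 * min_duration)` frames and scales with the `min_duration`
#' setting.
#'
#' @param min_area Minimum calcium signal area, pixels.
#' @param min_duration Minimum duration, frames.
#' @param theta_g_init Global threshold initialization coefficient.
#' @param accumulation_window Accumulation window m of the preprocessing
#'   stage, echoed here for the 16-to-8-bit output remapping.
#' @param theta_g_bounds Clamp range for the adaptive global threshold.
#' @param duration_reference Frames corresponding to `theta_l = 1`.
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(min_area = 29L, min_duration = 5L,
                            theta_g_init = 2.0,
                            accumulation_window = 13L,
                            theta_g_bounds = c(0.5, 6.0),
                            duration_reference = min_duration) {
  cfg <- list(min_area = as.integer(min_area),
              min_duration = as.integer(min_duration),
              theta_g_init = theta_g_init,
              accumulation_window = as.integer(accumulation_window),
              theta_g_bounds = theta_g_bounds,
              duration_reference = as.integer(duration_reference))
  if (cfg$min_area < 1L) stop("min_area must be >= 1")
  if (cfg$min_duration < 1L) stop("min_duration must be >= 1")
  if (cfg$theta_g_init <= 0) stop("theta_g_init must be > 0")
  if (cfg$theta_g_bounds[1] >= cfg$theta_g_bounds[2])
    stop("theta_g_bounds must be c(low, high) with low < high")
  class(cfg) <- "detector_config"
  cfg
}

#' Frame-wise intensity statistics
#'
#' Population mean and standard deviation over all pixels of a frame.
#'
#' @param frame A numeric matrix or vector.
#' @return A list with `mu` and `sigma`.
#' @export
frame_stats <- function(frame) {
  x <- as.numeric(frame)
  mu <- mean(x)
  list(mu = mu, sigma = sqrt(mean((x - mu)^2)))
}

#' Instantaneous bright-pixel mask
#'
#' Pixel on iff `intensity > mu + theta_g * sigma` for the current frame's
#' statistics.
#'
#' @param frame A numeric matrix.
#' @param stats Frame statistics from [frame_stats()].
#' @param theta_g Global threshold coefficient (> 0).
#' @return A logical matrix.
#' @export
instantaneous_mask <- function(frame, stats = frame_stats(frame),
                               theta_g = 2.0) {
  stopifnot(theta_g > 0)
  frame > stats$mu + theta_g * stats$sigma
}

#' Update the consecutive-activation count matrix
#'
#' Counts increment where the instantaneous mask is on and reset to zero
#' where it is off.
#'
#' @param C Integer matrix of per-pixel consecutive-activation counts.
#' @param inst_mask Logical matrix, the instantaneous mask.
#' @return The updated integer count matrix.
#' @export
update_count_matrix <- function(C, inst_mask) {
  if (!all(dim(C) == dim(inst_mask))) stop("shape mismatch")
  (C + 1L) * inst_mask
}

#' Effective duration threshold in frames
#'
#' Converts the dimensionless local threshold `theta_l` (in \[0.2, 0.5\])
#' to a frame count: `max(1, round(theta_l * D_ref))`. With the default
#' reference `D_ref = 10`, the initial `theta_l = 0.5` gives the 5-frame
#' minimum duration criterion.
#'
#' @param theta_l Local threshold in \[0.2, 0.5\].
#' @param duration_reference Frames corresponding to `theta_l = 1`.
#' @return An integer number of frames.
#' @export
effective_duration_threshold <- function(theta_l, duration_reference = 10L) {
  max(1L, as.integer(round_half_up(theta_l * duration_reference)))
}

#' Temporal-persistence mask
#'
#' Pixel on iff its consecutive-activation count reaches or exceeds the
#' duration threshold (inclusive).
#'
#' @param C Integer count matrix.
#' @param duration_threshold Required consecutive frames (>= 1).
#' @return A logical matrix.
#' @export
temporal_mask <- function(C, duration_threshold) {
  stopifnot(duration_threshold >= 1)
  C >= duration_threshold
}

#' Retain connected components by area and intensity elevation
#'
#' Labels the mask with 8-connectivity and keeps regions whose pixel count
#' is at least the segment's area threshold `tau_a` and whose mean
#' intensity is at least `L + tau_g` (intensity elevation above the
#' segment floor).
#'
#' @param mask Logical matrix (one segment's gray-level mask).
#' @param segment The segment row the mask was derived from.
#' @param frame The intensity frame.
#' @return A list with `mask` (logical matrix of retained pixels) and
#'   `regions` (data frame: `label`, `area`, `mean_intensity`,
#'   `retained`).
#' @export
filter_components <- function(mask, segment, frame) {
  stopifnot(all(dim(mask) == dim(frame)))
  labels <- cpp_label8(mask)
  n_lab <- max(labels)
  if (n_lab == 0L) {
    return(list(mask = mask & FALSE,
                regions = data.frame(label = integer(), area = integer(),
                                     mean_intensity = numeric(),
                                     retained = logical())))
  }
  inside <- labels > 0L
  area <- tabulate(labels[inside], nbins = n_lab)
  mean_int <- as.numeric(
    rowsum(as.numeric(frame[inside]), labels[inside])) / area
  retained <- area >= segment$tau_a & mean_int >= segment$L + segment$tau_g
  keep <- which(retained)
  out <- array(FALSE, dim(mask))
  if (length(keep) > 0) out[inside] <- labels[inside] %in% keep
  list(mask = out,
       regions = data.frame(label = seq_len(n_lab), area = area,
                            mean_intensity = mean_int, retained = retained))
}

#' Compose the event mask from retained regions
#'
#' The union of retained signal-segment regions, minus any pixel that
#' belongs to a retained background-segment region. Large, dominant
#' background structures therefore act as suppressors rather than
#' candidates.
#'
#' @param signal_mask Logical matrix of retained signal-segment pixels.
#' @param background_mask Logical matrix of retained background-segment
#'   pixels.
#' @return A logical matrix, the event mask.
#' @export
compose_event_mask <- function(signal_mask, background_mask) {
  if (!all(dim(signal_mask) == dim(background_mask))) stop("shape mismatch")
  signal_mask & !background_mask
}

#' Bright-pixel fraction of a mask
#'
#' @param mask A logical matrix.
#' @return The fraction of on pixels, in \[0, 1\].
#' @export
bright_fraction <- function(mask) mean(mask != 0)

#' Heuristic global-threshold update
#'
#' A fluctuating bright-pixel prevalence (|delta rho| >= 0.001) indicates
#' noise-dominated masks and tightens the threshold by the factor 1.2;
#' a stable prevalence indicates clean masks and relaxes it by 0.8 to
#' recover sensitivity. The opposing factors give the update a restoring
#' force: the threshold settles at the margin where mask flicker sets in,
#' instead of saturating at a bound. The result is clamped to `bounds`.
#'
#' @param theta_g Current global threshold.
#' @param delta_rho Change of bright-pixel fraction since the last frame.
#' @param bounds Clamp range `c(low, high)`.
#' @return The updated global threshold.
#' @export
update_global_threshold <- function(theta_g, delta_rho,
                                    bounds = c(0.5, 6.0)) {
  out <- theta_g * if (abs(delta_rho) < 0.001) 0.8 else 1.2
  min(max(out, bounds[1]), bounds[2])
}

#' Inter-frame Jaccard index
#'
#' `|A intersect B| / (|A union B| + 1e-9)`; the epsilon keeps the ratio
#' defined (and zero) when both masks are empty.
#'
#' @param mask_a,mask_b Logical matrices of equal shape.
#' @return The Jaccard similarity in \[0, 1\].
#' @export
jaccard_index <- function(mask_a, mask_b) {
  if (!all(dim(mask_a) == dim(mask_b))) stop("shape mismatch")
  cnt <- cpp_overlap_counts(mask_a, mask_b)
  inter <- cnt[3]
  uni <- cnt[1] + cnt[2] - inter
  inter / (uni + 1e-9)
}

#' Heuristic local-threshold update
#'
#' High inter-frame mask consistency (J > 0.7) raises the local threshold
#' by the factor 1.3 (capped at 0.5); otherwise it decays by 0.9 (floored
#' at 0.2).
#'
#' @param theta_l Current local threshold in \[0.2, 0.5\].
#' @param J Inter-frame Jaccard index.
#' @return The updated local threshold.
#' @export
update_local_threshold <- function(theta_l, J) {
  if (J > 0.7) min(1.3 * theta_l, 0.5) else max(0.9 * theta_l, 0.2)
}

#' Frame SNR relative to a mask
#'
#' Mean gray value inside the mask divided by the (population) standard
#' deviation outside it. Degenerate cases use fixed conventions: an empty
#' mask returns the neutral value 1, and a zero outside-deviation is
#' capped at 1e6.
#'
#' @param frame A numeric matrix.
#' @param mask A logical matrix (not the full frame).
#' @return A nonnegative scalar.
#' @export
mask_snr <- function(frame, mask) {
  if (!all(dim(frame) == dim(mask))) stop("shape mismatch")
  n_in <- sum(mask)
  if (n_in == 0L) return(1)
  if (n_in == length(mask)) return(1e6)
  outside <- frame[!mask]
  s <- sqrt(mean((outside - mean(outside))^2))
  if (s == 0) return(1e6)
  min(mean(frame[mask]) / s, 1e6)
}

#' Adaptive mixture re-estimation period
#'
#' `alpha = clip(1 - 1/SNR, 0.85, 0.99)` and
#' `N = max(1, round(1 / (1 - alpha)))`, so the refit period ranges from 7
#' frames (poor SNR, frequent refits) to 100 frames (excellent SNR).
#'
#' @param snr Frame SNR from [mask_snr()].
#' @return An integer period in \[7, 100\].
#' @export
update_estimation_period <- function(snr) {
  alpha <- min(max(1 - 1 / snr, 0.85), 0.99)
  max(1L, as.integer(round_half_up(1 / (1 - alpha))))
}

#' Window-function transformation to 8-bit
#'
#' Background pixels (outside the mask) are set to zero; pixels inside the
#' mask are remapped by `round(I / min(m * 255, 65535) * 255)`, clipped to
#' \[0, 255\]. The divisor compensates the amplitude scaling introduced by
#' m-frame accumulation; the map is monotone within the mask.
#'
#' @param frame A 16-bit intensity matrix.
#' @param mask Logical matrix of detected signal support.
#' @param m Frame accumulation window length.
#' @return An integer matrix with values in \[0, 255\].
#' @export
window_transform <- function(frame, mask, m = 13L) {
  if (!all(dim(frame) == dim(mask))) stop("shape mismatch")
  denom <- min(m * 255, 65535)
  out <- array(0L, dim(frame))
  sel <- which(mask)
  if (length(sel) > 0)
    out[sel] <- as.integer(pmin(pmax(
      round_half_up(frame[sel] * 255 / denom), 0), 255))
  out
}

#' Run the adaptive detection core over a preprocessed sequence
#'
#' Per frame: (i) frame statistics; (ii) instantaneous mask at the current
#' global threshold; (iii) count-matrix update and temporal-persistence
#' mask at the current effective duration threshold; (iv) at frame 1 and
#' then every N frames, a segment-wise mixture refit (GMM + per-component
#' gray-level segments + 8-connected component filtering) rebuilding the
#' event mask; (v)-(vii) heuristic updates of the global threshold (bright
#' -fraction fluctuation), local threshold (inter-frame Jaccard), and
#' refit period (frame SNR); (viii) 8-bit output via [window_transform()]
#' restricted to the intersection of the event mask and the temporal
#' mask. The event mask is held constant between refits.
#'
#' @param seq A preprocessed 16-bit [frame_sequence].
#' @param config A [detector_config()].
#' @param fit_cache Optional environment memoizing per-frame mixture fits
#'   (keyed by frame index). The fit depends only on the frame, so runs of
#'   different detector configurations over the same sequence can share
#'   one cache.
#' @param return_mask Materialize the logical mask stack (the nonzero
#'   support of the output). Set to `FALSE` in memory-tight batch runs;
#'   the support is always recoverable as `output$frames > 0`.
#' @return A list with `output` (8-bit [frame_sequence]), `mask` (logical
#'   `H x W x T` array of the detected support), and `trace` (one row per
#'   frame: `frame`, `theta_g`, `theta_l`, `duration_threshold`, `rho`,
#'   `jaccard`, `snr`, `period_N`, `refit`; threshold columns hold the
#'   post-update state).
#' @export
run_detection <- function(seq, config = detector_config(),
                          fit_cache = NULL, return_mask = TRUE) {
  stopifnot(inherits(seq, "frame_sequence"),
            inherits(config, "detector_config"))
  if (seq$bit_depth != 16L)
    stop("run_detection expects the preprocessed 16-bit sequence")
  d <- dim(seq$frames)
  n <- d[1] * d[2]
  n_t <- d[3]
  if (n_t < 1L) stop("empty sequence")
  bounds <- config$theta_g_bounds
  theta_g <- min(max(config$theta_g_init, bounds[1]), bounds[2])
  theta_l <- 0.5
  # fixed state buffers, updated in place by the fused C++ pass
  C <- integer(n)
  prev_tcm <- logical(n)
  cur_tcm <- logical(n)
  m_event <- logical(n)
  prev_rho <- 0
  N <- 7L
  frames_since_fit <- 0L
  denom <- min(config$accumulation_window * 255, 65535)
  out <- array(0L, d)
  tr_theta_g <- tr_theta_l <- tr_rho <- tr_j <- tr_snr <- numeric(n_t)
  tr_dthr <- tr_N <- integer(n_t)
  tr_refit <- logical(n_t)
  for (t in seq_len(n_t)) {
    dthr <- effective_duration_threshold(theta_l, config$duration_reference)
    step <- cpp_frame_step(seq$frames, t, n, C, prev_tcm, cur_tcm,
                           m_event, theta_g, dthr, denom, out)
    refit <- t == 1L || frames_since_fit >= N
    if (refit) {
      frame <- seq$frames[, , t]
      dim(frame) <- NULL
      m_event <- refit_event_mask(frame, d[1:2], config, t, fit_cache,
                                  gray_range = c(step[["fmin"]],
                                                 step[["fmax"]]))
      frames_since_fit <- 0L
      # the refit frame's output must use the fresh event mask
      of <- integer(n)
      sel <- which(cur_tcm & m_event)
      if (length(sel) > 0)
        of[sel] <- as.integer(pmin(pmax(
          round_half_up(frame[sel] * 255 / denom), 0), 255))
      out[, , t] <- of
    }
    frames_since_fit <- frames_since_fit + 1L
    # adaptive updates (take effect from the next frame on)
    rho <- step[["n_tcm"]] / n
    theta_g <- update_global_threshold(theta_g, rho - prev_rho, bounds)
    prev_rho <- rho
    J <- step[["n_inter"]] / (step[["n_union"]] + 1e-9)
    theta_l <- update_local_threshold(theta_l, J)
    snr <- snr_from_sums(step, n)
    N <- update_estimation_period(snr)
    tmp <- prev_tcm; prev_tcm <- cur_tcm; cur_tcm <- tmp
    tr_theta_g[t] <- theta_g; tr_theta_l[t] <- theta_l
    tr_dthr[t] <- dthr; tr_rho[t] <- rho; tr_j[t] <- J
    tr_snr[t] <- snr; tr_N[t] <- N; tr_refit[t] <- refit
  }
  trace <- data.frame(frame = seq_len(n_t), theta_g = tr_theta_g,
                      theta_l = tr_theta_l, duration_threshold = tr_dthr,
                      rho = tr_rho, jaccard = tr_j, snr = tr_snr,
                      period_N = tr_N, refit = tr_refit)
  list(output = fs_replace(seq, out, bit_depth = 8L),
       mask = if (return_mask) out > 0L else NULL,
       trace = trace)
}

# Frame-SNR conventions applied to the fused-pass sums.
snr_from_sums <- function(step, n) {
  n_in <- step[["n_tcm"]]
  if (n_in == 0) return(1)
  n_out <- n - n_in
  if (n_out == 0) return(1e6)
  mean_in <- step[["sum_in"]] / n_in
  var_out <- step[["sumsq_out"]] / n_out - (step[["sum_out"]] / n_out)^2
  s <- sqrt(max(var_out, 0))
  if (s == 0) return(1e6)
  min(mean_in / s, 1e6)
}

# One segment-wise mixture refit: fit the full frame, build segments,
# mask + filter each component, and compose the event mask.
refit_event_mask <- function(frame, hw, config, t = NA_integer_,
                             fit_cache = NULL, gray_range = range(frame)) {
  fr <- frame
  dim(fr) <- hw
  key <- as.character(t)
  if (!is.null(fit_cache) && !is.na(t) && !is.null(fit_cache[[key]])) {
    fit <- fit_cache[[key]]
  } else {
    fit <- fit_gmm(fr)
    if (!is.null(fit_cache) && !is.na(t)) fit_cache[[key]] <- fit
  }
  segs <- build_segments(fit, config$min_area, gray_range = gray_range)
  sig <- array(FALSE, hw)
  bg <- array(FALSE, hw)
  for (k in seq_len(nrow(segs))) {
    seg <- segs[k, ]
    fc <- filter_components(segment_mask(fr, seg), seg, fr)
    if (seg$is_signal) sig <- sig | fc$mask else bg <- bg | fc$mask
  }
  m <- compose_event_mask(sig, bg)
  dim(m) <- NULL
  m
}
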