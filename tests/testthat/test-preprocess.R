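test_that("bit promotion preserves values and prevents summation clipping", {
  seq8 <- frame_sequence(array(255L, c(8, 8, 13)), bit_depth = 8L)
  seq16 <- promote_bit_depth(seq8)
  expect_identical(seq16$bit_depth, 16L)
  expect_identical(seq16$frames, seq8$frames)
  acc <- accumulate_frames(seq16, m = 13L)
  expect_true(all(acc$frames == 13L * 255L))  # 3315 <= 65535, no clipping
  expect_warning(promote_bit_depth(seq16), "already 16-bit")
  # without promotion even a 2-frame sum must be refused
  expect_error(accumulate_frames(seq8, m = 2L), "promote")
})

test_that("accumulation implements the sliding-window sum", {
  seq <- frame_sequence(array(7L, c(4, 4, 20)), bit_depth = 16L)
  acc <- accumulate_frames(seq, m = 13L, stride = 1L)
  expect_equal(n_frames(acc), 8L)          # floor((20-13)/1)+1
  expect_true(all(acc$frames == 91L))
  expect_error(accumulate_frames(frame_sequence(array(0L, c(4, 4, 5)),
                                                bit_depth = 16L), m = 13L),
               "at least 13")
  # oracle equivalence on a random 20-frame toy
  set.seed(41)
  frames <- array(sample.int(256L, 4 * 4 * 20, TRUE) - 1L, c(4, 4, 20))
  seq <- frame_sequence(frames, bit_depth = 16L)
  for (m in c(3L, 5L)) for (stride in c(1L, 2L)) {
    acc <- accumulate_frames(seq, m, stride)
    n_out <- (20L - m) %/% stride + 1L
    expect_equal(n_frames(acc), n_out)
    for (j in seq_len(n_out)) {
      i0 <- (j - 1L) * stride + 1L
      brute <- frames[, , i0]
      for (i in (i0 + 1L):(i0 + m - 1L)) brute <- brute + frames[, , i]
      expect_identical(acc$frames[, , j], brute)
    }
  }
})

test_that("accumulation yields the sqrt(m) contrast gain on i.i.d. noise", {
  set.seed(42)
  mu <- 120; sd_n <- 10; m <- 13L
  frames <- array(as.integer(pmin(pmax(round(
    rnorm(32 * 32 * 400, mu, sd_n)), 0), 255)), c(32, 32, 400))
  seq <- promote_bit_depth(frame_sequence(frames, bit_depth = 8L))
  acc <- accumulate_frames(seq, m)
  contrast_raw <- mu / sd_n
  pix <- acc$frames[1, 1, ]   # one pixel's accumulated trajectory
  # use spatial statistics of one accumulated frame for independence
  fr <- as.numeric(acc$frames[, , 1])
  contrast_acc <- mean(fr) / sd(fr)
  expect_equal(contrast_acc / contrast_raw, sqrt(m), tolerance = 0.1 * sqrt(m))
})

test_that("generalized Anscombe transform is monotone with the closed form", {
  expect_equal(astrodetect:::gat_raw(0, 1, 0), 2 * sqrt(0.375))
  x <- seq(0, 255)
  y <- astrodetect:::gat_raw(x, 2, 3)
  expect_true(all(diff(y) > 0))
  seq <- frame_sequence(array(as.integer(0:255), c(16, 16, 1)),
                        bit_depth = 16L)
  out <- generalized_anscombe(seq, gain = 1, read_noise_sigma = 0)
  expect_identical(out$bit_depth, 16L)
  expect_equal(min(out$frames), 0L)
  expect_equal(max(out$frames), 65535L)
  o <- order(seq$frames)
  expect_true(all(diff(out$frames[o]) >= 0))
  expect_error(generalized_anscombe(seq, gain = -1), "gain")
})

test_that("static background is the temporal mean", {
  seq <- frame_sequence(array(5L, c(4, 4, 3)), bit_depth = 16L)
  expect_true(all(estimate_static_background(seq) == 5))
  two <- frame_sequence(array(c(rep(0L, 16), rep(10L, 16)), c(4, 4, 2)),
                        bit_depth = 16L)
  expect_true(all(estimate_static_background(two) == 5))
})

test_that("background subtraction keeps transients and normalizes globally", {
  seq <- frame_sequence(array(100L, c(8, 8, 5)), bit_depth = 16L)
  out <- subtract_background_normalize(seq)
  expect_true(all(out$frames == 0L))
  # a single bright transient: only its pixels are nonzero, and the
  # residual range maps exactly onto [0, 65535]
  frames <- array(100L, c(8, 8, 5))
  frames[3, 3, 2] <- 600L
  seq <- frame_sequence(frames, bit_depth = 16L)
  out <- subtract_background_normalize(seq)
  expect_equal(max(out$frames), 65535L)
  expect_equal(sum(out$frames > 0), 1)
  expect_error(subtract_background_normalize(seq, matrix(0, 2, 2)), "shape")
})

test_that("gaussian smoothing preserves constants and the frame mean", {
  seq <- frame_sequence(array(1000L, c(16, 16, 2)), bit_depth = 16L)
  out <- gaussian_smooth(seq, 1.0)
  expect_true(all(out$frames == 1000L))
  set.seed(43)
  frames <- array(sample.int(65536L, 32 * 32 * 2, TRUE) - 1L, c(32, 32, 2))
  seq <- frame_sequence(frames, bit_depth = 16L)
  out <- gaussian_smooth(seq, 1.0)
  expect_equal(mean(out$frames[, , 1]), mean(frames[, , 1]),
               tolerance = 1e-3 * mean(frames[, , 1]))
})

test_that("smoothing an impulse reproduces the truncated kernel", {
  fr <- matrix(0, 33, 33); fr[17, 17] <- 1
  sm <- astrodetect:::smooth_frame(fr, 1.0)
  k <- astrodetect:::gauss_kernel_1d(1.0)
  expect_equal(sm[17, 17], max(k)^2)
  expect_equal(sm[17, 13:21], k[1:9] * max(k))
  expect_equal(sum(sm), 1)
})

test_that("the full pipeline composes in the documented order", {
  set.seed(44)
  frames <- array(sample.int(256L, 16 * 16 * 40, TRUE) - 1L, c(16, 16, 40))
  seq <- frame_sequence(frames, bit_depth = 8L)
  out <- preprocess_video(seq, preprocess_config())
  expect_identical(out$bit_depth, 16L)
  expect_equal(n_frames(out), 40L - 13L + 1L)
  # degenerate pipeline: m = 1 reduces to background-subtract + smooth
  cfg <- preprocess_config(accumulation_window = 1L, gaussian_sigma = 1e-3)
  out2 <- preprocess_video(seq, cfg)
  ref <- subtract_background_normalize(promote_bit_depth(seq))
  expect_equal(max(abs(out2$frames - ref$frames)), 0)
  expect_error(preprocess_video(out, preprocess_config()), "8-bit")
})

test_that("GAT slots between accumulation and background subtraction", {
  set.seed(45)
  frames <- array(sample.int(256L, 16 * 16 * 30, TRUE) - 1L, c(16, 16, 30))
  seq <- frame_sequence(frames, bit_depth = 8L)
  cfg <- preprocess_config(use_gat = TRUE, gat_gain = 0.5,
                           gat_read_noise_sigma = 5)
  out <- preprocess_video(seq, cfg)
  # manual composition must agree exactly
  x <- accumulate_frames(promote_bit_depth(seq), 13L, 1L)
  x <- generalized_anscombe(x, 0.5, 5)
  x <- subtract_background_normalize(x)
  x <- gaussian_smooth(x, 1.0)
  expect_identical(out$frames, x$frames)
})
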