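test_that("frame statistics match the brute-force two-pass formula", {
  expect_equal(frame_stats(matrix(7, 4, 4)), list(mu = 7, sigma = 0))
  expect_equal(frame_stats(c(0, 0, 10, 10)), list(mu = 5, sigma = 5))
  set.seed(11)
  for (i in 1:5) {
    fr <- random_frame()
    expect_equal(frame_stats(fr), bf_frame_stats(fr))
  }
})

test_that("instantaneous mask matches its oracle on random toys", {
  # constant frame: sigma = 0 and the strict inequality keeps the mask off
  expect_false(any(instantaneous_mask(matrix(5, 8, 8), theta_g = 2)))
  fr <- matrix(c(0, 0, 0, 100), 2, 2)
  expect_false(any(instantaneous_mask(fr, theta_g = 2)))
  fr2 <- matrix(c(rep(0, 96), 1000, rep(0, 3)), 10, 10)
  m <- instantaneous_mask(fr2, theta_g = 2)
  expect_identical(which(m), which(fr2 == 1000))
  set.seed(12)
  for (i in 1:10) {
    fr <- random_frame()
    tg <- runif(1, 0.5, 6)
    expect_identical(instantaneous_mask(fr, theta_g = tg),
                     bf_instantaneous_mask(fr, tg))
  }
})

test_that("count matrix accumulates on consecutive activations and resets", {
  C <- matrix(0L, 4, 4)
  on <- matrix(TRUE, 4, 4)
  off <- matrix(FALSE, 4, 4)
  for (i in 1:5) C <- update_count_matrix(C, on)
  expect_true(all(C == 5L))
  C <- update_count_matrix(C, off)
  expect_true(all(C == 0L))
  # alternating on/off never exceeds 1
  C <- matrix(0L, 4, 4)
  for (i in 1:6) C <- update_count_matrix(C, if (i %% 2) on else off)
  expect_true(all(C <= 1L))
  set.seed(13)
  for (i in 1:10) {
    C <- matrix(sample.int(10L, 16, replace = TRUE) - 1L, 4, 4)
    inst <- matrix(sample(c(TRUE, FALSE), 16, replace = TRUE), 4, 4)
    expect_equal(update_count_matrix(C, inst), bf_update_counts(C, inst),
                 ignore_attr = TRUE)
  }
})

test_that("duration threshold mapping reproduces the 5-frame default", {
  expect_identical(effective_duration_threshold(0.5, 10L), 5L)
  expect_identical(effective_duration_threshold(0.2, 10L), 2L)
  expect_identical(effective_duration_threshold(0.34, 10L), 3L)
})

test_that("temporal mask threshold is inclusive", {
  C <- matrix(c(4L, 5L, 6L, 0L), 2, 2)
  m <- temporal_mask(C, 5L)
  expect_identical(as.vector(m), c(FALSE, TRUE, TRUE, FALSE))
  expect_identical(temporal_mask(C, 1L), C >= 1L)
})

test_that("global threshold update applies 1.2/0.8 factors and clamps", {
  # stable prevalence relaxes, fluctuation tightens (restoring force)
  expect_equal(update_global_threshold(2.0, 0.0005), 1.6)
  expect_equal(update_global_threshold(2.0, 0.01), 2.4)
  expect_equal(update_global_threshold(5.8, 0.01, c(0.5, 6)), 6.0)
  # stability includes slow decreases (absolute-value test)
  expect_equal(update_global_threshold(2.0, -0.0005), 1.6)
  expect_equal(update_global_threshold(0.5, 0.0005, c(0.5, 6)), 0.5)
})

test_that("bright fraction is the on-pixel proportion", {
  expect_equal(bright_fraction(matrix(FALSE, 16, 16)), 0)
  expect_equal(bright_fraction(matrix(TRUE, 16, 16)), 1)
  m <- matrix(FALSE, 256, 256)
  m[seq_len(64)] <- TRUE
  expect_equal(bright_fraction(m), 64 / 65536)
})

test_that("jaccard index matches its oracle and handles empty masks", {
  a <- matrix(FALSE, 10, 10); a[1:10] <- TRUE
  expect_equal(jaccard_index(a, a), 10 / (10 + 1e-9))
  b <- matrix(FALSE, 10, 10); b[91:100] <- TRUE
  expect_equal(jaccard_index(a, b), 0)
  e <- matrix(FALSE, 10, 10)
  expect_equal(jaccard_index(e, e), 0)
  set.seed(14)
  for (i in 1:10) {
    x <- matrix(sample(c(TRUE, FALSE), 256, TRUE), 16, 16)
    y <- matrix(sample(c(TRUE, FALSE), 256, TRUE), 16, 16)
    expect_equal(jaccard_index(x, y), bf_jaccard(x, y))
  }
})

test_that("local threshold update respects cap and floor", {
  expect_equal(update_local_threshold(0.5, 0.9), 0.5)
  expect_equal(update_local_threshold(0.3, 0.5), 0.27)
  expect_equal(update_local_threshold(0.21, 0.1), 0.2)
  expect_equal(update_local_threshold(0.4, 0.71), 0.5)
})

test_that("mask SNR follows the inside-mean / outside-sd definition", {
  fr <- matrix(0, 10, 10)
  mask <- matrix(FALSE, 10, 10)
  mask[1:10] <- TRUE
  fr[mask] <- 100
  out <- fr[!mask]
  fr[!mask] <- rep(c(0, 100), length.out = 90)  # outside sd ~ 50
  sd_out <- sqrt(mean((fr[!mask] - mean(fr[!mask]))^2))
  expect_equal(mask_snr(fr, mask), 100 / sd_out)
  expect_equal(mask_snr(fr, matrix(FALSE, 10, 10)), 1)
  expect_equal(mask_snr(matrix(5, 4, 4), rbind(c(TRUE, rep(FALSE, 3)),
                                               matrix(FALSE, 3, 4))), 1e6)
})

test_that("estimation period maps SNR to [7, 100] frames", {
  expect_identical(update_estimation_period(2), 7L)
  expect_identical(update_estimation_period(1000), 100L)
  expect_identical(update_estimation_period(0.5), 7L)
  for (snr in c(1, 5, 10, 50, 1e6)) {
    N <- update_estimation_period(snr)
    expect_true(N >= 7L && N <= 100L)
  }
})

test_that("window transform matches its oracle and zeroes background", {
  fr <- matrix(3315L, 2, 2)
  on <- matrix(TRUE, 2, 2)
  expect_true(all(window_transform(fr, on, 13L) == 255L))
  expect_true(all(window_transform(fr, !on, 13L) == 0L))
  expect_equal(window_transform(matrix(1658L, 1, 1),
                                matrix(TRUE, 1, 1), 13L),
               matrix(128L, 1, 1))
  set.seed(15)
  for (i in 1:10) {
    fr <- random_frame()
    mask <- matrix(sample(c(TRUE, FALSE), 256, TRUE), 16, 16)
    expect_identical(window_transform(fr, mask, 13L),
                     bf_window_transform(fr, mask, 13L))
  }
})

test_that("window transform is monotone within the mask", {
  set.seed(16)
  fr <- random_frame()
  mask <- matrix(TRUE, 16, 16)
  out <- window_transform(fr, mask, 13L)
  o <- order(fr)
  expect_true(all(diff(out[o]) >= 0))
})

test_that("8-connected labeling matches a flood-fill oracle", {
  # two diagonal-touching pixels form one component
  m <- matrix(FALSE, 4, 4); m[1, 1] <- TRUE; m[2, 2] <- TRUE
  expect_identical(max(cpp_label8(m)), 1L)
  set.seed(17)
  for (i in 1:10) {
    mask <- matrix(runif(256) < 0.4, 16, 16)
    expect_identical(canon_labels(cpp_label8(mask)),
                     canon_labels(bf_label8(mask)))
  }
})

test_that("component filtering enforces area and intensity elevation", {
  fr <- matrix(0L, 12, 12)
  fr[3:8, 3:8] <- 1000L  # 36-px bright block
  seg <- list(L = 500, H = 2000, tau_g = 100, tau_a = 29)
  m <- segment_mask(fr, seg)
  fc <- filter_components(m, seg, fr)
  expect_equal(sum(fc$mask), 36)
  # raise the area threshold above the region size: rejected
  seg$tau_a <- 37
  fc2 <- filter_components(m, seg, fr)
  expect_equal(sum(fc2$mask), 0)
  # dim region fails the intensity elevation criterion
  seg3 <- list(L = 500, H = 2000, tau_g = 600, tau_a = 29)
  fc3 <- filter_components(m, seg3, fr)
  expect_equal(sum(fc3$mask), 0)
})

test_that("event mask composition suppresses background regions", {
  sig <- matrix(FALSE, 6, 6); sig[2:4, 2:4] <- TRUE
  bg <- matrix(FALSE, 6, 6); bg[4:6, 4:6] <- TRUE
  m <- compose_event_mask(sig, bg)
  expect_false(m[4, 4])
  expect_true(m[2, 2])
  expect_equal(sum(m), sum(sig) - 1)
  expect_equal(sum(compose_event_mask(matrix(FALSE, 6, 6), bg)), 0)
})

test_that("segment mask bounds are inclusive and match the oracle", {
  fr <- matrix(c(10L, 20L, 30L, 40L), 2, 2)
  m <- segment_mask(fr, list(L = 20, H = 30))
  expect_identical(as.vector(m), c(FALSE, TRUE, TRUE, FALSE))
  set.seed(18)
  for (i in 1:5) {
    fr <- random_frame()
    L <- 20000; H <- 50000
    expect_identical(segment_mask(fr, list(L = L, H = H)),
                     bf_segment_mask(fr, L, H))
  }
})

test_that("detection state invariants hold on a long random-noise trace", {
  set.seed(19)
  frames <- array(as.integer(pmax(0, pmin(65535,
    rnorm(32 * 32 * 1000, 3000, 1500)))), c(32, 32, 1000))
  seq <- frame_sequence(frames, bit_depth = 16L)
  det <- run_detection(seq, detector_config())
  tr <- det$trace
  expect_true(all(tr$theta_g >= 0.5 & tr$theta_g <= 6))
  expect_true(all(tr$theta_l >= 0.2 & tr$theta_l <= 0.5))
  expect_true(all(tr$period_N >= 7L & tr$period_N <= 100L))
  # default duration reference: effective threshold spans 1..3 frames
  expect_true(all(tr$duration_threshold >= 1L & tr$duration_threshold <= 3L))
  expect_true(all(tr$rho >= 0 & tr$rho <= 1))
  expect_true(tr$refit[1])
})

test_that("detection output support is nested in the temporal gate", {
  # the 8-bit output must be zero wherever the mask stack is off
  set.seed(20)
  frames <- array(as.integer(runif(24 * 24 * 120, 0, 65535)),
                  c(24, 24, 120))
  seq <- frame_sequence(frames, bit_depth = 16L)
  det <- run_detection(seq)
  expect_true(all(det$output$frames[!det$mask] == 0L))
  expect_true(all(det$output$frames[det$mask] > 0L))
})

test_that("an all-constant video yields empty masks and zero output", {
  seq <- frame_sequence(array(777L, c(16, 16, 30)), bit_depth = 16L)
  det <- run_detection(seq)
  expect_equal(sum(det$mask), 0)
  expect_true(all(det$output$frames == 0L))
})

test_that("run_detection rejects 8-bit input and empty sequences", {
  expect_error(run_detection(frame_sequence(array(0L, c(8, 8, 2)),
                                            bit_depth = 8L)),
               "16-bit")
})
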