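test_that("background generation is deterministic and structured", {
  b1 <- generate_background(64, 64, seed = 1)
  b2 <- generate_background(64, 64, seed = 1)
  expect_identical(b1, b2)
  b3 <- generate_background(64, 64, seed = 2)
  expect_false(identical(b1, b3))
  expect_true(min(b1) >= 0 && max(b1) <= 1)
  # skeleton density: bright structures cover a plausible fraction
  frac <- mean(b1 > 0.5 * max(b1))
  expect_gt(frac, 0.01)
  expect_lt(frac, 0.60)
  # spatial autocorrelation beyond 1 px (structured, not white)
  ac <- cor(as.numeric(b1[-1, ]), as.numeric(b1[-64, ]))
  expect_gt(ac, 0.5)
  expect_error(generate_background(16, 64), "32")
})

test_that("event generation honours the count and duration contracts", {
  cfg <- small_sim_config(seed = 5)
  ev <- generate_events(cfg)
  expect_equal(nrow(ev$events), cfg$n_events)
  expect_true(all(dim(ev$clean) == c(64, 64, 200)))
  min_frames <- ceiling(cfg$min_event_duration * cfg$frame_rate)
  durations <- ev$events$end_frame - ev$events$start_frame + 1L
  expect_true(all(durations >= min_frames))
  expect_true(all(durations / cfg$frame_rate >= cfg$min_event_duration))
  for (i in seq_len(nrow(ev$events)))
    expect_equal(nrow(ev$events$trajectory[[i]]), durations[i])
  # zero events: silent stack, empty table
  cfg0 <- small_sim_config(seed = 5, n_events = 0)
  ev0 <- generate_events(cfg0)
  expect_true(all(ev0$clean == 0L))
  expect_equal(nrow(ev0$events), 0)
  expect_false(any(ev0$mask))
})

test_that("every event keeps a mask-positive pixel for its whole duration", {
  cfg <- small_sim_config(seed = 6)
  ev <- generate_events(cfg)
  for (i in seq_len(nrow(ev$events))) {
    fr <- ev$events$start_frame[i]:ev$events$end_frame[i]
    per_frame <- vapply(fr, function(t) sum(ev$mask[, , t]), numeric(1))
    expect_true(all(per_frame >= 1))
  }
})

test_that("mask-positive pixels carry at least the activity threshold", {
  cfg <- small_sim_config(seed = 7)
  ev <- generate_events(cfg)
  thr <- 0.5 * min(ev$events$peak_amplitude) * 65535
  expect_true(all(ev$clean[ev$mask] >= thr * (1 - 1e-6)))
})

test_that("fusion applies the 0.2/0.8 weights on the 8-bit scale", {
  h <- 32; w <- 32
  bg0 <- matrix(0, h, w)
  sig1 <- array(1, c(h, w, 2))
  out <- fuse_frames(sig1, bg0, 0.2, 0.8)
  expect_true(all(out$frames == 51L))        # 0.2 * 255
  out2 <- fuse_frames(sig1, matrix(1, h, w), 0.2, 0.8)
  expect_true(all(out2$frames == 255L))      # full scale
  out3 <- fuse_frames(array(0, c(h, w, 2)), matrix(0.5, h, w), 0.2, 0.8)
  expect_true(all(out3$frames == 102L))      # 0.8 * 0.5 * 255
  expect_error(fuse_frames(sig1, matrix(0, 8, 8)), "shape")
  expect_error(fuse_frames(sig1, bg0, 0.5, 0.6), "sum to 1")
})

test_that("Poisson-Gaussian noise matches its variance identity", {
  x <- frame_sequence(array(100L, c(64, 64, 8)), bit_depth = 8L)
  gain <- 2
  noisy <- add_poisson_gaussian_noise(x, gain, gaussian_sigma = 3,
                                      seed = 9)
  v <- var(as.numeric(noisy$frames))
  expected <- 100 / gain + 9
  expect_equal(v, expected, tolerance = 0.15 * expected)
  # noise-free limit: huge gain, zero sigma
  clean <- add_poisson_gaussian_noise(x, 1e5, 0, seed = 9)
  expect_lt(mean(abs(clean$frames - 100)), 0.05)
  # determinism
  n2 <- add_poisson_gaussian_noise(x, gain, 3, seed = 9)
  expect_identical(noisy$frames, n2$frames)
  expect_error(add_poisson_gaussian_noise(x, -1, 1), "poisson_gain")
  expect_error(add_poisson_gaussian_noise(x, 1, -1), "gaussian_sigma")
})

test_that("the variance/mean ratio of repeated draws follows 1/gain", {
  gain <- 0.5
  x <- frame_sequence(array(80L, c(8, 8, 1)), bit_depth = 8L)
  draws <- vapply(1:1000, function(s) {
    as.numeric(add_poisson_gaussian_noise(x, gain, 0,
                                          seed = s)$frames[1, 1, 1])
  }, numeric(1))
  ratio <- var(draws) / mean(draws)
  se <- sqrt(2 / length(draws)) * (1 / gain)  # approx SE of the ratio
  expect_lt(abs(ratio - 1 / gain), 3 * se + 0.1)
})

test_that("simulation is deterministic and composes all stages", {
  cfg <- small_sim_config(seed = 11)
  s1 <- simulate_video(cfg)
  s2 <- simulate_video(cfg)
  expect_identical(s1$video$frames, s2$video$frames)
  expect_identical(s1$truth$clean, s2$truth$clean)
  expect_identical(s1$truth$mask, s2$truth$mask)
  expect_identical(s1$video$bit_depth, 8L)
  expect_equal(nrow(s1$truth$events), cfg$n_events)
  expect_gt(sum(s1$truth$mask), 0)
  # different seed: same event count, different trajectories
  s3 <- simulate_video(small_sim_config(seed = 12))
  expect_equal(nrow(s3$truth$events), cfg$n_events)
  expect_false(identical(s1$truth$events$x_start, s3$truth$events$x_start))
})

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(signal_weight = 0.3,
                                 background_weight = 0.8), "equal 1")
  expect_error(simulation_config(n_events = -1), "n_events")
  expect_error(simulation_config(min_event_duration = 0.001), "frame period")
  expect_error(simulation_config(spot_sigma_range = c(6, 2)), "low <= high")
  expect_error(simulation_config(poisson_gain = 0), "poisson_gain")
  expect_error(simulation_config(width = 16), "32")
})

test_that("the default configuration matches the study conditions", {
  cfg <- simulation_config()
  expect_equal(cfg$n_events, 97L)
  expect_equal(cfg$duration * cfg$frame_rate, 2400)
  expect_equal(cfg$signal_weight, 0.2)
  expect_equal(cfg$background_weight, 0.8)
  expect_equal(cfg$min_event_duration, 1 / 3, tolerance = 1e-9)
})
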