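test_that("simulated recordings have the configured size and segmentation", {
  cfg <- simulation_config(duration_s = 60, n_episodes = 0, seed = 1)
  rec <- simulate_recording(cfg)
  expect_equal(nrow(rec$signal), 60 * 128)
  expect_equal(length(rec$segment_labels), 4)
  expect_true(all(rec$segment_labels == 0L))
  expect_equal(nrow(rec$truth_episodes), 0)
})

test_that("segment labeling follows the >=50% overlap rule", {
  # one 30-s episode forced to [15, 45] s inside a 60-s recording
  cfg <- simulation_config(duration_s = 60, n_episodes = 1,
                           episode_duration_range_s = c(30, 30),
                           inter_episode_gap_range_s = c(15, 15), seed = 7)
  rec <- simulate_recording(cfg)
  expect_equal(rec$truth_episodes$start_s, 15)
  expect_equal(rec$truth_episodes$end_s, 45)
  expect_equal(rec$segment_labels, c(0L, 1L, 1L, 0L))
})

test_that("recordings are deterministic under the seed and leave the RNG alone", {
  cfg <- simulation_config(duration_s = 120, n_episodes = 1,
                           episode_duration_range_s = c(30, 40),
                           inter_episode_gap_range_s = c(20, 40), seed = 11)
  set.seed(42)
  before <- rnorm(1)
  set.seed(42)
  r1 <- simulate_recording(cfg)
  after <- rnorm(1)
  r2 <- simulate_recording(cfg)
  expect_identical(r1, r2)
  expect_identical(before, after)
})

test_that("invalid simulation configs are rejected", {
  expect_error(simulation_config(duration_s = -5), class = "intakefuse_config_error")
  expect_error(simulation_config(sample_rate_hz = 0), class = "intakefuse_config_error")
  expect_error(simulation_config(chew_amplitude = -1), class = "intakefuse_config_error")
  # episodes that cannot fit
  bad <- simulation_config(duration_s = 100, n_episodes = 3,
                           episode_duration_range_s = c(60, 60),
                           inter_episode_gap_range_s = c(60, 60))
  expect_error(simulate_recording(bad), class = "intakefuse_config_error")
})

test_that("every episode of at least one window length yields an intake segment", {
  for (seed in 1:5) {
    cfg <- simulation_config(duration_s = 600, n_episodes = 3,
                             episode_duration_range_s = c(20, 60),
                             inter_episode_gap_range_s = c(30, 90),
                             seed = seed)
    rec <- simulate_recording(cfg)
    seg_start <- (seq_along(rec$segment_labels) - 1) * rec$window_s
    for (e in seq_len(nrow(rec$truth_episodes))) {
      ep <- rec$truth_episodes[e, ]
      if (ep$end_s - ep$start_s < rec$window_s) next
      ov <- pmax(0, pmin(seg_start + rec$window_s, ep$end_s) -
                   pmax(seg_start, ep$start_s))
      expect_true(any(rec$segment_labels[ov >= rec$window_s / 2] == 1L),
                  info = sprintf("seed %d episode %d", seed, e))
    }
  }
})

test_that("score streams respect capture and false-positive semantics", {
  lab <- rep(c(1L, 0L), 10)
  cfg <- score_stream_config(p_capture = 1, fp_rate = 0,
                             missing_image_rate = 0, seed = 3)
  s <- simulate_score_streams(lab, cfg)
  expect_equal(nrow(s), 20)
  expect_true(all(s$Sf[lab == 0L] == 0))
  expect_true(all(s$Sf[lab == 1L] > 0))
  expect_true(all(s$Sb[lab == 0L] == 0))
  expect_true(all(s$Ss >= 0 & s$Ss <= 1))

  s2 <- simulate_score_streams(lab, cfg)
  expect_identical(s, s2)
  expect_error(simulate_score_streams(integer(0), cfg),
               class = "intakefuse_data_error")
})

test_that("false-positive fraction concentrates at the configured rate", {
  lab <- rep(0L, 1e4)
  cfg <- score_stream_config(fp_rate = 0.2, missing_image_rate = 0, seed = 5)
  s <- simulate_score_streams(lab, cfg)
  expect_lt(abs(mean(s$Sf > 0) - 0.2), 0.02)
})

test_that("missing images zero out both image streams", {
  lab <- rep(1L, 200)
  cfg <- score_stream_config(p_capture = 1, missing_image_rate = 0.5, seed = 9)
  s <- simulate_score_streams(lab, cfg)
  expect_true(any(s$missing))
  expect_true(all(s$Sf[s$missing] == 0))
  expect_true(all(s$Sb[s$missing] == 0))
})

test_that("detection fixtures jitter truth boxes and add spurious boxes", {
  ds <- simulate_detections(10, 2, perturbation = 0, spurious_rate = 0, seed = 2)
  expect_equal(nrow(ds$truth_boxes), 20)
  expect_equal(nrow(ds$detections), 20)
  for (i in seq_len(nrow(ds$detections))) {
    expect_equal(iou(as.numeric(ds$detections[i, c("x", "y", "w", "h")]),
                     as.numeric(ds$truth_boxes[i, c("x", "y", "w", "h")])), 1.0)
  }
  expect_equal(nrow(simulate_detections(0, 1, seed = 1)$detections), 0)

  big <- simulate_detections(1000, 1, perturbation = 2, spurious_rate = 0.5,
                             seed = 8)
  n_spur <- sum(big$detections$spurious)
  expect_lt(abs(n_spur - 500), 50)
  expect_identical(big, simulate_detections(1000, 1, perturbation = 2,
                                            spurious_rate = 0.5, seed = 8))
})
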