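make_recording <- function(n_samples, fs = 128) {
  structure(list(signal = matrix(rnorm(n_samples * 3), ncol = 3,
                                 dimnames = list(NULL, c("ax", "ay", "az"))),
                 sample_rate_hz = fs, window_s = 15,
                 segment_labels = integer(0),
                 truth_episodes = data.frame(start_s = numeric(0),
                                             end_s = numeric(0))),
            class = "labeled_recording")
}

test_that("segmentation uses fixed 15-s windows and drops the partial tail", {
  set.seed(1)
  segs <- segment_signal(make_recording(1920), window_s = 15)
  expect_length(segs, 1)
  expect_equal(dim(segs[[1]]), c(1920, 3))

  expect_length(segment_signal(make_recording(3840)), 2)
  segs <- segment_signal(make_recording(2000))
  expect_length(segs, 1)
  expect_equal(attr(segs[[1]], "start_time_s"), 0)
  expect_length(segment_signal(make_recording(1000)), 0)
})

test_that("the scalogram grid is 64 frequencies x 1920 samples", {
  set.seed(2)
  rs <- cwt_scalogram(rnorm(1920))
  expect_equal(dim(rs$magnitude), c(64, 1920))
  expect_length(rs$freq_axis_hz, 64)
  expect_equal(range(rs$freq_axis_hz), c(1, 64))
  expect_true(all(rs$magnitude >= 0))
})

test_that("zero input gives a zero scalogram and invalid input errors", {
  rs <- cwt_scalogram(numeric(1920))
  expect_equal(max(rs$magnitude), 0)
  bad <- rnorm(1920)
  bad[5] <- NaN
  expect_error(cwt_scalogram(bad), class = "intakefuse_data_error")
  cfg <- cwt_config(freq_max_hz = 64)
  expect_error(cwt_scalogram(rnorm(1920), cfg, sample_rate_hz = 100),
               class = "intakefuse_config_error")
})

test_that("a pure tone peaks at the nearest frequency bin", {
  t <- (0:1919) / 128
  for (f0 in c(2, 4, 10)) {
    rs <- cwt_scalogram(sin(2 * pi * f0 * t))
    peak <- which.max(rowMeans(rs$magnitude))
    expect_equal(peak, which.min(abs(rs$freq_axis_hz - f0)),
                 info = sprintf("tone %g Hz", f0))
  }
})

test_that("the transform is linear in the input amplitude", {
  set.seed(3)
  x <- rnorm(1920)
  r1 <- cwt_scalogram(x)
  r3 <- cwt_scalogram(3 * x)
  expect_equal(r3$magnitude, 3 * r1$magnitude, tolerance = 1e-12)
})

test_that("linear frequency spacing is available", {
  cfg <- cwt_config(freq_spacing = "linear")
  expect_equal(diff(cwt_frequencies(cfg)), rep(1, 63))
  cfgg <- cwt_config()
  f <- cwt_frequencies(cfgg)
  expect_equal(f[2] / f[1], f[64] / f[63], tolerance = 1e-10)
})

test_that("8-bit quantization maps min/max to 0/255 with midpoint 128", {
  S <- matrix(c(0, 2.5, 5, 10), 2, 2)
  q <- quantize_scalogram(S)
  expect_equal(q[1, 1], 0L)
  expect_equal(q[2, 2], 255L)
  # (S_min + S_max)/2 -> 127.5 -> 128 under round-half-away-from-zero
  expect_equal(quantize_scalogram(matrix(c(0, 5, 10), 1))[1, 2], 128L)
  expect_true(all(q >= 0 & q <= 255))
})

test_that("a constant scalogram quantizes to all zeros with a warning", {
  expect_warning(q <- quantize_scalogram(matrix(7, 4, 4)), "constant")
  expect_true(all(q == 0L))
})

test_that("assembly concatenates three axes and downsamples time to 192", {
  set.seed(4)
  axes <- lapply(1:3, function(i) {
    matrix(sample(0:255, 64 * 1920, replace = TRUE), 64, 1920)
  })
  img <- assemble_scalogram(axes)
  expect_equal(dim(unclass(img)), c(192, 192))
  expect_true(all(img >= 0 & img <= 255))
  # constant input is preserved exactly by bilinear interpolation
  const <- lapply(1:3, function(i) matrix(37L, 64, 1920))
  expect_true(all(assemble_scalogram(const) == 37L))
  # axis order is x, y, z top to bottom
  marked <- list(matrix(10L, 64, 1920), matrix(20L, 64, 1920),
                 matrix(30L, 64, 1920))
  out <- assemble_scalogram(marked)
  expect_true(all(out[1:64, ] == 10L))
  expect_true(all(out[129:192, ] == 30L))
  expect_error(assemble_scalogram(axes[1:2]), class = "intakefuse_data_error")
  expect_error(assemble_scalogram(list(axes[[1]], axes[[2]],
                                       matrix(0L, 32, 1920))),
               class = "intakefuse_data_error")
})

test_that("bilinear downsampling averages the two nearest source columns", {
  m <- matrix(as.numeric(1:1920), 1, 1920, byrow = TRUE)
  out <- intakefuse:::resize_columns_bilinear(m, 192)
  # output column j has source centre at 10*j - 5.5 (1-based columns), the
  # mean of columns 10j-5 and 10j-4
  j <- c(1, 50, 192)
  expect_equal(out[1, j], (m[1, 10 * j - 5] + m[1, 10 * j - 4]) / 2)
})

test_that("end-to-end shapes run 1920 -> 64x1920 -> 192x192 and PNG roundtrips", {
  set.seed(5)
  seg <- matrix(rnorm(1920 * 3), 1920, 3)
  attr(seg, "sample_rate_hz") <- 128
  img <- scalogram_from_segment(seg)
  expect_equal(dim(unclass(img)), c(192, 192))
  path <- tempfile(fileext = ".png")
  write_scalogram_png(img, path, label = 1, start_time_s = 0)
  back <- read_scalogram_png(path)
  expect_equal(unclass(back), unclass(img), ignore_attr = TRUE)
  expect_true(file.exists(paste0(path, ".json")))
})

test_that("intake segments carry more chew-band energy than non-intake", {
  cfg <- simulation_config(duration_s = 600, n_episodes = 2,
                           episode_duration_range_s = c(60, 120),
                           inter_episode_gap_range_s = c(60, 120),
                           chew_amplitude = 0.2, noise_amplitude = 0.02,
                           seed = 21)
  rec <- simulate_recording(cfg)
  segs <- segment_signal(rec)
  ccfg <- cwt_config()
  band <- function(seg) {
    rs <- cwt_scalogram(seg[, 1] - mean(seg[, 1]), ccfg)
    rows <- rs$freq_axis_hz >= 1 & rs$freq_axis_hz <= 2.5
    mean(rs$magnitude[rows, ])
  }
  e <- vapply(segs, band, numeric(1))
  lab <- rec$segment_labels
  expect_gt(mean(e[lab == 1]), mean(e[lab == 0]))
})
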