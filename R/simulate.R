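#' Configuration for a synthetic accelerometer recording
#'
#' Describes a free-living-style tri-axial accelerometer recording containing a
#' given number of eating episodes. Chewing inside an episode is modelled as an
#' amplitude-modulated sinusoid whose instantaneous frequency drifts within the
#' chewing band, superimposed on a slowly varying gravity/posture baseline,
#' Gaussian sensor noise and occasional broadband motion artifacts.
#'
#' @param duration_s Recording length in seconds.
#' @param sample_rate_hz Sampling rate in Hz (the device samples at 128 Hz).
#' @param n_episodes Number of eating episodes to embed.
#' @param episode_duration_range_s Length-2 vector, min/max episode duration (s).
#' @param inter_episode_gap_range_s Length-2 vector, min/max gap between
#'   episodes (s); the gap before the first episode is drawn from the same
#'   range.
#' @param chew_freq_range_hz Length-2 vector, chewing-band frequency range (Hz).
#' @param chew_amplitude Peak chewing oscillation amplitude, g-units.
#' @param noise_amplitude Standard deviation of the Gaussian sensor noise,
#'   g-units.
#' @param motion_artifact_rate Expected broadband motion artifacts per hour.
#' @param seed Integer seed; all draws flow from one seeded generator per call.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(duration_s = 5400,
                              sample_rate_hz = 128,
                              n_episodes = 2,
                              episode_duration_range_s = c(180, 480),
                              inter_episode_gap_range_s = c(960, 1500),
                              chew_freq_range_hz = c(1.0, 2.5),
                              chew_amplitude = 0.15,
                              noise_amplitude = 0.03,
                              motion_artifact_rate = 30,
                              seed = 1L) {
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop_config("duration_s must be > 0")
  }
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0) {
    stop_config("sample_rate_hz must be > 0")
  }
  if (chew_amplitude < 0) stop_config("chew_amplitude must be >= 0")
  if (noise_amplitude < 0) stop_config("noise_amplitude must be >= 0")
  if (n_episodes < 0) stop_config("n_episodes must be >= 0")
  stopifnot(length(episode_duration_range_s) == 2,
            length(inter_episode_gap_range_s) == 2,
            length(chew_freq_range_hz) == 2)
  structure(list(duration_s = duration_s,
                 sample_rate_hz = sample_rate_hz,
                 n_episodes = as.integer(n_episodes),
                 episode_duration_range_s = episode_duration_range_s,
                 inter_episode_gap_range_s = inter_episode_gap_range_s,
                 chew_freq_range_hz = chew_freq_range_hz,
                 chew_amplitude = chew_amplitude,
                 noise_amplitude = noise_amplitude,
                 motion_artifact_rate = motion_artifact_rate,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# place episodes sequentially: gap, episode, gap, episode, ...
place_episodes <- function(config) {
  n <- config$n_episodes
  if (n == 0L) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  dur <- runif(n, config$episode_duration_range_s[1],
               config$episode_duration_range_s[2])
  gap <- runif(n, config$inter_episode_gap_range_s[1],
               config$inter_episode_gap_range_s[2])
  start <- cumsum(gap) + c(0, cumsum(dur))[seq_len(n)]
  end <- start + dur
  if (end[n] > config$duration_s) {
    stop_config("episodes do not fit into duration_s: shorten episodes/gaps ",
                "or extend the recording")
  }
  data.frame(start_s = start, end_s = end)
}

# label a segment intake iff >= `frac` of the window lies inside an episode
label_segments <- function(episodes, n_segments, window_s, frac = 0.5) {
  labels <- integer(n_segments)
  if (nrow(episodes) == 0L || n_segments == 0L) return(labels)
  seg_start <- (seq_len(n_segments) - 1) * window_s
  for (i in seq_len(n_segments)) {
    a <- seg_start[i]
    b <- a + window_s
    ov <- sum(pmax(0, pmin(b, episodes$end_s) - pmax(a, episodes$start_s)))
    if (ov >= frac * window_s) labels[i] <- 1L
  }
  labels
}

#' Simulate a labeled tri-axial accelerometer recording
#'
#' Generates a recording with embedded eating episodes and derives per-segment
#' intake labels: a 15-s segment is labeled intake when at least half of it
#' lies inside a ground-truth episode. Identical config and seed give
#' byte-identical output; the global RNG state is left untouched.
#'
#' @param config A [simulation_config()].
#' @return An object of class `labeled_recording`: list with `signal`
#'   (n_samples x 3 matrix, g-units, columns ax/ay/az), `sample_rate_hz`,
#'   `window_s`, `segment_labels` (0/1 per 15-s segment), and `truth_episodes`
#'   (data frame start_s/end_s).
#' @export
simulate_recording <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  fs <- config$sample_rate_hz
  n <- floor(config$duration_s * fs)
  window_s <- 15
  with_seed(config$seed, {
    episodes <- place_episodes(config)
    t <- (seq_len(n) - 1) / fs

    # gravity/posture baseline: constant orientation + slow sway per axis
    signal <- matrix(0, n, 3, dimnames = list(NULL, c("ax", "ay", "az")))
    offset <- c(0, 0, 1)
    for (ax in 1:3) {
      sway <- numeric(n)
      for (h in 1:2) {
        f <- runif(1, 0.02, 0.15)
        sway <- sway + runif(1, 0.01, 0.05) * sin(2 * pi * f * t + runif(1, 0, 2 * pi))
      }
      signal[, ax] <- offset[ax] + sway + rnorm(n, sd = config$noise_amplitude)
    }

    # broadband motion artifacts (posture changes, walking bouts)
    n_art <- rpois(1, config$motion_artifact_rate * config$duration_s / 3600)
    for (k in seq_len(n_art)) {
      ctr <- runif(1, 0, config$duration_s)
      wid <- runif(1, 0.5, 3)
      amp <- runif(1, 0.1, 0.3)
      ax <- sample.int(3, 1)
      pulse <- amp * exp(-((t - ctr)^2) / (2 * (wid / 3)^2)) *
        sin(2 * pi * runif(1, 3, 10) * t)
      signal[, ax] <- signal[, ax] + pulse
    }

    # chewing bursts: AM sinusoid with drifting frequency, bite/pause envelope
    for (e in seq_len(nrow(episodes))) {
      i0 <- max(1L, floor(episodes$start_s[e] * fs) + 1L)
      i1 <- min(n, floor(episodes$end_s[e] * fs))
      if (i1 <= i0) next
      m <- i1 - i0 + 1L
      f0 <- runif(1, config$chew_freq_range_hz[1], config$chew_freq_range_hz[2])
      drift <- cumsum(rnorm(m, sd = 0.002))
      freq <- pmin(pmax(f0 + drift, config$chew_freq_range_hz[1]),
                   config$chew_freq_range_hz[2])
      phase <- cumsum(2 * pi * freq / fs)
      # alternate chewing sequences and pauses (bites)
      env <- numeric(m)
      pos <- 1L
      while (pos <= m) {
        chew_len <- round(runif(1, 4, 8) * fs)
        pause_len <- round(runif(1, 0.5, 2) * fs)
        hi <- min(m, pos + chew_len - 1L)
        # quick attack then flat top
        env[pos:hi] <- pmin(1, seq_len(hi - pos + 1L) / (0.5 * fs))
        pos <- hi + pause_len + 1L
      }
      w <- runif(3, 0.4, 1)
      osc <- config$chew_amplitude * env * sin(phase)
      for (ax in 1:3) signal[i0:i1, ax] <- signal[i0:i1, ax] + w[ax] * osc
    }

    n_seg <- floor(n / (window_s * fs))
    labels <- label_segments(episodes, n_seg, window_s)
    structure(list(signal = signal,
                   sample_rate_hz = fs,
                   window_s = window_s,
                   segment_labels = labels,
                   truth_episodes = episodes),
              class = "labeled_recording")
  })
}

#' @export
print.labeled_recording <- function(x, ...) {
  cat(sprintf("<labeled_recording> %d samples @ %g Hz (%.1f s), %d segments, %d episodes\n",
              nrow(x$signal), x$sample_rate_hz,
              nrow(x$signal) / x$sample_rate_hz,
              length(x$segment_labels), nrow(x$truth_episodes)))
  invisible(x)
}

#' Configuration for synthetic detector score streams
#'
#' Emulates the per-segment confidence streams an image-based food/beverage
#' detector and the sensor classifier would produce, including image false
#' positives (food visible but not consumed) and missing images.
#'
#' @param p_capture Probability that a food (and, independently, a beverage)
#'   object is detected during an intake segment.
#' @param fp_rate Probability of a spurious food/beverage score in a
#'   non-intake segment.
#' @param score_dist_pos,score_dist_neg Length-2 Beta parameters for scores
#'   conditioned on (true) presence / absence.
#' @param missing_image_rate Probability a segment's image is missing.
#' @param seed Integer seed.
#' @return An object of class `score_stream_config`.
#' @export
score_stream_config <- function(p_capture = 0.9,
                                fp_rate = 0.05,
                                score_dist_pos = c(8, 2),
                                score_dist_neg = c(2, 8),
                                missing_image_rate = 0.05,
                                seed = 1L) {
  assert_prob(p_capture, "p_capture")
  assert_prob(fp_rate, "fp_rate")
  assert_prob(missing_image_rate, "missing_image_rate")
  stopifnot(length(score_dist_pos) == 2, length(score_dist_neg) == 2,
            all(score_dist_pos > 0), all(score_dist_neg > 0))
  structure(list(p_capture = p_capture, fp_rate = fp_rate,
                 score_dist_pos = score_dist_pos,
                 score_dist_neg = score_dist_neg,
                 missing_image_rate = missing_image_rate,
                 seed = as.integer(seed)),
            class = "score_stream_config")
}

#' Simulate aligned confidence score streams Sf, Sb, Ss
#'
#' For intake segments the food score `Sf` is drawn from the positive Beta
#' distribution with probability `p_capture` (else 0); for non-intake segments
#' from the negative distribution with probability `fp_rate` (else 0). The
#' beverage stream `Sb` behaves analogously and independently. The sensor
#' stream `Ss` is always present and drawn from the positive/negative
#' distribution according to the label. Segments flagged missing get
#' `Sf = Sb = 0`.
#'
#' @param labels Integer/logical vector of per-segment intake labels.
#' @param config A [score_stream_config()].
#' @param window_s Segment length in seconds (for segment start times).
#' @return A [confidence_series()] data frame.
#' @export
simulate_score_streams <- function(labels, config, window_s = 15) {
  stopifnot(inherits(config, "score_stream_config"))
  if (length(labels) == 0L) stop_data("labels must be non-empty")
  lab <- as.integer(as.logical(labels))
  n <- length(lab)
  with_seed(config$seed, {
    draw_stream <- function() {
      present <- ifelse(lab == 1L,
                        rbinom(n, 1, config$p_capture),
                        rbinom(n, 1, config$fp_rate))
      value <- ifelse(lab == 1L,
                      rbeta(n, config$score_dist_pos[1], config$score_dist_pos[2]),
                      rbeta(n, config$score_dist_neg[1], config$score_dist_neg[2]))
      present * value
    }
    Sf <- draw_stream()
    Sb <- draw_stream()
    Ss <- ifelse(lab == 1L,
                 rbeta(n, config$score_dist_pos[1], config$score_dist_pos[2]),
                 rbeta(n, config$score_dist_neg[1], config$score_dist_neg[2]))
    missing <- rbinom(n, 1, config$missing_image_rate) == 1
    Sf[missing] <- 0
    Sb[missing] <- 0
    confidence_series(Sf = Sf, Sb = Sb, Ss = Ss,
                      t_start_s = (seq_len(n) - 1) * window_s,
                      label = lab, missing = missing)
  })
}

#' Simulate an object-detection fixture with ground-truth boxes
#'
#' Ground-truth food/beverage boxes are placed in each image; detections are
#' the truth boxes jittered by at most `perturbation` pixels (with high
#' confidence scores), plus low-score spurious boxes added per image with
#' probability `spurious_rate`.
#'
#' @param n_images Number of images.
#' @param boxes_per_image Ground-truth boxes per image.
#' @param perturbation Maximum absolute jitter, pixels, applied to x/y/w/h.
#' @param spurious_rate Probability of adding one spurious detection per image.
#' @param seed Integer seed.
#' @param image_width,image_height Image dimensions in pixels.
#' @return An object of class `detection_set`: list with `images`,
#'   `truth_boxes` and `detections` data frames (boxes as x/y/w/h with class
#'   `"food"` or `"beverage"`; detections also carry `score` and a `spurious`
#'   flag).
#' @export
simulate_detections <- function(n_images, boxes_per_image = 1,
                                perturbation = 0, spurious_rate = 0,
                                seed = 1L,
                                image_width = 640, image_height = 480) {
  if (n_images < 0 || boxes_per_image < 0) stop_config("counts must be >= 0")
  assert_prob(spurious_rate, "spurious_rate")
  classes <- c("food", "beverage")
  with_seed(seed, {
    nb <- n_images * boxes_per_image
    truth <- data.frame(image_id = rep(seq_len(n_images), each = boxes_per_image),
                        x = numeric(nb), y = numeric(nb),
                        w = numeric(nb), h = numeric(nb),
                        class = character(nb),
                        stringsAsFactors = FALSE)
    if (nb > 0) {
      truth$w <- runif(nb, 40, 160)
      truth$h <- runif(nb, 40, 160)
      truth$x <- runif(nb, 0, image_width - truth$w)
      truth$y <- runif(nb, 0, image_height - truth$h)
      truth$class <- sample(classes, nb, replace = TRUE)
    }
    det <- truth
    if (nb > 0) {
      jit <- function(v) v + runif(nb, -perturbation, perturbation)
      det$x <- jit(det$x)
      det$y <- jit(det$y)
      det$w <- pmax(1, jit(det$w))
      det$h <- pmax(1, jit(det$h))
      det$score <- runif(nb, 0.6, 1)
      det$spurious <- FALSE
    } else {
      det$score <- numeric(0)
      det$spurious <- logical(0)
    }
    spur_flag <- if (n_images > 0) rbinom(n_images, 1, spurious_rate) == 1 else logical(0)
    ns <- sum(spur_flag)
    if (ns > 0) {
      sp <- data.frame(image_id = which(spur_flag),
                       w = runif(ns, 40, 160), h = runif(ns, 40, 160),
                       stringsAsFactors = FALSE)
      sp$x <- runif(ns, 0, image_width - sp$w)
      sp$y <- runif(ns, 0, image_height - sp$h)
      sp$class <- sample(classes, ns, replace = TRUE)
      sp$score <- runif(ns, 0.05, 0.4)
      sp$spurious <- TRUE
      det <- rbind(det, sp[, names(det)])
    }
    structure(list(images = seq_len(n_images),
                   truth_boxes = truth,
                   detections = det[order(det$image_id), , drop = FALSE]),
              class = "detection_set")
  })
}

# ---- plain-text I/O -------------------------------------------------------

#' Write/read a recording as CSV (time_s, ax, ay, az)
#' @param recording A `labeled_recording`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(recording, path) {
  t <- (seq_len(nrow(recording$signal)) - 1) / recording$sample_rate_hz
  df <- data.frame(time_s = t, recording$signal)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @param sample_rate_hz Sampling rate to assume when reading.
#' @export
read_recording_csv <- function(path, sample_rate_hz = 128) {
  df <- read.csv(path)
  sig <- as.matrix(df[, c("ax", "ay", "az")])
  structure(list(signal = sig, sample_rate_hz = sample_rate_hz, window_s = 15,
                 segment_labels = integer(0),
                 truth_episodes = data.frame(start_s = numeric(0),
                                             end_s = numeric(0))),
            class = "labeled_recording")
}

#' Write labels and ground-truth episodes as JSON
#' @param recording A `labeled_recording`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_labels_json <- function(recording, path) {
  jsonlite::write_json(list(window_s = recording$window_s,
                            segment_labels = recording$segment_labels,
                            truth_episodes = recording$truth_episodes),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a detection fixture as JSON
#' @param detection_set A `detection_set`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_detections_json <- function(detection_set, path) {
  jsonlite::write_json(list(images = detection_set$images,
                            truth_boxes = detection_set$truth_boxes,
                            detections = detection_set$detections),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
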