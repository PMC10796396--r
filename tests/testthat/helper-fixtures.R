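# Shared synthetic fixtures. The trained CNN and the fusion benchmark are
# expensive, so they are built once per test session and cached.

.fixtures <- new.env(parent = emptyenv())

# dense-episode recording used to train the sensor CNN: strongly separable
# chewing (amplitude 0.2 g against 0.02 g noise), roughly class-balanced
cnn_train_sim_config <- function(seed) {
  simulation_config(duration_s = 1800, n_episodes = 8,
                    episode_duration_range_s = c(60, 120),
                    inter_episode_gap_range_s = c(45, 90),
                    chew_amplitude = 0.2, noise_amplitude = 0.02,
                    seed = seed)
}

# free-living-style benchmark recording: episodes separated by > 15 min
benchmark_sim_config <- function(seed) {
  simulation_config(duration_s = 3800, n_episodes = 3,
                    episode_duration_range_s = c(90, 200),
                    inter_episode_gap_range_s = c(920, 1000),
                    chew_amplitude = 0.2, noise_amplitude = 0.02,
                    seed = seed)
}

# Train the default 8-epoch / batch-32 CNN on 200 synthetic scalograms and
# hold out the remaining segments for accuracy measurement.
get_sensor_fixture <- function() {
  if (!is.null(.fixtures$sensor)) return(.fixtures$sensor)
  sc1 <- scalogram_batch(simulate_recording(cnn_train_sim_config(501)))
  sc2 <- scalogram_batch(simulate_recording(cnn_train_sim_config(502)))
  images <- c(sc1$images, sc2$images)
  labels <- c(sc1$labels, sc2$labels)
  n <- length(images)
  split <- holdout_split(n, c(200 / n, 0, 1 - 200 / n), seed = 503)
  model <- train_sensor_model(images[split$train], labels[split$train],
                              model_config(seed = 504))
  ss_test <- predict_intake(model, images[split$test])
  .fixtures$sensor <- list(
    model = model,
    n_train = length(split$train),
    test_labels = labels[split$test],
    test_scores = ss_test,
    holdout_accuracy = mean(as.integer(ss_test > 0.5) == labels[split$test]))
  .fixtures$sensor
}

# Score-fusion benchmark: image streams with 20% false-positive rate, sensor
# stream from the trained CNN; five seeded replicates of the evaluation day.
get_benchmark_fixture <- function() {
  if (!is.null(.fixtures$benchmark)) return(.fixtures$benchmark)
  fx <- get_sensor_fixture()
  score_cfg <- function(seed) score_stream_config(fp_rate = 0.2, seed = seed)
  make_series <- function(rec, score_seed) {
    sc <- scalogram_batch(rec)
    ss <- predict_intake(fx$model, sc$images)
    sim <- simulate_score_streams(rec$segment_labels, score_cfg(score_seed))
    confidence_series(Sf = sim$Sf, Sb = sim$Sb, Ss = ss,
                      t_start_s = sim$t_start_s, label = sim$label,
                      missing = sim$missing)
  }
  rec_tr <- simulate_recording(benchmark_sim_config(601))
  train_series <- make_series(rec_tr, 602)
  replicates <- lapply(1:5, function(r) {
    rec_ev <- simulate_recording(benchmark_sim_config(610 + r))
    test_series <- make_series(rec_ev, 620 + r)
    bench <- run_fusion_benchmark(train_series, test_series,
                                  rec_ev$truth_episodes, n = 1,
                                  params = fusion_params(seed = 630 + r))
    bench
  })
  .fixtures$benchmark <- list(train_series = train_series,
                              replicates = replicates)
  .fixtures$benchmark
}
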