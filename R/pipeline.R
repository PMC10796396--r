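#' Pipeline configuration
#'
#' Nested configuration for the end-to-end demo pipeline: simulate a training
#' and an evaluation recording, build scalograms, train the sensor CNN,
#' simulate detector score streams, fuse, aggregate episodes and evaluate.
#' Unknown section names are rejected. All stage seeds are derived from the
#' global `seed`.
#'
#' @param seed Global integer seed.
#' @param out_dir Optional output directory; when given, a resolved-config
#'   snapshot and the run report are written there as JSON.
#' @param simulate_train,simulate_eval Named lists of [simulation_config()]
#'   overrides for the training and evaluation recordings.
#' @param scores Named list of [score_stream_config()] overrides for the
#'   image-detector streams.
#' @param sensor Named list of [model_config()] overrides.
#' @param fusion Named list: `n` (integer lag, or `"grid"` for a 0..4 grid
#'   search on a temporal validation split of the training series),
#'   plus [fusion_params()] overrides.
#' @param episodes Named list: `gap_min`, `min_overlap_s`.
#' @param log_level `"info"` or `"quiet"`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            out_dir = NULL,
                            simulate_train = list(),
                            simulate_eval = list(),
                            scores = list(),
                            sensor = list(),
                            fusion = list(),
                            episodes = list(),
                            log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  # `n_lags` is the YAML-safe spelling (YAML 1.1 reads a bare `n` key as a
  # boolean); plain `n` is accepted from R code
  known_fusion <- c("n", "n_lags", "n_trees", "max_splits", "fp_cost", "fn_cost")
  bad <- setdiff(names(fusion), known_fusion)
  if (length(bad)) stop_config("unknown fusion keys: ", paste(bad, collapse = ", "))
  known_epi <- c("gap_min", "min_overlap_s")
  bad <- setdiff(names(episodes), known_epi)
  if (length(bad)) stop_config("unknown episodes keys: ", paste(bad, collapse = ", "))
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 simulate_train = simulate_train,
                 simulate_eval = simulate_eval,
                 scores = scores, sensor = sensor, fusion = fusion,
                 episodes = episodes, log_level = log_level),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML (or JSON)
#' @param path Path to a YAML/JSON file of [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- setdiff(names(formals(pipeline_config)), "")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop_config("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, cfg)
}

build_series <- function(recording, ss, score_cfg, window_s = 15) {
  sim <- simulate_score_streams(recording$segment_labels, score_cfg, window_s)
  confidence_series(Sf = sim$Sf, Sb = sim$Sb, Ss = ss,
                    t_start_s = sim$t_start_s, label = sim$label,
                    missing = sim$missing)
}

#' Single-modality and fused segment/episode benchmark
#'
#' Trains three forests with identical machinery on a training series — one
#' on the image streams (`Sf`, `Sb`) alone, one on the sensor stream (`Ss`)
#' alone and one on all three — then evaluates each on a test series at both
#' segment and episode level. This realizes the package's central comparison:
#' fusion versus either single modality.
#'
#' @param train_series,test_series [confidence_series()] objects with labels.
#' @param truth_episodes Ground-truth episodes of the test recording.
#' @param n Temporal lag count used for all three models.
#' @param params A [fusion_params()].
#' @param gap_min Episode merge threshold, minutes.
#' @param min_overlap_s Episode matching overlap, seconds.
#' @param window_s Segment length, seconds.
#' @return List with per-modality `segment` metric vectors, `episode` metric
#'   vectors, `confusion` counts and per-modality predicted labels.
#' @export
run_fusion_benchmark <- function(train_series, test_series, truth_episodes,
                                 n = 1, params = fusion_params(),
                                 gap_min = 15, min_overlap_s = 1,
                                 window_s = 15) {
  cols_for <- function(modality, nm) {
    switch(modality,
           image = grep("^(Sf|Sb)_", nm, value = TRUE),
           sensor = grep("^Ss_", nm, value = TRUE),
           fused = nm)
  }
  vtr <- build_predictor_vectors(train_series, n)
  vte <- build_predictor_vectors(test_series, n)
  # ground-truth intervals are subject to the same <gap_min merge rule, so
  # annotation bouts separated by short breaks count as one episode
  truth_episodes <- merge_events_to_episodes(truth_episodes, gap_min)
  out <- list()
  for (modality in c("image", "sensor", "fused")) {
    keep <- cols_for(modality, colnames(vtr))
    model <- train_fusion(vtr[, keep, drop = FALSE], train_series$label, params)
    pred <- predict_fused(model, vte[, keep, drop = FALSE])
    cc <- confusion_counts(pred$label, test_series$label)
    events <- segments_to_events(pred$label, test_series$t_start_s, window_s)
    epis <- merge_events_to_episodes(events, gap_min)
    conf <- match_episodes(epis, truth_episodes, min_overlap_s)
    out[[modality]] <- list(
      segment = suppressWarnings(
        segment_metrics(cc[["TP"]], cc[["FP"]], cc[["TN"]], cc[["FN"]])),
      confusion = cc,
      episode = episode_metrics(conf),
      episode_confusion = conf,
      labels = pred$label)
  }
  out
}

#' Run the end-to-end demo pipeline
#'
#' Executes simulate, scalogram, sensor-CNN training, sensor prediction,
#' score-stream simulation, fusion (with optional lag grid search), episode
#' aggregation and evaluation in dependency order, entirely driven by the
#' configuration and its seed.
#'
#' @param config A [pipeline_config()].
#' @return A run report (list): per-stage record counts, chosen lag `n`,
#'   segment- and episode-level metrics for the fused and single-modality
#'   classifiers, episode confusion counts and, when both discordant counts
#'   are not both zero, a McNemar comparison of the image-only and fused
#'   segment decisions.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) {
    if (config$log_level == "info") message("[intakefuse] ", sprintf(...))
  }
  seed <- config$seed

  say("simulating recordings")
  cfg_tr <- do.call(simulation_config,
                    utils::modifyList(list(seed = seed), config$simulate_train))
  cfg_ev <- do.call(simulation_config,
                    utils::modifyList(list(seed = seed + 1000L),
                                      config$simulate_eval))
  rec_tr <- simulate_recording(cfg_tr)
  rec_ev <- simulate_recording(cfg_ev)

  say("computing scalograms")
  sc_tr <- scalogram_batch(rec_tr)
  sc_ev <- scalogram_batch(rec_ev)

  say("training sensor CNN (%d segments)", length(sc_tr$images))
  mc <- do.call(model_config,
                utils::modifyList(list(seed = seed + 2000L), config$sensor))
  sensor <- train_sensor_model(sc_tr$images, sc_tr$labels, mc)
  ss_tr <- predict_intake(sensor, sc_tr$images)
  ss_ev <- predict_intake(sensor, sc_ev$images)

  say("simulating detector score streams")
  sc_cfg_tr <- do.call(score_stream_config,
                       utils::modifyList(list(seed = seed + 3000L),
                                         config$scores))
  sc_cfg_ev <- do.call(score_stream_config,
                       utils::modifyList(list(seed = seed + 4000L),
                                         config$scores))
  ser_tr <- build_series(rec_tr, ss_tr, sc_cfg_tr, rec_tr$window_s)
  ser_ev <- build_series(rec_ev, ss_ev, sc_cfg_ev, rec_ev$window_s)

  fus_args <- config$fusion
  n_req <- fus_args$n %||% fus_args$n_lags %||% 1L
  fus_params <- do.call(fusion_params, c(
    fus_args[setdiff(names(fus_args), c("n", "n_lags"))],
    list(seed = seed + 5000L)))
  grid <- NULL
  if (identical(n_req, "grid")) {
    say("grid search over temporal lag n = 0..4")
    cut <- floor(0.8 * nrow(ser_tr))
    grid <- grid_search_n(ser_tr[seq_len(cut), ],
                          ser_tr[(cut + 1):nrow(ser_tr), ],
                          n_range = 0:4, params = fus_params)
    n_req <- grid$best_n
  }
  n_req <- as.integer(n_req)

  say("fusing with n = %d and evaluating", n_req)
  epi_cfg <- utils::modifyList(list(gap_min = 15, min_overlap_s = 1),
                               config$episodes)
  bench <- run_fusion_benchmark(ser_tr, ser_ev, rec_ev$truth_episodes,
                                n = n_req, params = fus_params,
                                gap_min = epi_cfg$gap_min,
                                min_overlap_s = epi_cfg$min_overlap_s,
                                window_s = rec_ev$window_s)

  img_err <- bench$image$labels != ser_ev$label
  fus_err <- bench$fused$labels != ser_ev$label
  e01 <- sum(img_err & !fus_err)
  e10 <- sum(!img_err & fus_err)
  mcn <- if (e01 + e10 > 0) mcnemar_test(e01, e10) else NULL

  report <- list(
    seed = seed,
    counts = list(train_segments = length(sc_tr$images),
                  eval_segments = length(sc_ev$images),
                  train_intake_segments = sum(sc_tr$labels),
                  eval_intake_segments = sum(sc_ev$labels),
                  truth_episodes = nrow(rec_ev$truth_episodes)),
    chosen_n = n_req,
    grid_metrics = if (!is.null(grid)) grid$metrics else NULL,
    sensor_training_loss = sensor$training_log,
    segment_metrics = lapply(bench, function(b) as.list(b$segment)),
    episode_metrics = lapply(bench, function(b) as.list(b$episode)),
    episode_confusion = lapply(bench, function(b)
      list(TP = b$episode_confusion$TP, FP = b$episode_confusion$FP,
           FN = b$episode_confusion$FN)),
    mcnemar_image_vs_fused = if (!is.null(mcn)) {
      list(e01 = mcn$e01, e10 = mcn$e10, chi_square = mcn$chi_square,
           reject = mcn$reject)
    } else NULL)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    snap <- config
    snap$out_dir <- NULL
    jsonlite::write_json(unclass(snap),
                         file.path(config$out_dir, "config_resolved.json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
    say("report written to %s", file.path(config$out_dir, "report.json"))
  }
  report
}
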