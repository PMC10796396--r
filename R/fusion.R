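#' Aligned per-segment confidence score streams
#'
#' Holds the three per-segment confidence streams: food object score `Sf`,
#' beverage object score `Sb` (each the maximum detector confidence in the
#' segment's image, 0 when nothing is detected or the image is missing) and
#' the sensor intake probability `Ss`.
#'
#' @param Sf,Sb,Ss Numeric vectors in \[0, 1\], equal lengths.
#' @param t_start_s Segment start times, seconds (monotone increasing).
#' @param label Optional 0/1 intake labels.
#' @param missing Optional logical missing-image flags.
#' @return A data frame of class `confidence_series` with columns
#'   `segment_index`, `t_start_s`, `Sf`, `Sb`, `Ss`, `label`, `missing`.
#' @export
confidence_series <- function(Sf, Sb, Ss, t_start_s = NULL, label = NULL,
                              missing = NULL) {
  n <- length(Sf)
  if (length(Sb) != n || length(Ss) != n) {
    stop_data("Sf, Sb, Ss must have equal lengths")
  }
  assert_prob(Sf, "Sf"); assert_prob(Sb, "Sb"); assert_prob(Ss, "Ss")
  t_start_s <- t_start_s %||% ((seq_len(n) - 1) * 15)
  if (is.unsorted(t_start_s, strictly = TRUE)) {
    stop_data("t_start_s must be strictly increasing")
  }
  out <- data.frame(segment_index = seq_len(n),
                    t_start_s = t_start_s,
                    Sf = Sf, Sb = Sb, Ss = Ss,
                    label = if (is.null(label)) NA_integer_ else as.integer(label),
                    missing = if (is.null(missing)) FALSE else as.logical(missing))
  class(out) <- c("confidence_series", class(out))
  out
}

#' Per-segment image scores from raw detections
#'
#' For each segment's image, `Sf` is the highest confidence score over food
#' detections (0 if none) and `Sb` the highest over beverage detections;
#' segments whose image is missing get `(0, 0)` and a flag.
#'
#' @param detections Data frame with columns `image_id` (1-based segment
#'   index), `class` (`"food"`/`"beverage"`) and `score` in \[0, 1\].
#' @param n_segments Total number of segments.
#' @param missing_images Optional integer vector of segment indices whose
#'   image is missing.
#' @return Data frame with `segment_index`, `Sf`, `Sb`, `missing`.
#' @export
extract_image_scores <- function(detections, n_segments,
                                 missing_images = integer(0)) {
  Sf <- numeric(n_segments)
  Sb <- numeric(n_segments)
  if (nrow(detections) > 0) {
    if (any(detections$score < 0 | detections$score > 1)) {
      stop_data("detection scores must lie in [0, 1]")
    }
    if (!all(detections$class %in% c("food", "beverage"))) {
      stop_data("detection class must be 'food' or 'beverage'")
    }
    food <- detections[detections$class == "food", ]
    bev <- detections[detections$class == "beverage", ]
    if (nrow(food) > 0) {
      mx <- tapply(food$score, food$image_id, max)
      Sf[as.integer(names(mx))] <- mx
    }
    if (nrow(bev) > 0) {
      mx <- tapply(bev$score, bev$image_id, max)
      Sb[as.integer(names(mx))] <- mx
    }
  }
  missing <- seq_len(n_segments) %in% missing_images
  Sf[missing] <- 0
  Sb[missing] <- 0
  data.frame(segment_index = seq_len(n_segments), Sf = Sf, Sb = Sb,
             missing = missing)
}

#' Temporal predictor vectors
#'
#' For each segment t builds the lagged predictor vector
#' `[Sf(t) ... Sf(t-n), Sb(t) ... Sb(t-n), Ss(t) ... Ss(t-n)]` of length
#' `3 * (n + 1)`. Lags reaching before the start of the series are
#' zero-padded (zero meaning "no evidence", consistent with the no-detection
#' convention).
#'
#' @param series A [confidence_series()].
#' @param n Number of temporal lags (`n = 0` uses only the current segment).
#' @return Numeric matrix, one row per segment, `3 * (n + 1)` columns named
#'   `Sf_lag0 ... Ss_lagn`.
#' @export
build_predictor_vectors <- function(series, n = 0) {
  if (n < 0) stop_config("lag count n must be >= 0")
  if (nrow(series) < 1) stop_data("series must be non-empty")
  n <- as.integer(n)
  lag_mat <- function(v) {
    m <- matrix(0, length(v), n + 1L)
    for (l in 0:n) {
      m[, l + 1L] <- c(rep(0, min(l, length(v))),
                       head(v, max(0L, length(v) - l)))
    }
    m
  }
  out <- cbind(lag_mat(series$Sf), lag_mat(series$Sb), lag_mat(series$Ss))
  colnames(out) <- paste0(rep(c("Sf", "Sb", "Ss"), each = n + 1L),
                          "_lag", rep(0:n, times = 3))
  out
}

#' Fusion random-forest parameters
#'
#' The fusion classifier is a random forest with 30 trees, at most 1000
#' decision splits (branch nodes) per tree and misclassification cost matrix
#' `[0 1; 2 0]` (misclassifying an intake segment costs twice as much as
#' misclassifying a non-intake segment). The cost matrix is realized as the
#' minimum-expected-cost decision threshold on the forest's intake vote
#' fraction: predict intake when `score > fp_cost / (fp_cost + fn_cost)`
#' (1/3 at defaults).
#'
#' @param n_trees Number of trees.
#' @param max_splits Maximum branch nodes per tree.
#' @param fp_cost Cost of misclassifying a non-intake segment as intake.
#' @param fn_cost Cost of misclassifying an intake segment as non-intake.
#' @param seed Integer seed.
#' @return An object of class `fusion_params`.
#' @export
fusion_params <- function(n_trees = 30, max_splits = 1000,
                          fp_cost = 1, fn_cost = 2, seed = 1L) {
  if (n_trees < 1 || max_splits < 1) stop_config("invalid forest size")
  if (fp_cost <= 0 || fn_cost <= 0) stop_config("costs must be positive")
  structure(list(n_trees = as.integer(n_trees),
                 max_splits = as.integer(max_splits),
                 fp_cost = fp_cost, fn_cost = fn_cost,
                 seed = as.integer(seed)),
            class = "fusion_params")
}

#' Train the cost-sensitive fusion random forest
#'
#' @param vectors Predictor matrix from [build_predictor_vectors()] (or any
#'   numeric matrix of per-segment predictors).
#' @param labels 0/1 intake labels, both classes present.
#' @param params A [fusion_params()].
#' @return An object of class `fusion_model` with the fitted forest, the
#'   predictor column names, the decision threshold and the lag count implied
#'   by the columns.
#' @export
train_fusion <- function(vectors, labels, params = fusion_params()) {
  stopifnot(inherits(params, "fusion_params"))
  y <- factor(as.integer(as.logical(labels)), levels = c(0, 1),
              labels = c("non_intake", "intake"))
  if (length(unique(y)) < 2L) {
    stop_data("fusion training requires both classes")
  }
  if (nrow(vectors) != length(y)) stop_data("vectors/labels length mismatch")
  x <- as.data.frame(vectors)
  forest <- with_seed(params$seed, {
    randomForest::randomForest(
      x = x, y = y,
      ntree = params$n_trees,
      # branch nodes = terminal nodes - 1; a tree can never have more leaves
      # than training rows, so cap there to keep the constraint well-formed
      maxnodes = min(params$max_splits + 1L, length(y))
    )
  })
  structure(list(forest = forest,
                 feature_names = colnames(x),
                 threshold = params$fp_cost / (params$fp_cost + params$fn_cost),
                 params = params,
                 n_lags = length(grep("^Sf_lag", colnames(x))) - 1L),
            class = "fusion_model")
}

#' Fused per-segment prediction
#'
#' The fused score is the forest's intake vote fraction; the label applies the
#' cost-sensitive threshold (intake when `score > threshold`).
#'
#' @param model A `fusion_model`.
#' @param vectors Predictor matrix with the same columns the model was
#'   trained on.
#' @return Data frame with `label` (0/1) and `score` in \[0, 1\].
#' @export
predict_fused <- function(model, vectors) {
  stopifnot(inherits(model, "fusion_model"))
  if (ncol(vectors) != length(model$feature_names)) {
    stop_data("predictor vector length ", ncol(vectors),
              " does not match the model's ", length(model$feature_names))
  }
  x <- as.data.frame(vectors)
  colnames(x) <- model$feature_names
  score <- predict(model$forest, x, type = "prob")[, "intake"]
  data.frame(label = as.integer(score > model$threshold),
             score = as.numeric(score))
}

#' F1 score of 0/1 predictions (helper for grid search)
#' @keywords internal
#' @noRd
f1_binary <- function(pred, truth) {
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  if (2 * tp + fn + fp == 0) return(NaN)
  2 * tp / (2 * tp + fn + fp)
}

#' Grid search over the temporal lag n
#'
#' Trains one fusion model per candidate `n` on the training series and
#' evaluates it on the validation series; returns the `n` maximizing the
#' metric (ties broken toward the smallest, i.e. cheapest, model).
#'
#' @param train_series,val_series [confidence_series()] objects with labels.
#' @param n_range Candidate lag counts.
#' @param params A [fusion_params()].
#' @param metric `"f1"` (default) or `"accuracy"`.
#' @return List with `best_n`, `metrics` (data frame n/metric) and `models`.
#' @export
grid_search_n <- function(train_series, val_series, n_range = 0:4,
                          params = fusion_params(), metric = c("f1", "accuracy")) {
  metric <- match.arg(metric)
  if (length(n_range) == 0) stop_config("n_range must be non-empty")
  if (any(n_range < 0)) stop_config("lag counts must be >= 0")
  scores <- numeric(length(n_range))
  models <- vector("list", length(n_range))
  for (i in seq_along(n_range)) {
    n <- n_range[i]
    m <- train_fusion(build_predictor_vectors(train_series, n),
                      train_series$label, params)
    pred <- predict_fused(m, build_predictor_vectors(val_series, n))
    scores[i] <- if (metric == "f1") {
      f1_binary(pred$label, val_series$label)
    } else {
      mean(pred$label == val_series$label)
    }
    models[[i]] <- m
  }
  best <- which(scores >= max(scores, na.rm = TRUE) - 1e-12)[1]
  list(best_n = n_range[best],
       metrics = data.frame(n = n_range, metric = scores),
       models = models)
}

#' Write/read aligned score streams as CSV
#'
#' Columns: `segment_index`, `t_start_s`, `Sf`, `Sb`, `Ss`, `label`,
#' `missing`.
#'
#' @param series A [confidence_series()].
#' @param path CSV path.
#' @return `path` (write) or a `confidence_series` (read).
#' @export
write_score_csv <- function(series, path) {
  write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_score_csv
#' @export
read_score_csv <- function(path) {
  df <- read.csv(path)
  confidence_series(Sf = df$Sf, Sb = df$Sb, Ss = df$Ss,
                    t_start_s = df$t_start_s,
                    label = if ("label" %in% names(df)) df$label else NULL,
                    missing = if ("missing" %in% names(df)) df$missing else NULL)
}
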