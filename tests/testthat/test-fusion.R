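test_that("image score extraction takes the per-class maximum per image", {
  det <- data.frame(image_id = c(1, 1, 2),
                    class = c("food", "food", "beverage"),
                    score = c(0.3, 0.9, 0.7))
  s <- extract_image_scores(det, n_segments = 3)
  expect_equal(s$Sf, c(0.9, 0, 0))
  expect_equal(s$Sb, c(0, 0.7, 0))
  # no detections at all
  s0 <- extract_image_scores(det[0, ], n_segments = 2)
  expect_equal(s0$Sf, c(0, 0))
  # missing image overrides detections
  sm <- extract_image_scores(det, n_segments = 3, missing_images = 1L)
  expect_equal(sm$Sf[1], 0)
  expect_true(sm$missing[1])
  det$score[1] <- 1.2
  expect_error(extract_image_scores(det, 3), class = "intakefuse_data_error")
})

test_that("predictor vectors have length 3(n+1) with zero-padded lags", {
  ser <- confidence_series(Sf = c(0.1, 0.2, 0.3), Sb = c(0.4, 0.5, 0.6),
                           Ss = c(0.7, 0.8, 0.9))
  v0 <- build_predictor_vectors(ser, 0)
  expect_equal(dim(v0), c(3, 3))
  expect_equal(unname(v0[2, ]), c(0.2, 0.5, 0.8))
  v2 <- build_predictor_vectors(ser, 2)
  expect_equal(ncol(v2), 9)
  for (n in 0:4) {
    expect_equal(ncol(build_predictor_vectors(ser, n)), 3 * (n + 1))
  }
  v1 <- build_predictor_vectors(ser, 1)
  expect_equal(unname(v1[1, ]), c(0.1, 0, 0.4, 0, 0.7, 0))
  expect_equal(unname(v1[2, ]), c(0.2, 0.1, 0.5, 0.4, 0.8, 0.7))
  expect_error(build_predictor_vectors(ser, -1),
               class = "intakefuse_config_error")
})

test_that("the fusion forest fits separable data and is seed-reproducible", {
  set.seed(10)
  lab <- rep(c(0L, 1L), 60)
  ser <- confidence_series(Sf = runif(120), Sb = runif(120),
                           Ss = ifelse(lab == 1L, runif(120, 0.6, 1),
                                       runif(120, 0, 0.4)))
  v <- build_predictor_vectors(ser, 0)
  m <- train_fusion(v, lab, fusion_params(seed = 5))
  pred <- predict_fused(m, v)
  expect_equal(mean(pred$label == lab), 1.0)
  expect_true(all(pred$score >= 0 & pred$score <= 1))
  m2 <- train_fusion(v, lab, fusion_params(seed = 5))
  expect_identical(predict_fused(m2, v), pred)
  expect_error(train_fusion(v, rep(1L, 120), fusion_params()),
               class = "intakefuse_data_error")
  expect_error(predict_fused(m, v[, 1:2]), class = "intakefuse_data_error")
})

test_that("all-zero vectors predict the non-intake convention", {
  lab <- c(rep(0L, 30), rep(1L, 30))
  v <- rbind(matrix(0, 30, 3), matrix(runif(90, 0.5, 1), 30, 3))
  colnames(v) <- c("Sf_lag0", "Sb_lag0", "Ss_lag0")
  m <- train_fusion(v, lab, fusion_params(seed = 2))
  p <- predict_fused(m, matrix(0, 1, 3))
  expect_equal(p$label, 0L)
})

test_that("raising the intake misclassification cost never lowers intake recall", {
  set.seed(30)
  n <- 200
  lab <- rbinom(n, 1, 0.3)
  ser <- confidence_series(Sf = runif(n), Sb = runif(n),
                           Ss = pmin(1, pmax(0, 0.5 * lab + runif(n, 0, 0.5))))
  v <- build_predictor_vectors(ser, 0)
  recall_at <- function(fn_cost) {
    m <- train_fusion(v, lab, fusion_params(fn_cost = fn_cost, seed = 4))
    p <- predict_fused(m, v)
    sum(p$label == 1 & lab == 1) / sum(lab == 1)
  }
  r1 <- recall_at(1)
  r2 <- recall_at(2)
  r4 <- recall_at(4)
  expect_true(r2 >= r1)
  expect_true(r4 >= r2)
})

test_that("grid search evaluates each candidate lag and breaks ties downward", {
  set.seed(11)
  lab <- rep(c(0L, 1L), 40)
  mk <- function() {
    confidence_series(Sf = runif(80), Sb = runif(80),
                      Ss = ifelse(lab == 1L, runif(80, 0.7, 1),
                                  runif(80, 0, 0.3)),
                      label = lab)
  }
  gs <- grid_search_n(mk(), mk(), n_range = 0:4, params = fusion_params(seed = 6))
  expect_equal(nrow(gs$metrics), 5)
  expect_equal(gs$metrics$n, 0:4)
  expect_true(all(gs$metrics$metric > 0.9))
  # ties (and near-ties) break toward the smallest n
  expect_equal(gs$best_n,
               gs$metrics$n[which(gs$metrics$metric >=
                                    max(gs$metrics$metric) - 1e-12)[1]])
  expect_error(grid_search_n(mk(), mk(), n_range = integer(0)),
               class = "intakefuse_config_error")
})

test_that("temporal lags improve F1 on noisy, temporally clustered eating", {
  mk <- function(seed) {
    lab <- unlist(lapply(1:8, function(i) c(rep(0L, 25), rep(1L, 10))))
    simulate_score_streams(lab, score_stream_config(
      p_capture = 0.6, fp_rate = 0.2,
      score_dist_pos = c(4, 2), score_dist_neg = c(2, 4), seed = seed))
  }
  gs <- grid_search_n(mk(98), mk(99), n_range = 0:1,
                      params = fusion_params(seed = 199))
  expect_gte(gs$metrics$metric[2], gs$metrics$metric[1])
})

test_that("score CSV roundtrips preserve the series", {
  lab <- rep(c(0L, 1L), 10)
  ser <- simulate_score_streams(lab, score_stream_config(seed = 12))
  path <- tempfile(fileext = ".csv")
  write_score_csv(ser, path)
  back <- read_score_csv(path)
  expect_equal(back$Sf, ser$Sf)
  expect_equal(back$Ss, ser$Ss)
  expect_equal(back$label, ser$label)
})
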