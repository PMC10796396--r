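test_that("segment metrics compute the four standard formulas", {
  m <- segment_metrics(TP = 8, FP = 2, TN = 88, FN = 2)
  expect_equal(unname(m), c(0.8, 0.8, 0.96, 0.8))
  perfect <- segment_metrics(TP = 10, FP = 0, TN = 5, FN = 0)
  expect_true(all(perfect == 1))
  expect_equal(unname(segment_metrics(TP = 0, FP = 3, TN = 5, FN = 4)["sensitivity"]), 0)
  expect_error(segment_metrics(-1, 0, 0, 1), class = "intakefuse_data_error")
  expect_warning(m0 <- segment_metrics(TP = 0, FP = 0, TN = 5, FN = 2),
                 "precision")
  expect_true(is.nan(m0[["precision"]]))
  all_und <- suppressWarnings(segment_metrics(TP = 0, FP = 0, TN = 5, FN = 0))
  expect_true(is.nan(all_und[["sensitivity"]]) && is.nan(all_und[["f1"]]))
})

test_that("F1 is the harmonic mean of precision and sensitivity", {
  set.seed(16)
  for (i in 1:200) {
    counts <- sample(0:50, 4, replace = TRUE)
    if (counts[1] == 0) counts[1] <- 1  # keep all metrics defined
    m <- suppressWarnings(segment_metrics(counts[1], counts[2],
                                          counts[3], counts[4]))
    h <- 2 / (1 / m[["precision"]] + 1 / m[["sensitivity"]])
    expect_equal(m[["f1"]], h, tolerance = 1e-12)
  }
})

test_that("McNemar's statistic uses the continuity correction", {
  r <- mcnemar_test(70, 6)
  expect_equal(round(r$chi_square, 2), 52.22)
  expect_equal(round(r$critical_value, 3), 6.635)
  expect_true(r$reject)
  sym <- mcnemar_test(5, 5)
  expect_equal(sym$chi_square, 0.1)
  expect_false(sym$reject)
  # symmetry in the discordant counts
  expect_equal(mcnemar_test(17, 40)$chi_square, mcnemar_test(40, 17)$chi_square)
  expect_error(mcnemar_test(0, 0), class = "intakefuse_data_error")
})

test_that("IoU handles identity, disjunction and partial overlap", {
  expect_equal(iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1.0)
  expect_equal(iou(c(0, 0, 2, 2), c(10, 10, 2, 2)), 0.0)
  # unit-cell count: intersection 1, union 7
  expect_equal(iou(c(0, 0, 2, 2), c(1, 1, 2, 2)), 1 / 7)
  expect_error(iou(c(0, 0, 0, 2), c(0, 0, 2, 2)),
               class = "intakefuse_data_error")
})

test_that("average precision covers the trivial endpoint cases", {
  truth <- data.frame(image_id = 1, x = 0, y = 0, w = 10, h = 10)
  exact <- data.frame(image_id = 1, x = 0, y = 0, w = 10, h = 10, score = 1.0)
  for (thr in c(0.5, 0.75, 0.95)) {
    expect_equal(average_precision(exact, truth, thr), 1.0)
  }
  # a detection with IoU ~0.43 < 0.5 never matches
  off <- data.frame(image_id = 1, x = 4, y = 0, w = 10, h = 10, score = 0.9)
  expect_equal(average_precision(off, truth, 0.5), 0)
  expect_warning(ap <- average_precision(exact, truth[0, ], 0.5), "undefined")
  expect_true(is.na(ap))
})

test_that("AP equals exhaustive enumeration on a hand-built instance", {
  truths <- data.frame(image_id = c(1, 1), x = c(0, 100), y = c(0, 0),
                       w = c(10, 10), h = c(10, 10))
  det <- data.frame(image_id = c(1, 1),
                    x = c(0, 300), y = c(0, 0), w = c(10, 10), h = c(10, 10),
                    score = c(0.9, 0.6))
  got <- average_precision(det, truths, 0.5)
  want <- oracle_average_precision(det, truths, 0.5)
  expect_equal(got, want)
  # thresholds <= 0.6 keep both detections: P = 1/2, R = 1/2;
  # thresholds 0.7..0.9 keep only the correct one: P = 1, R = 1/2.
  # AP = area under [(0, 1), (0.5, 1)] after augmentation = 0.5
  expect_equal(got, 0.5)
})

test_that("AP matches exhaustive enumeration on random small fixtures", {
  for (seed in 1:5) {
    ds <- simulate_detections(6, 2, perturbation = 4, spurious_rate = 0.4,
                              seed = seed)
    for (cl in c("food", "beverage")) {
      d <- ds$detections[ds$detections$class == cl, , drop = FALSE]
      t <- ds$truth_boxes[ds$truth_boxes$class == cl, , drop = FALSE]
      if (nrow(t) == 0) next
      for (thr in c(0.5, 0.75)) {
        expect_equal(average_precision(d, t, thr),
                     oracle_average_precision(d, t, thr),
                     info = sprintf("seed %d class %s thr %.2f", seed, cl, thr))
      }
    }
  }
})

test_that("mAP averages 10 IoU thresholds and is 100 for perfect detections", {
  cfg <- detection_eval_config()
  expect_length(cfg$iou_thresholds, 10)
  expect_length(cfg$score_thresholds, 11)
  ds <- simulate_detections(15, 2, perturbation = 0, spurious_rate = 0,
                            seed = 3)
  mp <- mean_average_precision(ds$detections, ds$truth_boxes, cfg)
  expect_equal(mp$overall, 100)
  expect_true(all(mp$per_class == 100))
  expect_true(all(mp$ap_matrix >= 0 & mp$ap_matrix <= 1))
  # detections far from every truth box score zero
  far <- ds$detections
  far$x <- far$x + 500
  mp0 <- mean_average_precision(far, ds$truth_boxes, cfg)
  expect_equal(mp0$overall, 0)
})

test_that("LOSO folds partition records by subject", {
  subjects <- rep(paste0("s", 1:30), each = 4)
  folds <- loso_split(subjects)
  expect_length(folds, 30)
  test_idx <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_equal(test_idx, seq_along(subjects))
  for (f in folds) {
    expect_equal(intersect(subjects[f$train], subjects[f$test]), character(0))
    expect_length(f$test, 4)
  }
  expect_error(loso_split(rep("a", 5)), class = "intakefuse_data_error")
})

test_that("holdout split is 80/10/10, seed-stable and covers the data", {
  s <- holdout_split(100, seed = 4)
  expect_equal(lengths(s), c(train = 80L, val = 10L, test = 10L))
  expect_equal(sort(unname(unlist(s))), 1:100)
  expect_identical(s, holdout_split(100, seed = 4))
  s2 <- holdout_split(101, seed = 4)
  expect_equal(sum(lengths(s2)), 101)
  expect_true(all(abs(lengths(s2) - 101 * c(0.8, 0.1, 0.1)) <= 1))
  expect_error(holdout_split(10, fractions = c(0.5, 0.3, 0.1)),
               class = "intakefuse_config_error")
})
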