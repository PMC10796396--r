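#' Segment-level classification metrics
#'
#' Sensitivity `TP/(TP+FN)`, precision `TP/(TP+FP)`, accuracy
#' `(TP+TN)/(TP+FP+TN+FN)` and F1 `2TP/(2TP+FN+FP)`. Metrics with a zero
#' denominator are reported as `NaN` with a warning rather than 0, so they
#' cannot silently inflate averages.
#'
#' @param TP,FP,TN,FN Non-negative confusion counts.
#' @return Named numeric vector `sensitivity`, `precision`, `accuracy`, `f1`.
#' @export
segment_metrics <- function(TP, FP, TN, FN) {
  counts <- c(TP, FP, TN, FN)
  if (any(counts < 0)) stop_data("confusion counts must be non-negative")
  if (sum(counts) == 0) stop_data("confusion counts are all zero")
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reporting NaN")
      return(NaN)
    }
    num / den
  }
  c(sensitivity = safe(TP, TP + FN, "sensitivity"),
    precision = safe(TP, TP + FP, "precision"),
    accuracy = safe(TP + TN, TP + FP + TN + FN, "accuracy"),
    f1 = safe(2 * TP, 2 * TP + FN + FP, "F1"))
}

#' Confusion counts from 0/1 predictions
#' @param pred,truth 0/1 vectors of equal length.
#' @return Named vector `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(pred, truth) {
  pred <- as.integer(as.logical(pred))
  truth <- as.integer(as.logical(truth))
  if (length(pred) != length(truth)) stop_data("length mismatch")
  c(TP = sum(pred == 1 & truth == 1), FP = sum(pred == 1 & truth == 0),
    TN = sum(pred == 0 & truth == 0), FN = sum(pred == 0 & truth == 1))
}

#' McNemar's paired test on discordant episode counts
#'
#' Chi-square statistic with continuity correction,
#' \deqn{\chi^2 = \frac{(|e_{01} - e_{10}| - 1)^2}{e_{01} + e_{10}},}
#' with 1 degree of freedom, where `e01` counts cases misclassified by
#' classifier 1 but not classifier 2 and `e10` the reverse. The null
#' hypothesis of equal error rates is rejected when the statistic exceeds
#' the chi-square critical value at level `alpha`.
#'
#' @param e01,e10 Discordant counts; `e01 + e10` must be positive.
#' @param alpha Significance level.
#' @return List of class `mcnemar_result` with `e01`, `e10`, `chi_square`,
#'   `alpha`, `critical_value`, `reject`.
#' @export
mcnemar_test <- function(e01, e10, alpha = 0.01) {
  if (e01 < 0 || e10 < 0) stop_data("discordant counts must be >= 0")
  if (e01 + e10 == 0) {
    stop_data("e01 + e10 must be positive; the test is undefined")
  }
  chi <- (abs(e01 - e10) - 1)^2 / (e01 + e10)
  crit <- qchisq(1 - alpha, df = 1)
  structure(list(e01 = e01, e10 = e10, chi_square = chi, alpha = alpha,
                 critical_value = crit, reject = chi > crit),
            class = "mcnemar_result")
}

#' @export
print.mcnemar_result <- function(x, ...) {
  cat(sprintf("McNemar chi-square = %.2f (e01=%d, e10=%d); critical value %.3f at alpha=%g: %s\n",
              x$chi_square, x$e01, x$e10, x$critical_value, x$alpha,
              if (x$reject) "reject equal error rates" else "no rejection"))
  invisible(x)
}

#' Intersection over union of two bounding boxes
#'
#' Boxes are `c(x, y, w, h)` with positive width and height.
#'
#' @param boxA,boxB Numeric length-4 vectors.
#' @return IoU in \[0, 1\]; 0 for disjoint boxes.
#' @export
iou <- function(boxA, boxB) {
  if (boxA[3] <= 0 || boxA[4] <= 0 || boxB[3] <= 0 || boxB[4] <= 0) {
    stop_data("degenerate box: width and height must be positive")
  }
  ix <- max(0, min(boxA[1] + boxA[3], boxB[1] + boxB[3]) - max(boxA[1], boxB[1]))
  iy <- max(0, min(boxA[2] + boxA[4], boxB[2] + boxB[4]) - max(boxA[2], boxB[2]))
  inter <- ix * iy
  union <- boxA[3] * boxA[4] + boxB[3] * boxB[4] - inter
  inter / union
}

#' Detection evaluation configuration
#'
#' @param iou_thresholds IoU thresholds (default 0.50 to 0.95 step 0.05).
#' @param score_thresholds Confidence score thresholds at which the
#'   precision-recall points are computed (default 0 to 1 step 0.1).
#' @return An object of class `detection_eval_config`.
#' @export
detection_eval_config <- function(iou_thresholds = seq(0.5, 0.95, by = 0.05),
                                  score_thresholds = seq(0, 1, by = 0.1)) {
  if (is.unsorted(iou_thresholds) || is.unsorted(score_thresholds)) {
    stop_config("thresholds must be sorted")
  }
  assert_prob(iou_thresholds, "iou_thresholds")
  assert_prob(score_thresholds, "score_thresholds")
  structure(list(iou_thresholds = iou_thresholds,
                 score_thresholds = score_thresholds),
            class = "detection_eval_config")
}

# greedy matching at one (score, IoU) threshold: detections in descending
# score order, each truth box used at most once, same image and class only
match_detections_at <- function(det, truth, iou_thr) {
  if (nrow(det) == 0) return(c(tp = 0, fp = 0, fn = nrow(truth)))
  det <- det[order(-det$score), , drop = FALSE]
  used <- rep(FALSE, nrow(truth))
  tp <- 0L
  for (i in seq_len(nrow(det))) {
    best <- 0
    best_j <- 0L
    cand <- which(!used & truth$image_id == det$image_id[i])
    for (j in cand) {
      v <- iou(as.numeric(det[i, c("x", "y", "w", "h")]),
               as.numeric(truth[j, c("x", "y", "w", "h")]))
      if (v >= iou_thr && v > best) {
        best <- v
        best_j <- j
      }
    }
    if (best_j > 0L) {
      used[best_j] <- TRUE
      tp <- tp + 1L
    }
  }
  c(tp = tp, fp = nrow(det) - tp, fn = nrow(truth) - tp)
}

#' Average precision of one class at one IoU threshold
#'
#' Precision and recall are computed at each confidence-score threshold of the
#' configured grid (detections with score >= threshold, greedily matched by
#' descending score, one truth box per detection, IoU >= `iou_threshold`
#' required). AP is the trapezoidal area under the resulting recall-precision
#' points, augmented with a point at recall 0 carrying the first point's
#' precision; thresholds landing on the same recall are collapsed to their
#' best precision, and thresholds where precision is undefined (no detections
#' retained) are dropped.
#'
#' @param detections Data frame `image_id`, `x`, `y`, `w`, `h`, `score` (one
#'   class).
#' @param truths Data frame `image_id`, `x`, `y`, `w`, `h` (same class).
#' @param iou_threshold Required IoU for a match.
#' @param score_thresholds Score threshold grid.
#' @return AP in \[0, 1\], or `NA` (with a warning) when there are no truth
#'   boxes.
#' @export
average_precision <- function(detections, truths, iou_threshold,
                              score_thresholds = seq(0, 1, by = 0.1)) {
  if (nrow(truths) == 0) {
    warning("no ground-truth boxes: AP undefined, skipping")
    return(NA_real_)
  }
  pr <- lapply(score_thresholds, function(thr) {
    kept <- detections[detections$score >= thr, , drop = FALSE]
    m <- match_detections_at(kept, truths, iou_threshold)
    if (m["tp"] + m["fp"] == 0) return(NULL)  # precision undefined
    c(recall = unname(m["tp"] / (m["tp"] + m["fn"])),
      precision = unname(m["tp"] / (m["tp"] + m["fp"])))
  })
  pr <- do.call(rbind, pr[!vapply(pr, is.null, logical(1))])
  if (is.null(pr) || nrow(pr) == 0) return(0)
  # several score thresholds can land on the same recall; the PR curve keeps
  # the best precision attained at each recall level
  recs <- sort(unique(pr[, "recall"]))
  precs <- vapply(recs, function(rv) {
    max(pr[pr[, "recall"] == rv, "precision"])
  }, numeric(1))
  r <- c(0, recs)
  p <- c(precs[1], precs)
  sum(diff(r) * (head(p, -1) + tail(p, -1)) / 2)
}

#' Mean average precision over IoU thresholds (mAP@\[.5,.95\])
#'
#' AP is averaged over the configured IoU thresholds per class, and over
#' classes for the overall score; results are reported on the 0-100 scale.
#'
#' @param detections Data frame `image_id`, `x`, `y`, `w`, `h`, `class`,
#'   `score`.
#' @param truths Data frame `image_id`, `x`, `y`, `w`, `h`, `class`.
#' @param config A [detection_eval_config()].
#' @return List with `per_class` (named vector, 0-100), `overall` (0-100) and
#'   the per-class, per-threshold `ap_matrix` (0-1 scale).
#' @export
mean_average_precision <- function(detections, truths,
                                   config = detection_eval_config()) {
  classes <- sort(unique(truths$class))
  if (length(classes) == 0) stop_data("no classes present in ground truth")
  ap <- matrix(NA_real_, length(classes), length(config$iou_thresholds),
               dimnames = list(classes, config$iou_thresholds))
  for (cl in classes) {
    d <- detections[detections$class == cl, , drop = FALSE]
    t <- truths[truths$class == cl, , drop = FALSE]
    for (j in seq_along(config$iou_thresholds)) {
      ap[cl, j] <- average_precision(d, t, config$iou_thresholds[j],
                                     config$score_thresholds)
    }
  }
  per_class <- rowMeans(ap) * 100
  list(per_class = per_class,
       overall = mean(per_class),
       ap_matrix = ap)
}

#' Leave-one-subject-out cross-validation folds
#'
#' One fold per subject: the test fold is exactly that subject's records and
#' the folds partition the data.
#'
#' @param subject_ids Vector of per-record subject identifiers.
#' @return List of folds, each with `subject`, `train` and `test` index
#'   vectors.
#' @export
loso_split <- function(subject_ids) {
  subjects <- unique(subject_ids)
  if (length(subjects) < 2) stop_data("LOSO requires at least 2 subjects")
  lapply(subjects, function(s) {
    list(subject = s,
         train = which(subject_ids != s),
         test = which(subject_ids == s))
  })
}

#' Random train/validation/test holdout split
#'
#' Sizes are within one record of the exact fractions; the split is
#' reproducible under the seed and does not disturb the global RNG state.
#'
#' @param n Number of records (or a vector whose length is used).
#' @param fractions Length-3 fractions summing to 1.
#' @param seed Integer seed.
#' @return List with disjoint `train`, `val`, `test` index vectors covering
#'   `1:n`.
#' @export
holdout_split <- function(n, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (length(n) > 1) n <- length(n)
  if (abs(sum(fractions) - 1) > 1e-8 || length(fractions) != 3) {
    stop_config("fractions must be 3 values summing to 1")
  }
  sizes <- floor(n * fractions)
  rem <- n - sum(sizes)
  if (rem > 0) {
    frac_rem <- n * fractions - sizes
    add <- order(frac_rem, decreasing = TRUE)[seq_len(rem)]
    sizes[add] <- sizes[add] + 1
  }
  with_seed(seed, {
    ord <- sample.int(n)
    list(train = sort(ord[seq_len(sizes[1])]),
         val = sort(ord[sizes[1] + seq_len(sizes[2])]),
         test = sort(ord[sizes[1] + sizes[2] + seq_len(sizes[3])]))
  })
}
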