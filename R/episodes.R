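#' Convert per-segment predictions to eating events
#'
#' Maximal runs of consecutive intake-labeled segments become one eating
#' event spanning the run's first segment start to its last segment end
#' (start + `window_s`).
#'
#' @param labels 0/1 per-segment predictions.
#' @param t_start_s Segment start times, seconds; defaults to consecutive
#'   `window_s` windows from 0.
#' @param window_s Segment length in seconds.
#' @return Data frame with `start_s`, `end_s`, one row per event (possibly
#'   zero rows).
#' @export
segments_to_events <- function(labels, t_start_s = NULL, window_s = 15) {
  lab <- as.integer(as.logical(labels))
  n <- length(lab)
  t_start_s <- t_start_s %||% ((seq_len(n) - 1) * window_s)
  if (length(t_start_s) != n) stop_data("labels/times length mismatch")
  if (n == 0L || !any(lab == 1L)) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 1L
  data.frame(start_s = t_start_s[starts[keep]],
             end_s = t_start_s[ends[keep]] + window_s)
}

#' Merge eating events into eating episodes
#'
#' Consecutive events whose inter-event interval (next start minus previous
#' end) is strictly less than `gap_min` minutes are combined into one eating
#' episode; a gap of exactly `gap_min` minutes starts a new episode. The
#' episode spans the earliest start to the latest end of its constituent
#' events.
#'
#' @param events Data frame with `start_s`, `end_s` (sorted by start; unsorted
#'   input is sorted with a warning).
#' @param gap_min Merge threshold in minutes.
#' @return Data frame with `start_s`, `end_s`, `n_events`.
#' @export
merge_events_to_episodes <- function(events, gap_min = 15) {
  if (nrow(events) == 0L) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_events = integer(0)))
  }
  if (any(events$end_s <= events$start_s)) {
    stop_data("events must have end_s > start_s")
  }
  if (is.unsorted(events$start_s)) {
    warning("events not sorted by start time; sorting")
    events <- events[order(events$start_s), , drop = FALSE]
  }
  gap_s <- gap_min * 60
  start <- events$start_s[1]
  end <- events$end_s[1]
  count <- 1L
  out <- list()
  for (i in seq_len(nrow(events))[-1]) {
    if (events$start_s[i] - end < gap_s) {
      end <- max(end, events$end_s[i])
      count <- count + 1L
    } else {
      out[[length(out) + 1L]] <- data.frame(start_s = start, end_s = end,
                                            n_events = count)
      start <- events$start_s[i]
      end <- events$end_s[i]
      count <- 1L
    }
  }
  out[[length(out) + 1L]] <- data.frame(start_s = start, end_s = end,
                                        n_events = count)
  do.call(rbind, out)
}

#' Match predicted episodes against ground truth
#'
#' Greedy one-to-one matching in time order: a predicted episode overlapping
#' an as-yet-unmatched truth episode by at least `min_overlap_s` seconds is a
#' true positive; unmatched predictions are false positives and unmatched
#' truth episodes are false negatives.
#'
#' @param predicted,truth Data frames with `start_s`, `end_s`; each list must
#'   be sorted and internally non-overlapping.
#' @param min_overlap_s Minimum temporal overlap (seconds) to count a match.
#' @return List of class `episode_confusion` with `TP`, `FP`, `FN` and a
#'   `matches` data frame (predicted index, truth index).
#' @export
match_episodes <- function(predicted, truth, min_overlap_s = 1) {
  check_disjoint <- function(df, what) {
    if (nrow(df) > 1) {
      df <- df[order(df$start_s), , drop = FALSE]
      if (any(df$start_s[-1] < df$end_s[-nrow(df)])) {
        stop_data(what, " episodes overlap within the list")
      }
    }
    df
  }
  predicted <- check_disjoint(predicted, "predicted")
  truth <- check_disjoint(truth, "truth")
  matched_truth <- rep(FALSE, nrow(truth))
  matches <- list()
  tp <- 0L
  for (i in seq_len(nrow(predicted))) {
    for (j in seq_len(nrow(truth))) {
      if (matched_truth[j]) next
      ov <- min(predicted$end_s[i], truth$end_s[j]) -
        max(predicted$start_s[i], truth$start_s[j])
      if (ov >= min_overlap_s) {
        matched_truth[j] <- TRUE
        tp <- tp + 1L
        matches[[length(matches) + 1L]] <- c(pred = i, truth = j)
        break
      }
    }
  }
  structure(list(TP = tp,
                 FP = nrow(predicted) - tp,
                 FN = nrow(truth) - tp,
                 matches = if (length(matches)) {
                   as.data.frame(do.call(rbind, matches))
                 } else {
                   data.frame(pred = integer(0), truth = integer(0))
                 }),
            class = "episode_confusion")
}

#' @export
print.episode_confusion <- function(x, ...) {
  cat(sprintf("<episode_confusion> TP=%d FP=%d FN=%d\n", x$TP, x$FP, x$FN))
  invisible(x)
}

#' Episode-level sensitivity and precision
#' @param confusion An `episode_confusion`.
#' @return Named numeric vector `sensitivity`, `precision`, `f1`.
#' @export
episode_metrics <- function(confusion) {
  tp <- confusion$TP; fp <- confusion$FP; fn <- confusion$FN
  c(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NaN,
    precision = if (tp + fp > 0) tp / (tp + fp) else NaN,
    f1 = if (2 * tp + fn + fp > 0) 2 * tp / (2 * tp + fn + fp) else NaN)
}

#' Write events/episodes as JSON or BED-like TSV
#' @param intervals Data frame with `start_s`, `end_s`.
#' @param path Output path; `.json` or `.tsv`/`.bed` by extension.
#' @return `path`, invisibly.
#' @export
write_episodes <- function(intervals, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(intervals, path, digits = NA)
  } else {
    write.table(intervals, path, sep = "\t", row.names = FALSE,
                quote = FALSE)
  }
  invisible(path)
}
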