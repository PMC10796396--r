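# Independent oracles used to validate the fast implementations.

# Brute-force CWT at one scale: the Morse wavelet is reconstructed in the
# time domain by trapezoidal quadrature of its one-sided Fourier integral,
# then the transform is evaluated as a direct (circular) correlation sum.
# Entirely separate from the FFT filter-bank path.
oracle_cwt_magnitude <- function(x, scale, gamma = 3, beta = 20,
                                 n_quad = 20001) {
  n <- length(x)
  omega <- seq(0, pi, length.out = n_quad)
  dw <- omega[2] - omega[1]
  Psi <- intakefuse:::morse_psi(scale * omega, gamma, beta) * sqrt(scale)
  wts <- c(0.5, rep(1, n_quad - 2), 0.5) * dw
  tt <- seq(-n / 2, n / 2 - 1)
  g <- vapply(tt, function(t1) sum(Psi * exp(1i * omega * t1) * wts) / (2 * pi),
              complex(1))
  wrap <- function(d) ((d + n / 2) %% n) - n / 2
  taus <- 0:(n - 1)
  C <- vapply(0:(n - 1), function(b) {
    d <- wrap(b - taus)
    sum(x * g[d + n / 2 + 1])
  }, complex(1))
  Mod(C)
}

# Transitive-closure clustering of events under the strict "<gap" relation;
# the episode span of each connected component is its min start / max end.
oracle_merge_episodes <- function(events, gap_min = 15) {
  n <- nrow(events)
  if (n == 0L) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  gap_s <- gap_min * 60
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      sep <- max(events$start_s[j] - events$end_s[i],
                 events$start_s[i] - events$end_s[j], 0)
      adj[i, j] <- sep < gap_s
    }
  }
  reach <- adj | diag(n) > 0
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[which(reach[i, ])] <- cid
    }
  }
  out <- do.call(rbind, lapply(seq_len(cid), function(k) {
    data.frame(start_s = min(events$start_s[comp == k]),
               end_s = max(events$end_s[comp == k]))
  }))
  out[order(out$start_s), , drop = FALSE]
}

# Exhaustive-enumeration AP: at each (score, IoU) threshold pair the true
# positive count is the MAXIMUM over all injective detection-to-truth
# assignments (per image, same class), rather than the greedy-by-score count.
oracle_max_tp <- function(det, truth, iou_thr) {
  per_image <- function(d, t) {
    if (nrow(d) == 0 || nrow(t) == 0) return(0L)
    best <- 0L
    recurse <- function(di, used, count) {
      if (count + (nrow(d) - di + 1L) <= best) return()  # bound
      if (di > nrow(d)) {
        best <<- max(best, count)
        return()
      }
      recurse(di + 1L, used, count)
      for (j in seq_len(nrow(t))) {
        if (!used[j] &&
            iou(as.numeric(d[di, c("x", "y", "w", "h")]),
                as.numeric(t[j, c("x", "y", "w", "h")])) >= iou_thr) {
          used[j] <- TRUE
          recurse(di + 1L, used, count + 1L)
          used[j] <- FALSE
        }
      }
      best <<- max(best, count)
    }
    recurse(1L, rep(FALSE, nrow(t)), 0L)
    best
  }
  tp <- 0L
  for (img in unique(truth$image_id)) {
    tp <- tp + per_image(det[det$image_id == img, , drop = FALSE],
                         truth[truth$image_id == img, , drop = FALSE])
  }
  extra <- det[!det$image_id %in% truth$image_id, , drop = FALSE]
  tp
}

oracle_average_precision <- function(det, truth, iou_thr,
                                     score_thr = seq(0, 1, by = 0.1)) {
  pts <- list()
  for (thr in score_thr) {
    kept <- det[det$score >= thr, , drop = FALSE]
    if (nrow(kept) == 0) next
    tp <- oracle_max_tp(kept, truth, iou_thr)
    pts[[length(pts) + 1L]] <- c(recall = tp / nrow(truth),
                                 precision = tp / nrow(kept))
  }
  if (length(pts) == 0) return(0)
  pr <- do.call(rbind, pts)
  recs <- sort(unique(pr[, "recall"]))
  precs <- vapply(recs, function(rv) {
    max(pr[pr[, "recall"] == rv, "precision"])
  }, numeric(1))
  r <- c(0, recs)
  p <- c(precs[1], precs)
  sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
}
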