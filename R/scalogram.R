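#' Continuous wavelet transform configuration
#'
#' Parameters of the Morse-wavelet filter bank used to turn one 15-s
#' accelerometer axis into a scalogram. The generalized Morse wavelet is
#' defined in the frequency domain as
#' \eqn{\Psi(\omega) = A\,\omega^{\beta} e^{-\omega^{\gamma}}} for
#' \eqn{\omega > 0}, with symmetry \eqn{\gamma} and time-bandwidth product
#' \eqn{P^2 = \beta\gamma}; the defaults (\eqn{\gamma = 3}, \eqn{P^2 = 60})
#' are the conventional choice for oscillatory biomedical signals.
#'
#' @param n_freq_bins Number of centre frequencies (rows of the scalogram).
#' @param freq_min_hz,freq_max_hz Frequency range covered by the bank, Hz.
#'   `freq_max_hz` must not exceed the Nyquist frequency.
#' @param wavelet_symmetry Morse symmetry parameter \eqn{\gamma}.
#' @param wavelet_time_bandwidth Morse time-bandwidth product \eqn{P^2}.
#' @param freq_spacing `"geometric"` (the natural CWT scale discretization)
#'   or `"linear"`.
#' @return An object of class `cwt_config`.
#' @export
cwt_config <- function(n_freq_bins = 64,
                       freq_min_hz = 1,
                       freq_max_hz = 64,
                       wavelet_symmetry = 3,
                       wavelet_time_bandwidth = 60,
                       freq_spacing = c("geometric", "linear")) {
  freq_spacing <- match.arg(freq_spacing)
  if (n_freq_bins < 2) stop_config("n_freq_bins must be >= 2")
  if (freq_min_hz <= 0 || freq_max_hz <= freq_min_hz) {
    stop_config("need 0 < freq_min_hz < freq_max_hz")
  }
  if (wavelet_symmetry <= 0 || wavelet_time_bandwidth <= 0) {
    stop_config("Morse parameters must be positive")
  }
  structure(list(n_freq_bins = as.integer(n_freq_bins),
                 freq_min_hz = freq_min_hz, freq_max_hz = freq_max_hz,
                 wavelet_symmetry = wavelet_symmetry,
                 wavelet_time_bandwidth = wavelet_time_bandwidth,
                 freq_spacing = freq_spacing),
            class = "cwt_config")
}

#' Frequency axis of a CWT configuration
#' @param config A [cwt_config()].
#' @return Numeric vector of centre frequencies in Hz (descending-frequency
#'   row order is \emph{not} applied; row 1 is `freq_min_hz`).
#' @export
cwt_frequencies <- function(config) {
  if (config$freq_spacing == "geometric") {
    exp(seq(log(config$freq_min_hz), log(config$freq_max_hz),
            length.out = config$n_freq_bins))
  } else {
    seq(config$freq_min_hz, config$freq_max_hz,
        length.out = config$n_freq_bins)
  }
}

# Morse wavelet in the frequency domain, peak-normalized to Psi(omega_p) = 2.
# Evaluated in log space to keep omega^beta stable.
morse_psi <- function(omega, gamma, beta) {
  omega_p <- (beta / gamma)^(1 / gamma)
  logA <- log(2) - beta * log(omega_p) + omega_p^gamma
  out <- numeric(length(omega))
  pos <- omega > 0
  out[pos] <- exp(logA + beta * log(omega[pos]) - omega[pos]^gamma)
  out
}

# cache filter banks keyed by (n, fs, config) — recomputing 64x1920 exp grids
# per segment dominates batch runs otherwise
.bank_cache <- new.env(parent = emptyenv())

# Filter bank: matrix n_freq x n of sqrt(a) * Psi(a * omega_k) with the
# negative-frequency half zeroed (analytic wavelet). omega_k = 2*pi*k/n in
# radians/sample; the scale a_j places the Morse peak at centre frequency f_j.
morse_filter_bank <- function(n, sample_rate_hz, config) {
  key <- paste(n, sample_rate_hz, config$n_freq_bins, config$freq_min_hz,
               config$freq_max_hz, config$wavelet_symmetry,
               config$wavelet_time_bandwidth, config$freq_spacing, sep = "|")
  hit <- .bank_cache[[key]]
  if (!is.null(hit)) return(hit)
  gamma <- config$wavelet_symmetry
  beta <- config$wavelet_time_bandwidth / gamma
  omega_p <- (beta / gamma)^(1 / gamma)
  freqs <- cwt_frequencies(config)
  scales <- omega_p / (2 * pi * freqs / sample_rate_hz)
  k <- 0:(n - 1)
  omega <- 2 * pi * k / n
  keep <- k <= floor(n / 2)           # one-sided (analytic) support
  bank <- matrix(0, config$n_freq_bins, n)
  for (j in seq_along(scales)) {
    row <- numeric(n)
    row[keep] <- sqrt(scales[j]) * morse_psi(scales[j] * omega[keep], gamma, beta)
    bank[j, ] <- row
  }
  out <- list(bank = bank, freqs = freqs, scales = scales)
  .bank_cache[[key]] <- out
  out
}

#' Raw Morse-wavelet scalogram of one accelerometer axis
#'
#' Computes the absolute magnitude of the continuous wavelet transform
#' \deqn{C(a,b) = \frac{1}{\sqrt{|a|}} \int s(\tau)\,
#'   \overline{\psi}\!\left(\frac{\tau-b}{a}\right) d\tau}
#' on a bank of Morse wavelets whose centre frequencies span the configured
#' range (64 bins over 1-64 Hz at defaults, giving a 64 x 1920 scalogram for a
#' 15-s segment at 128 Hz). The transform is evaluated per scale by frequency-
#' domain multiplication; it is linear in the input amplitude.
#'
#' @param axis_signal Numeric vector, one axis of a segment.
#' @param config A [cwt_config()].
#' @param sample_rate_hz Sampling rate in Hz.
#' @return An object of class `raw_scalogram`: list with `magnitude`
#'   (n_freq_bins x n_samples, non-negative) and `freq_axis_hz`.
#' @export
cwt_scalogram <- function(axis_signal, config = cwt_config(),
                          sample_rate_hz = 128) {
  if (!is.numeric(axis_signal) || length(axis_signal) < 2) {
    stop_data("axis_signal must be a numeric vector")
  }
  if (any(!is.finite(axis_signal))) {
    stop_data("axis_signal contains NaN/Inf")
  }
  if (config$freq_max_hz > sample_rate_hz / 2) {
    stop_config("freq_max_hz exceeds the Nyquist frequency")
  }
  n <- length(axis_signal)
  fb <- morse_filter_bank(n, sample_rate_hz, config)
  xf <- fft(axis_signal)
  # columns: one filtered spectrum per scale; a single inverse mvfft batch
  Y <- t(fb$bank) * xf          # n x n_freq, recycled column-wise
  C <- mvfft(Y, inverse = TRUE) / n
  structure(list(magnitude = t(Mod(C)), freq_axis_hz = fb$freqs),
            class = "raw_scalogram")
}

#' Quantize a scalogram to 8-bit
#'
#' Unit-based normalization followed by 8-bit conversion:
#' \deqn{I(x,y) = \mathrm{round}\left(255\,\frac{S(x,y)-S_{min}}
#'   {S_{max}-S_{min}}\right)}
#' with rounding half away from zero and clipping to \[0, 255\]. A constant
#' (degenerate) scalogram quantizes to all zeros with a warning rather than
#' erroring, so signal-free gaps do not abort batch runs.
#'
#' @param raw A `raw_scalogram` or a numeric matrix.
#' @return Integer matrix with values in 0..255.
#' @export
quantize_scalogram <- function(raw) {
  S <- if (inherits(raw, "raw_scalogram")) raw$magnitude else raw
  if (any(!is.finite(S))) stop_data("scalogram contains non-finite values")
  smin <- min(S)
  smax <- max(S)
  if (smax == smin) {
    warning("constant scalogram: quantizing to all zeros")
    out <- matrix(0L, nrow(S), ncol(S))
    return(out)
  }
  q <- round_half_up(255 * (S - smin) / (smax - smin))
  q <- pmin(pmax(q, 0), 255)
  matrix(as.integer(q), nrow(S), ncol(S))
}

# 1-D bilinear resize along columns using half-pixel-centre mapping: each
# output value is a weighted average of the two nearest input columns.
resize_columns_bilinear <- function(m, out_cols) {
  in_cols <- ncol(m)
  if (in_cols == out_cols) return(m)
  r <- in_cols / out_cols
  u <- (seq_len(out_cols) - 0.5) * r - 0.5      # 0-based source centre coords
  i0 <- pmin(pmax(floor(u), 0), in_cols - 1)
  i1 <- pmin(i0 + 1, in_cols - 1)
  w <- u - i0
  m[, i0 + 1, drop = FALSE] * rep(1 - w, each = nrow(m)) +
    m[, i1 + 1, drop = FALSE] * rep(w, each = nrow(m))
}

#' Assemble the final scalogram image from three axis scalograms
#'
#' Vertically concatenates the quantized x/y/z-axis scalograms (64 x 1920 each
#' at defaults) into a 192 x 1920 image, then bilinearly downsamples the time
#' axis to give the final 192 x 192 x 1 input image of the sensor CNN. Values
#' are re-quantized to 0..255 after interpolation.
#'
#' @param axis_scalograms List of exactly 3 quantized matrices (x, y, z order)
#'   with identical dimensions.
#' @param out_cols Number of time columns after downsampling.
#' @param segment_id Optional provenance identifier.
#' @return An integer matrix of class `scalogram_image` (192 x 192 at
#'   defaults; the single channel dimension is implicit).
#' @export
assemble_scalogram <- function(axis_scalograms, out_cols = 192,
                               segment_id = NULL) {
  if (!is.list(axis_scalograms) || length(axis_scalograms) != 3) {
    stop_data("axis_scalograms must be a list of exactly 3 matrices")
  }
  dims <- lapply(axis_scalograms, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop_data("axis scalograms have mismatched shapes")
  }
  stacked <- do.call(rbind, axis_scalograms)
  resized <- resize_columns_bilinear(stacked, out_cols)
  q <- pmin(pmax(round_half_up(resized), 0), 255)
  img <- matrix(as.integer(q), nrow(stacked), out_cols)
  structure(img, class = c("scalogram_image", class(img)),
            segment_id = segment_id)
}

#' Split a recording into fixed non-overlapping segments
#'
#' Consecutive 15-s rectangular windows (1920 samples per axis at 128 Hz); a
#' trailing partial window is discarded.
#'
#' @param recording A `labeled_recording`.
#' @param window_s Window length in seconds.
#' @return List of segments; each is an n x 3 matrix with attributes
#'   `start_time_s` and `sample_rate_hz`. Empty list if the recording is
#'   shorter than one window.
#' @export
segment_signal <- function(recording, window_s = 15) {
  stopifnot(inherits(recording, "labeled_recording"))
  if (window_s <= 0) stop_config("window_s must be > 0")
  fs <- recording$sample_rate_hz
  step <- floor(window_s * fs)
  n_seg <- floor(nrow(recording$signal) / step)
  lapply(seq_len(n_seg), function(i) {
    seg <- recording$signal[((i - 1) * step + 1):(i * step), , drop = FALSE]
    attr(seg, "start_time_s") <- (i - 1) * window_s
    attr(seg, "sample_rate_hz") <- fs
    seg
  })
}

#' Full scalogram image for one tri-axial segment
#'
#' Applies [cwt_scalogram()] and [quantize_scalogram()] per axis (per-axis
#' normalization, so one high-variance axis cannot blank the others), then
#' [assemble_scalogram()].
#'
#' @param segment n x 3 numeric matrix (a [segment_signal()] element).
#' @param config A [cwt_config()].
#' @param sample_rate_hz Sampling rate; taken from the segment attribute when
#'   present.
#' @return A `scalogram_image`.
#' @export
scalogram_from_segment <- function(segment, config = cwt_config(),
                                   sample_rate_hz = NULL) {
  fs <- sample_rate_hz %||% attr(segment, "sample_rate_hz") %||% 128
  axes <- lapply(1:3, function(ax) {
    quantize_scalogram(cwt_scalogram(segment[, ax], config, fs))
  })
  assemble_scalogram(axes, segment_id = attr(segment, "start_time_s"))
}

#' Scalogram images for every segment of a recording
#'
#' @param recording A `labeled_recording`.
#' @param config A [cwt_config()].
#' @return List with `images` (list of `scalogram_image`), `labels` and
#'   `start_times_s`.
#' @export
scalogram_batch <- function(recording, config = cwt_config()) {
  segs <- segment_signal(recording, recording$window_s)
  images <- lapply(segs, scalogram_from_segment, config = config,
                   sample_rate_hz = recording$sample_rate_hz)
  labels <- recording$segment_labels
  if (length(labels) == 0L) labels <- rep(NA_integer_, length(images))
  list(images = images,
       labels = labels[seq_along(images)],
       start_times_s = vapply(segs, attr, numeric(1), "start_time_s"))
}

#' Write/read a scalogram image as 8-bit grayscale PNG with a JSON sidecar
#'
#' @param image A `scalogram_image`.
#' @param path PNG path; the sidecar is written next to it as `<path>.json`.
#' @param label Optional intake label stored in the sidecar.
#' @param start_time_s Optional segment start time stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_scalogram_png <- function(image, path, label = NA, start_time_s = NA) {
  png::writePNG(unclass(image) / 255, path)
  jsonlite::write_json(list(segment_id = attr(image, "segment_id"),
                            label = label, start_time_s = start_time_s),
                       paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_scalogram_png
#' @export
read_scalogram_png <- function(path) {
  px <- png::readPNG(path)
  img <- matrix(as.integer(round_half_up(px * 255)), nrow(px), ncol(px))
  structure(img, class = c("scalogram_image", class(img)))
}
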