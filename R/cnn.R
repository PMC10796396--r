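#' Configuration of the 15-layer sensor CNN
#'
#' The network classifies a quantized scalogram image as intake vs non-intake.
#' Its fixed composition is three convolutional layers, three ReLU layers, two
#' cross-channel (local response) normalization layers, three max-pooling
#' layers, one dropout layer, one fully connected layer, one softmax layer and
#' one classification layer — 15 layers in total, arranged as
#' `[conv-ReLU-LRN-pool] x2, [conv-ReLU-pool], dropout, FC(2), softmax,
#' classification`. Training runs 8 epochs with batch size 32 by default.
#' Filter counts, kernel sizes, LRN constants and the optimizer settings are
#' tunable; the defaults are conventional values for this network lineage.
#'
#' @param input_shape Length-2 or -3 integer vector; spatial input size
#'   (192 x 192 single-channel at defaults). Height and width must be
#'   divisible by 8 (three 2x2 poolings).
#' @param conv_filters Filter counts of the three convolutional layers.
#' @param conv_kernels Odd kernel sizes of the three convolutional layers.
#' @param pool_size Max-pooling window and stride.
#' @param lrn_params Named list `window`, `k`, `alpha`, `beta` of the
#'   cross-channel normalization.
#' @param dropout_rate Dropout probability before the fully connected layer.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param learning_rate SGD learning rate.
#' @param momentum SGD momentum.
#' @param seed Integer seed controlling initialization, shuffling and dropout.
#' @return An object of class `model_config`.
#' @export
model_config <- function(input_shape = c(192, 192, 1),
                         conv_filters = c(8, 16, 32),
                         conv_kernels = c(5, 3, 3),
                         pool_size = 2,
                         lrn_params = list(window = 5, k = 1,
                                           alpha = 1e-4, beta = 0.75),
                         dropout_rate = 0.5,
                         epochs = 8,
                         batch_size = 32,
                         learning_rate = 1e-3,
                         momentum = 0.9,
                         seed = 1L) {
  if (length(input_shape) == 3 && input_shape[3] != 1) {
    stop_config("only single-channel input is supported")
  }
  hw <- input_shape[1:2]
  if (any(hw %% 8 != 0)) {
    stop_config("input height/width must be divisible by 8")
  }
  if (length(conv_filters) != 3 || length(conv_kernels) != 3) {
    stop_config("exactly three convolutional layers are required")
  }
  if (any(conv_kernels %% 2 == 0)) stop_config("kernel sizes must be odd")
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop_config("dropout_rate must be in [0, 1)")
  }
  if (epochs < 1) stop_config("epochs must be >= 1")
  if (learning_rate <= 0) stop_config("learning_rate must be > 0")
  structure(list(input_shape = c(hw, 1L),
                 conv_filters = as.integer(conv_filters),
                 conv_kernels = as.integer(conv_kernels),
                 pool_size = as.integer(pool_size),
                 lrn_params = lrn_params,
                 dropout_rate = dropout_rate,
                 n_classes = 2L,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 momentum = momentum,
                 seed = as.integer(seed)),
            class = "model_config")
}

cnn_layer_sequence <- function(config) {
  f <- config$conv_filters
  k <- config$conv_kernels
  c(sprintf("conv(%dx%d, %d filters)", k[1], k[1], f[1]), "relu",
    "cross_channel_norm", "maxpool(2x2/2)",
    sprintf("conv(%dx%d, %d filters)", k[2], k[2], f[2]), "relu",
    "cross_channel_norm", "maxpool(2x2/2)",
    sprintf("conv(%dx%d, %d filters)", k[3], k[3], f[3]), "relu",
    "maxpool(2x2/2)",
    sprintf("dropout(%.2f)", config$dropout_rate),
    "fully_connected(2)", "softmax", "classification")
}

cnn_par_list <- function(config) {
  list(k1 = config$conv_kernels[1], k2 = config$conv_kernels[2],
       k3 = config$conv_kernels[3], pool = config$pool_size,
       lrn_window = as.integer(config$lrn_params$window),
       lrn_k = config$lrn_params$k, lrn_alpha = config$lrn_params$alpha,
       lrn_beta = config$lrn_params$beta)
}

cnn_fc_dim <- function(config) {
  hw <- config$input_shape[1:2] %/% 8
  as.integer(hw[1] * hw[2] * config$conv_filters[3])
}

# He-normal initialization; conv weights stored as (filters x k^2*C_in)
# matrices matching the im2col row layout of the compute kernel.
cnn_init_weights <- function(config) {
  f <- config$conv_filters
  k <- config$conv_kernels
  fan <- c(k[1]^2 * 1, k[2]^2 * f[1], k[3]^2 * f[2])
  D <- cnn_fc_dim(config)
  he <- function(nr, nc, fan_in) {
    matrix(rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
  }
  list(W1 = he(f[1], fan[1], fan[1]), b1 = numeric(f[1]),
       W2 = he(f[2], fan[2], fan[2]), b2 = numeric(f[2]),
       W3 = he(f[3], fan[3], fan[3]), b3 = numeric(f[3]),
       Wf = he(2L, D, D), bf = numeric(2))
}

#' Build the (untrained) 15-layer sensor CNN
#'
#' @param config A [model_config()].
#' @return An object of class `sensor_cnn` with elements `config`, `layers`
#'   (the 15-layer architecture summary), seeded initial `weights`, and
#'   `trained = FALSE`.
#' @export
build_cnn <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  weights <- with_seed(config$seed, cnn_init_weights(config))
  structure(list(config = config,
                 layers = cnn_layer_sequence(config),
                 weights = weights,
                 trained = FALSE,
                 training_log = numeric(0)),
            class = "sensor_cnn")
}

#' @export
print.sensor_cnn <- function(x, ...) {
  cat(sprintf("<sensor_cnn> %d-layer scalogram classifier (%s), input %s\n",
              length(x$layers),
              if (x$trained) "trained" else "untrained",
              paste(x$config$input_shape, collapse = "x")))
  cat(paste0("  ", seq_along(x$layers), ". ", x$layers, "\n"), sep = "")
  invisible(x)
}

# images: list of scalogram matrices or an H x W x N array -> H x W x N array
# of pixel intensities scaled to [0, 1]
as_image_array <- function(images, config) {
  hw <- config$input_shape[1:2]
  if (is.list(images)) {
    arr <- array(0, c(hw[1], hw[2], length(images)))
    for (i in seq_along(images)) {
      m <- unclass(images[[i]])
      if (!all(dim(m) == hw)) {
        stop_data("scalogram shape ", paste(dim(m), collapse = "x"),
                  " does not match model input ", paste(hw, collapse = "x"))
      }
      arr[, , i] <- m
    }
  } else if (is.array(images) && length(dim(images)) == 3) {
    if (!all(dim(images)[1:2] == hw)) stop_data("image array shape mismatch")
    arr <- images
  } else if (is.matrix(images)) {
    if (!all(dim(images) == hw)) stop_data("image shape mismatch")
    arr <- array(images, c(hw, 1))
  } else {
    stop_data("images must be a matrix, list of matrices, or 3-d array")
  }
  arr / 255
}

#' Train the sensor CNN on labeled scalograms
#'
#' Minimizes weighted cross-entropy with SGD + momentum; class imbalance is
#' handled by inverse-frequency sample weighting. Training is deterministic
#' under a fixed `config$seed`.
#'
#' @param scalograms List of `scalogram_image` matrices (or an H x W x N
#'   array).
#' @param labels Per-image intake labels (0/1, logical, or factor).
#' @param config A [model_config()].
#' @param verbose Print per-epoch loss.
#' @return A trained `sensor_cnn` with `training_log` (mean loss per epoch).
#' @export
train_sensor_model <- function(scalograms, labels, config = model_config(),
                               verbose = FALSE) {
  y <- as.integer(as.logical(labels))  # 0 = non-intake, 1 = intake
  n <- length(y)
  if (n == 0L) stop_data("empty training set")
  if (length(unique(y)) < 2L) {
    stop_data("training labels contain a single class; need both intake and ",
              "non-intake examples")
  }
  x <- as_image_array(scalograms, config)
  if (dim(x)[3] != n) stop_data("number of images and labels differ")

  model <- build_cnn(config)
  par <- cnn_par_list(config)
  D <- cnn_fc_dim(config)
  # inverse class-frequency weights, mean 1
  cls_w <- n / (2 * tabulate(y + 1L, nbins = 2L))
  sw <- cls_w[y + 1L]

  w <- model$weights
  vel <- lapply(w, function(m) m * 0)
  log_loss <- numeric(config$epochs)
  with_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      ep_loss <- 0
      for (s0 in starts) {
        idx <- ord[s0:min(s0 + config$batch_size - 1L, n)]
        B <- length(idx)
        xb <- x[, , idx, drop = FALSE]
        keep <- 1 - config$dropout_rate
        mask <- matrix(rbinom(D * B, 1, keep) / keep, D, B)
        res <- cnn_batch(xb, y[idx], w, par, mask, sw[idx], TRUE)
        g <- res$grads
        for (nm in names(w)) {
          vel[[nm]] <- config$momentum * vel[[nm]] -
            config$learning_rate * g[[nm]]
          w[[nm]] <- w[[nm]] + vel[[nm]]
        }
        ep_loss <- ep_loss + res$loss * B
      }
      log_loss[ep] <- ep_loss / n
      if (verbose) message(sprintf("epoch %d/%d: loss %.4f",
                                   ep, config$epochs, log_loss[ep]))
    }
  })
  model$weights <- w
  model$trained <- TRUE
  model$training_log <- log_loss
  model
}

#' Sensor confidence score: probability that a scalogram shows intake
#'
#' Returns the softmax probability of the intake class (`Ss`).
#'
#' @param model A `sensor_cnn`.
#' @param scalograms One `scalogram_image`, a list of them, or an array.
#' @param batch_size Forward-pass chunk size.
#' @return Numeric vector of intake probabilities in \[0, 1\].
#' @export
predict_intake <- function(model, scalograms, batch_size = 64) {
  stopifnot(inherits(model, "sensor_cnn"))
  x <- as_image_array(scalograms, model$config)
  n <- dim(x)[3]
  par <- cnn_par_list(model$config)
  D <- cnn_fc_dim(model$config)
  out <- numeric(n)
  for (s0 in seq(1, n, by = batch_size)) {
    idx <- s0:min(s0 + batch_size - 1L, n)
    xb <- x[, , idx, drop = FALSE]
    mask <- matrix(1, D, length(idx))
    res <- cnn_batch(xb, rep(0L, length(idx)), model$weights, par, mask,
                     rep(1, length(idx)), FALSE)
    out[idx] <- res$probs[, 2]
  }
  out
}

#' Class probabilities for scalograms
#' @param model A `sensor_cnn`.
#' @param scalograms Input image(s).
#' @return n x 2 matrix, columns `non_intake` and `intake`, rows sum to 1.
#' @export
predict_intake_proba <- function(model, scalograms) {
  p <- predict_intake(model, scalograms)
  cbind(non_intake = 1 - p, intake = p)
}

#' Save / load a trained sensor model checkpoint
#'
#' The checkpoint is an RDS file; a JSON sidecar `<path>.json` records the
#' architecture and training configuration.
#'
#' @param model A `sensor_cnn`.
#' @param path Checkpoint path.
#' @return `path` (save) or the restored `sensor_cnn` (load).
#' @export
save_sensor_model <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(model$config[setdiff(names(model$config), "lrn_params")],
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_sensor_model
#' @export
load_sensor_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "sensor_cnn"))
  model
}
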