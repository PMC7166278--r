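#' @title Network family and shape arithmetic
#' @description The classifier is a one-dimensional CNN of three identical
#'   blocks — convolution (valid padding, stride 1), batch normalization,
#'   ReLU, dropout, ceil-mode max-pooling (size 2, stride 2) — followed by
#'   two ReLU+dropout fully connected layers and a softmax output layer with
#'   one neuron per class. Eight named configurations M1-M8 span receptive
#'   fields 5/3/3 vs 40/20/10, FC widths 32/16 vs 64/32, and FC dropout 0.2
#'   vs 0.5; the kernel counts 20/40/80 and the conv dropout of 0.2 are
#'   common to all.
#' @name model
NULL

#' Output length of a valid, stride-1 1-D convolution
#'
#' @param input_len incoming sequence length.
#' @param kernel_len kernel (receptive field) length.
#' @return `input_len - kernel_len + 1`.
#' @export
conv_valid_length <- function(input_len, kernel_len) {
  if (kernel_len > input_len) {
    stop_("shape error: kernel length ", kernel_len,
          " exceeds input length ", input_len)
  }
  as.integer(input_len - kernel_len + 1L)
}

#' Output length of ceil-mode max pooling (size 2, stride 2)
#'
#' Odd input lengths are right-padded so the final window holds just the
#' last element; hence 139 pools to 70 and 17 to 9.
#'
#' @param input_len incoming sequence length.
#' @return `ceiling(input_len / 2)`.
#' @export
pool_ceil_length <- function(input_len) {
  if (input_len < 1L) stop_("shape error: non-positive length")
  as.integer(ceiling(input_len / 2))
}

#' Valid 1-D cross-correlation
#'
#' The sliding-dot-product form used by convolutional layers (no kernel
#' flip): `out[t] = sum_a x[t + a - 1] * w[a]`.
#'
#' @param x numeric signal.
#' @param w numeric kernel.
#' @return numeric vector of length `length(x) - length(w) + 1`.
#' @export
cross_correlate <- function(x, w) {
  k <- length(w)
  if (k == 0L) stop_("shape error: empty kernel")
  L <- conv_valid_length(length(x), k)
  out <- numeric(L)
  for (a in seq_len(k)) out <- out + w[a] * x[a:(a + L - 1L)]
  out
}

#' Rectified linear unit, max(0, x)
#' @param x numeric.
#' @export
relu <- function(x) pmax(x, 0)

#' Mini-batch normalization (the normalization step)
#'
#' Per column (channel), subtracts the batch mean and divides by
#' `sqrt(delta + population variance)`; the stabilizer `delta` sits inside
#' the square root so the divisor never falls below `sqrt(delta)`. This is
#' the pure normalization; inside the network it is followed by learnable
#' per-channel scale and shift.
#'
#' @param H numeric vector (one channel) or matrix with one column per
#'   channel; rows are the batch.
#' @param delta small non-negative stabilizer.
#' @return normalized object of the same shape.
#' @export
batch_normalize <- function(H, delta = 1e-3) {
  vec <- is.null(dim(H))
  H <- as.matrix(H)
  if (nrow(H) < 2L) stop_("batch-size error: need at least 2 responses")
  mu <- colMeans(H)
  Hc <- sweep(H, 2L, mu)
  sigma <- sqrt(delta + colMeans(Hc^2))
  out <- sweep(Hc, 2L, sigma, "/")
  if (vec) drop(out) else out
}

#' Numerically stable softmax
#'
#' @param z numeric vector of scores (length >= 2).
#' @return probabilities summing to one; never overflows thanks to
#'   max-subtraction.
#' @export
softmax <- function(z) {
  if (length(z) < 2L) stop_("softmax needs at least two scores")
  e <- exp(z - max(z))
  e / sum(e)
}

#' Specify one convolutional block
#'
#' @param n_kernels number of kernels (output channels).
#' @param receptive_field kernel length.
#' @param dropout_rate dropout fraction in [0, 1).
#' @return a `conv_block_spec` list; conv stride is 1 and pooling is fixed at
#'   size 2 / stride 2 throughout the family.
#' @export
conv_block_spec <- function(n_kernels, receptive_field, dropout_rate = 0.2) {
  stopifnot(is_count(n_kernels), is_count(receptive_field))
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop_("dropout_rate must lie in [0, 1)")
  }
  structure(
    list(n_kernels = as.integer(n_kernels),
         receptive_field = as.integer(receptive_field),
         conv_stride = 1L, dropout_rate = dropout_rate,
         pool_size = 2L, pool_stride = 2L),
    class = "conv_block_spec")
}

#' Specify one fully connected layer
#'
#' @param n_neurons layer width.
#' @param dropout_rate dropout fraction applied after the activation.
#' @param activation "relu" or "softmax" (output layer only).
#' @export
dense_spec <- function(n_neurons, dropout_rate = 0, activation = "relu") {
  stopifnot(is_count(n_neurons))
  activation <- match.arg(activation, c("relu", "softmax"))
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop_("dropout_rate must lie in [0, 1)")
  }
  structure(
    list(n_neurons = as.integer(n_neurons), dropout_rate = dropout_rate,
         activation = activation),
    class = "dense_spec")
}

# The M1-M8 grid: receptive fields, FC widths, FC dropout.
.PRESETS <- list(
  M1 = list(fields = c(5L, 3L, 3L),    fc = c(32L, 16L), fc_dropout = 0.2),
  M2 = list(fields = c(5L, 3L, 3L),    fc = c(32L, 16L), fc_dropout = 0.5),
  M3 = list(fields = c(5L, 3L, 3L),    fc = c(64L, 32L), fc_dropout = 0.2),
  M4 = list(fields = c(5L, 3L, 3L),    fc = c(64L, 32L), fc_dropout = 0.5),
  M5 = list(fields = c(40L, 20L, 10L), fc = c(32L, 16L), fc_dropout = 0.2),
  M6 = list(fields = c(40L, 20L, 10L), fc = c(32L, 16L), fc_dropout = 0.5),
  M7 = list(fields = c(40L, 20L, 10L), fc = c(64L, 32L), fc_dropout = 0.2),
  M8 = list(fields = c(40L, 20L, 10L), fc = c(64L, 32L), fc_dropout = 0.5))

.CONV_KERNELS <- c(20L, 40L, 80L)
.CONV_DROPOUT <- 0.2

#' Names of the eight preset configurations
#' @export
list_model_presets <- function() names(.PRESETS)

#' Build a model configuration
#'
#' Either a named preset (`"M1"`..`"M8"`; `"M7"` is the selected model) or a
#' custom architecture given explicit `blocks` and `fc` specs. Every
#' configuration has exactly three convolutional blocks and three fully
#' connected layers; the output layer always uses softmax with `n_classes`
#' neurons.
#'
#' @param name preset name, or any string for a custom model.
#' @param n_classes number of classes (2, 3 or 5 for the standard tasks).
#' @param blocks list of 3 [conv_block_spec()]s (custom models only).
#' @param fc list of 2 hidden [dense_spec()]s (custom models only).
#' @param input_len input window length (178 for chunked Bonn data).
#' @return an object of class `model_config`.
#' @export
model_config <- function(name = "M7", n_classes = 2L, blocks = NULL,
                         fc = NULL, input_len = CHUNK_LENGTH) {
  stopifnot(is_count(n_classes), n_classes >= 2)
  if (is.null(blocks) && is.null(fc)) {
    p <- .PRESETS[[name]]
    if (is.null(p)) {
      stop_("unknown model '", name, "'; presets: ",
            paste(names(.PRESETS), collapse = ", "))
    }
    blocks <- lapply(1:3, function(i) {
      conv_block_spec(.CONV_KERNELS[i], p$fields[i], .CONV_DROPOUT)
    })
    fc <- lapply(p$fc, dense_spec, dropout_rate = p$fc_dropout,
                 activation = "relu")
  } else {
    if (length(blocks) != 3L || !all(vapply(blocks, inherits, logical(1),
                                            "conv_block_spec"))) {
      stop_("blocks must be a list of exactly 3 conv_block_spec")
    }
    if (length(fc) != 2L || !all(vapply(fc, inherits, logical(1),
                                        "dense_spec"))) {
      stop_("fc must be a list of exactly 2 hidden dense_spec")
    }
  }
  out_layer <- dense_spec(n_classes, dropout_rate = 0, activation = "softmax")
  cfg <- structure(
    list(name = name, blocks = blocks, fc = c(fc, list(out_layer)),
         n_classes = as.integer(n_classes),
         input_len = as.integer(input_len)),
    class = "model_config")
  shape_trace(cfg)  # validates that every receptive field fits
  cfg
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("<model_config> %s: %d-class, input length %d\n",
              x$name, x$n_classes, x$input_len))
  for (i in 1:3) {
    b <- x$blocks[[i]]
    cat(sprintf("  block %d: %d kernels x %d, dropout %.1f, pool 2/2\n",
                i, b$n_kernels, b$receptive_field, b$dropout_rate))
  }
  for (i in 1:3) {
    f <- x$fc[[i]]
    cat(sprintf("  FC%d: %d neurons, %s, dropout %.1f\n",
                i, f$n_neurons, f$activation, f$dropout_rate))
  }
  invisible(x)
}

#' Write/read a model configuration as YAML
#'
#' Presets round-trip by name; custom architectures serialize their full
#' block and FC specification.
#'
#' @param cfg a [model_config()].
#' @param path YAML file path.
#' @export
write_model_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "model_config"))
  yaml::write_yaml(list(
    name = cfg$name, n_classes = cfg$n_classes, input_len = cfg$input_len,
    blocks = lapply(cfg$blocks, function(b) {
      list(n_kernels = b$n_kernels, receptive_field = b$receptive_field,
           dropout_rate = b$dropout_rate)
    }),
    fc = lapply(cfg$fc[1:2], function(f) {
      list(n_neurons = f$n_neurons, dropout_rate = f$dropout_rate)
    })), path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (raw$name %in% names(.PRESETS)) {
    return(model_config(raw$name, n_classes = raw$n_classes,
                        input_len = raw$input_len %||% CHUNK_LENGTH))
  }
  model_config(
    raw$name, n_classes = raw$n_classes,
    blocks = lapply(raw$blocks, function(b) {
      conv_block_spec(b$n_kernels, b$receptive_field, b$dropout_rate)
    }),
    fc = lapply(raw$fc, function(f) {
      dense_spec(f$n_neurons, dropout_rate = f$dropout_rate)
    }),
    input_len = raw$input_len %||% CHUNK_LENGTH)
}

#' Layer-by-layer output shapes of a configuration
#'
#' Applies [conv_valid_length()] and [pool_ceil_length()] through the three
#' blocks. For M7 on 178-sample input the trace is 139x20, 70x20, 51x40,
#' 26x40, 17x80, 9x80, flattening to 720 features.
#'
#' @param cfg a [model_config()].
#' @param input_len input window length; defaults to the config's.
#' @return list with `layers` (data.frame: layer, length, channels) and
#'   `flatten_size`.
#' @export
shape_trace <- function(cfg, input_len = NULL) {
  stopifnot(inherits(cfg, "model_config") || is.list(cfg))
  input_len <- input_len %||% cfg$input_len
  len <- as.integer(input_len)
  rows <- list()
  for (i in 1:3) {
    b <- cfg$blocks[[i]]
    len <- tryCatch(conv_valid_length(len, b$receptive_field),
                    error = function(e) {
                      stop_("shape error in conv", i, ": ",
                            conditionMessage(e))
                    })
    rows[[length(rows) + 1L]] <- data.frame(
      layer = paste0("conv", i), length = len, channels = b$n_kernels)
    len <- pool_ceil_length(len)
    rows[[length(rows) + 1L]] <- data.frame(
      layer = paste0("pool", i), length = len, channels = b$n_kernels)
  }
  layers <- do.call(rbind, rows)
  list(layers = layers,
       flatten_size = as.integer(len * cfg$blocks[[3]]$n_kernels))
}
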