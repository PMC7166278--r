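#' @title Training protocol
#' @description Mini-batch stochastic gradient descent with the Adam
#'   optimizer and categorical cross-entropy loss. The protocol defaults are
#'   learning rate 5e-4, beta1 0.9, beta2 0.999, batch size 100 and 300
#'   epochs; scaled-down epoch counts for quick runs are a configuration
#'   value, never hard-coded. Adam's epsilon (1e-7), the absence of any
#'   learning-rate schedule, early stopping or weight decay, and the use of
#'   the final incomplete mini-batch are package choices the protocol leaves
#'   open.
#' @name training
NULL

#' Training configuration
#'
#' @param learning_rate Adam step size.
#' @param beta1,beta2 Adam moment decay rates.
#' @param epsilon Adam stabilizer.
#' @param batch_size examples per update.
#' @param epochs full passes over the training data (0 = no training).
#' @param seed integer seed driving shuffling and dropout.
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 5e-4, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-7, batch_size = 100L, epochs = 300L,
                         seed = 1L) {
  stopifnot(learning_rate > 0, beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1,
            epsilon > 0, is_count(batch_size))
  if (!(is.numeric(epochs) && length(epochs) == 1L && epochs >= 0 &&
        epochs == floor(epochs))) {
    stop_("epochs must be a non-negative integer")
  }
  structure(
    list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
         epsilon = epsilon, batch_size = as.integer(batch_size),
         epochs = as.integer(epochs), seed = as.integer(seed),
         loss = "categorical cross-entropy"),
    class = "train_config")
}

#' @export
print.train_config <- function(x, ...) {
  cat(sprintf(paste0("<train_config> Adam(lr %g, beta1 %g, beta2 %g, eps %g),",
                     " batch %d, %d epochs, seed %d\n"),
              x$learning_rate, x$beta1, x$beta2, x$epsilon, x$batch_size,
              x$epochs, x$seed))
  invisible(x)
}

.adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       t = 0L)
}

.adam_step <- function(params, grads, opt, tc) {
  opt$t <- opt$t + 1L
  c1 <- 1 - tc$beta1^opt$t
  c2 <- 1 - tc$beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- tc$beta1 * opt$m[[nm]] + (1 - tc$beta1) * g
    opt$v[[nm]] <- tc$beta2 * opt$v[[nm]] + (1 - tc$beta2) * g^2
    step <- tc$learning_rate * (opt$m[[nm]] / c1) /
      (sqrt(opt$v[[nm]] / c2) + tc$epsilon)
    params[[nm]] <- params[[nm]] - step
  }
  list(params = params, opt = opt)
}

#' Train a network on a chunk dataset
#'
#' Runs the full protocol: per-epoch seeded shuffling, mini-batches of
#' `tc$batch_size` (the last, possibly incomplete batch is used), one-hot
#' cross-entropy loss and Adam updates. Deterministic for fixed
#' `(network, ds, tc)` on a given platform. Inputs are expected to be
#' standardized (see [standardize_chunks()]).
#'
#' @param net a [build_network()] result.
#' @param ds a [chunk_dataset()] with labels in `0..n_classes-1`.
#' @param tc a [train_config()].
#' @return list with `net` (trained) and `history` (data.frame: epoch, loss,
#'   accuracy, seconds — training-mode statistics aggregated over batches).
#' @export
train_network <- function(net, ds, tc = train_config()) {
  stopifnot(inherits(net, "cnn1d"), inherits(ds, "chunk_dataset"),
            inherits(tc, "train_config"))
  n <- n_chunks(ds)
  if (n == 0L) stop_("training error: empty dataset")
  k <- net$config$n_classes
  if (any(ds$class_label < 0L | ds$class_label >= k)) {
    stop_("training error: labels out of range 0..", k - 1L)
  }
  X <- ds$x
  y <- ds$class_label
  history <- data.frame(epoch = integer(), loss = numeric(),
                        accuracy = numeric(), seconds = numeric())
  if (tc$epochs == 0L) return(list(net = net, history = history))
  opt <- .adam_init(net$params)
  withr::with_seed(tc$seed, {
    for (epoch in seq_len(tc$epochs)) {
      t0 <- proc.time()[["elapsed"]]
      perm <- sample.int(n)
      loss_sum <- 0
      correct <- 0
      from <- 1L
      while (from <= n) {
        to <- min(from + tc$batch_size - 1L, n)
        idx <- perm[from:to]
        fwd <- .forward_cnn(net, X[idx, , drop = FALSE], training = TRUE)
        net$state <- fwd$state
        loss_sum <- loss_sum + .cross_entropy(fwd$probs, y[idx]) * length(idx)
        pred <- max.col(fwd$probs, ties.method = "first") - 1L
        correct <- correct + sum(pred == y[idx])
        grads <- .backward_cnn(net, fwd, y[idx])
        upd <- .adam_step(net$params, grads, opt, tc)
        net$params <- upd$params
        opt <- upd$opt
        from <- to + 1L
      }
      history <- rbind(history, data.frame(
        epoch = epoch, loss = loss_sum / n, accuracy = correct / n,
        seconds = proc.time()[["elapsed"]] - t0))
    }
  })
  list(net = net, history = history)
}

#' Predict class labels and probabilities for chunks
#'
#' Inference mode: dropout off, batch normalization on running statistics,
#' so identical inputs always give identical outputs. Ties in the
#' probability vector break toward the lowest class index.
#'
#' @param object a trained `cnn1d` network.
#' @param x a [chunk_dataset()] or a numeric matrix of chunks (rows),
#'   standardized identically to the training data.
#' @param batch_size forward-pass batch size (memory knob only).
#' @param ... unused.
#' @return list with `labels` (0-based integer vector) and `probs`
#'   (row-stochastic matrix, one column per class).
#' @export
predict.cnn1d <- function(object, x, batch_size = 500L, ...) {
  if (inherits(x, "chunk_dataset")) x <- x$x
  x <- as.matrix(x)
  if (ncol(x) != object$config$input_len) {
    stop_("shape error: expected ", object$config$input_len,
          " samples per chunk, got ", ncol(x))
  }
  n <- nrow(x)
  probs <- matrix(NA_real_, n, object$config$n_classes)
  from <- 1L
  while (from <= n) {
    to <- min(from + batch_size - 1L, n)
    fwd <- .forward_cnn(object, x[from:to, , drop = FALSE], training = FALSE)
    probs[from:to, ] <- fwd$probs
    from <- to + 1L
  }
  list(labels = max.col(probs, ties.method = "first") - 1L, probs = probs)
}

#' Write a training history to CSV
#' @param history the `history` element of [train_network()]'s result.
#' @param path output CSV path.
#' @export
write_train_history <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}
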