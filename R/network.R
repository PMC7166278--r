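#' @title Network construction and forward/backward passes
#' @description Dense-algebra implementation of the 1-D CNN. Activations are
#'   kept as (batch, length, channels) arrays; convolutions are computed as
#'   a sum over kernel offsets of BLAS matrix products, which matches the
#'   cross-correlation convention of [cross_correlate()]. Batch
#'   normalization carries learnable per-channel scale/shift and running
#'   inference statistics; dropout uses inverted scaling so inference needs
#'   no rescaling. Convolution layers carry no additive bias: the following
#'   batch normalization recentres every channel, so a conv bias would
#'   receive exactly zero gradient.
#' @name network
NULL

.BN_DELTA <- 1e-3     # stabilizer inside the BN square root (assumed value)
.BN_MOMENTUM <- 0.99  # running-statistics momentum (assumed value)

.glorot <- function(fan_in, fan_out, dims) {
  limit <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -limit, limit), dim = dims)
}

#' Build a trainable network from a configuration
#'
#' Weights are drawn from a fan-based (Glorot) uniform distribution with the
#' given seed; batch-norm scale/shift start at 1/0 and running statistics at
#' 0/1.
#'
#' @param cfg a [model_config()].
#' @param seed integer seed for weight initialization.
#' @return an object of class `cnn1d`.
#' @export
build_network <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  trace <- shape_trace(cfg)
  params <- list()
  state <- list()
  withr::with_seed(as.integer(seed), {
    ch_in <- 1L
    for (i in 1:3) {
      b <- cfg$blocks[[i]]
      k <- b$receptive_field
      params[[paste0("conv", i, "_W")]] <-
        .glorot(k * ch_in, k * b$n_kernels, c(k, ch_in, b$n_kernels))
      params[[paste0("bn", i, "_gamma")]] <- rep(1, b$n_kernels)
      params[[paste0("bn", i, "_beta")]] <- rep(0, b$n_kernels)
      state[[paste0("bn", i, "_mean")]] <- rep(0, b$n_kernels)
      state[[paste0("bn", i, "_var")]] <- rep(0, b$n_kernels)
      state[[paste0("bn", i, "_count")]] <- 0L
      ch_in <- b$n_kernels
    }
    n_in <- trace$flatten_size
    for (i in 1:3) {
      f <- cfg$fc[[i]]
      params[[paste0("fc", i, "_W")]] <-
        .glorot(n_in, f$n_neurons, c(n_in, f$n_neurons))
      params[[paste0("fc", i, "_b")]] <- rep(0, f$n_neurons)
      n_in <- f$n_neurons
    }
  })
  structure(
    list(config = cfg, params = params, state = state, trace = trace,
         init_seed = as.integer(seed)),
    class = "cnn1d")
}

#' @export
print.cnn1d <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<cnn1d> %s, %d classes, %d parameters (init seed %d)\n",
              x$config$name, x$config$n_classes, n_par, x$init_seed))
  invisible(x)
}

# ---- layer primitives over (batch, length, channels) arrays ------------

# A convolution layer is one GEMM over the im2col expansion of its input;
# the gather (and the scatter-add adjoint used by the backward pass) is
# compiled code, see src/conv_ops.cpp.

.conv_fwd <- function(A, W) {
  d <- dim(A); n <- d[1]; L <- d[2]; cin <- d[3]
  k <- dim(W)[1]; cout <- dim(W)[3]
  Xcol <- .im2col_gather(A, n, L, cin, k)
  out <- Xcol %*% matrix(W, k * cin, cout)
  dim(out) <- c(n, L - k + 1L, cout)
  list(out = out, Xcol = Xcol, in_dim = d)
}

.conv_bwd <- function(Xcol, in_dim, W, dOut) {
  n <- in_dim[1]; L <- in_dim[2]; cin <- in_dim[3]
  k <- dim(W)[1]; cout <- dim(W)[3]
  dOm <- dOut; dim(dOm) <- c(n * (L - k + 1L), cout)
  dW <- crossprod(Xcol, dOm)
  dim(dW) <- dim(W)
  dXcol <- dOm %*% t(matrix(W, k * cin, cout))
  list(dA = .col2im_scatter(dXcol, n, L, cin, k), dW = dW)
}

# Ceil-mode max pooling, compiled (src/bn_pool_ops.cpp); ties and the odd
# right edge route to the first element of the window.
.pool_fwd <- function(A) {
  d <- dim(A)
  .pool2_fwd_cpp(A, d[1], d[2], d[3])
}

.pool_bwd <- function(dOut, cache) {
  d <- dim(dOut)
  .pool2_bwd_cpp(dOut, cache$mask1, d[1], cache$L, d[3])
}

# rep(v, each = m) expands a per-channel vector to the (m, C) matrix layout;
# cheaper than sweep(), which permutes through aperm().
#
# Running statistics accumulate from zero and are debiased by
# 1 - momentum^count at inference (the same correction Adam applies to its
# moments). Without it the zero initialization dominates for the first few
# hundred updates and inference-time normalization is systematically off in
# short runs.
.bn_fwd <- function(A, gamma, beta, run_mean, run_var, count, training) {
  d <- dim(A); C <- d[3]; m <- d[1] * d[2]
  M <- A; dim(M) <- c(m, C)
  if (training) {
    bn <- .bn_train_cpp(M, gamma, beta, .BN_DELTA)
    out <- bn$out; dim(out) <- d
    return(list(out = out, xhat = bn$xhat, sigma = bn$sigma, dims = d,
                run_mean = .BN_MOMENTUM * run_mean +
                  (1 - .BN_MOMENTUM) * bn$mu,
                run_var = .BN_MOMENTUM * run_var + (1 - .BN_MOMENTUM) * bn$v,
                count = count + 1L))
  } else {
    if (count > 0L) {
      debias <- 1 - .BN_MOMENTUM^count
      mu_hat <- run_mean / debias
      v_hat <- run_var / debias
    } else {
      mu_hat <- rep(0, C)
      v_hat <- rep(1, C)
    }
    sigma <- sqrt(.BN_DELTA + v_hat)
    xhat <- (M - rep(mu_hat, each = m)) * rep(1 / sigma, each = m)
    new_mean <- run_mean
    new_var <- run_var
  }
  out <- xhat * rep(gamma, each = m) + rep(beta, each = m)
  dim(out) <- d
  list(out = out, xhat = xhat, sigma = sigma, dims = d,
       run_mean = new_mean, run_var = new_var, count = count)
}

.bn_bwd <- function(dOut, cache, gamma) {
  d <- cache$dims; m <- d[1] * d[2]
  dM <- dOut; dim(dM) <- c(m, d[3])
  out <- .bn_bwd_cpp(dM, cache$xhat, cache$sigma, gamma)
  dim(out$dA) <- d
  out
}

.dropout_mask <- function(dims, rate) {
  if (rate <= 0) return(NULL)
  array(stats::runif(prod(dims)) >= rate, dim = dims) / (1 - rate)
}

.softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# ---- full passes -------------------------------------------------------

# X: matrix (batch, input_len). Returns probs and, when training, the caches
# needed for the backward pass. Dropout draws come from the current RNG
# stream; callers seed it.
.forward_cnn <- function(net, X, training = FALSE) {
  cfg <- net$config
  p <- net$params
  st <- net$state
  if (ncol(X) != cfg$input_len) {
    stop_("shape error: expected input length ", cfg$input_len,
          ", got ", ncol(X))
  }
  n <- nrow(X)
  A <- X; dim(A) <- c(n, ncol(X), 1L)
  caches <- list()
  shapes <- list()
  for (i in 1:3) {
    b <- cfg$blocks[[i]]
    cv <- .conv_fwd(A, p[[paste0("conv", i, "_W")]])
    cache <- list(Xcol = cv$Xcol, in_dim = cv$in_dim)
    Z <- cv$out
    shapes[[paste0("conv", i)]] <- dim(Z)[2:3]
    bn <- .bn_fwd(Z, p[[paste0("bn", i, "_gamma")]],
                  p[[paste0("bn", i, "_beta")]],
                  st[[paste0("bn", i, "_mean")]],
                  st[[paste0("bn", i, "_var")]],
                  st[[paste0("bn", i, "_count")]], training)
    if (training) {
      st[[paste0("bn", i, "_mean")]] <- bn$run_mean
      st[[paste0("bn", i, "_var")]] <- bn$run_var
      st[[paste0("bn", i, "_count")]] <- bn$count
    }
    H <- bn$out
    relu_mask <- H > 0
    H <- H * relu_mask
    if (training && b$dropout_rate > 0) {
      dm <- .dropout_mask(dim(H), b$dropout_rate)
      H <- H * dm
      cache$drop <- dm
    }
    pl <- .pool_fwd(H)
    shapes[[paste0("pool", i)]] <- dim(pl$out)[2:3]
    cache$bn <- bn[c("xhat", "sigma", "dims")]
    cache$relu_mask <- relu_mask
    cache$pool <- pl[c("mask1", "L")]
    caches[[i]] <- cache
    A <- pl$out
  }
  Hf <- A; dim(Hf) <- c(n, prod(dim(A)[2:3]))
  fc_caches <- list()
  H <- Hf
  for (i in 1:3) {
    f <- cfg$fc[[i]]
    cache <- list(H_in = H)
    Z <- H %*% p[[paste0("fc", i, "_W")]]
    Z <- Z + matrix(p[[paste0("fc", i, "_b")]], n, ncol(Z), byrow = TRUE)
    if (f$activation == "relu") {
      mask <- Z > 0
      H <- Z * mask
      cache$relu_mask <- mask
      if (training && f$dropout_rate > 0) {
        dm <- .dropout_mask(dim(H), f$dropout_rate)
        H <- H * dm
        cache$drop <- dm
      }
    } else {
      H <- .softmax_rows(Z)
    }
    fc_caches[[i]] <- cache
  }
  list(probs = H, caches = caches, fc_caches = fc_caches,
       flat_dim = dim(A)[2:3], shapes = shapes, state = st)
}

# Gradient of mean cross-entropy wrt every parameter. y: 0-based labels.
.backward_cnn <- function(net, fwd, y) {
  cfg <- net$config
  p <- net$params
  n <- nrow(fwd$probs)
  k <- ncol(fwd$probs)
  Y <- matrix(0, n, k)
  Y[cbind(seq_len(n), y + 1L)] <- 1
  grads <- list()
  dH <- (fwd$probs - Y) / n
  for (i in 3:1) {
    cache <- fwd$fc_caches[[i]]
    if (!is.null(cache$drop)) dH <- dH * cache$drop
    if (!is.null(cache$relu_mask)) dH <- dH * cache$relu_mask
    grads[[paste0("fc", i, "_W")]] <- crossprod(cache$H_in, dH)
    grads[[paste0("fc", i, "_b")]] <- colSums(dH)
    dH <- dH %*% t(p[[paste0("fc", i, "_W")]])
  }
  dA <- dH
  dim(dA) <- c(n, fwd$flat_dim[1], fwd$flat_dim[2])
  for (i in 3:1) {
    cache <- fwd$caches[[i]]
    dA <- .pool_bwd(dA, cache$pool)
    if (!is.null(cache$drop)) dA <- dA * cache$drop
    dA <- dA * cache$relu_mask
    bnb <- .bn_bwd(dA, cache$bn, p[[paste0("bn", i, "_gamma")]])
    grads[[paste0("bn", i, "_gamma")]] <- bnb$dgamma
    grads[[paste0("bn", i, "_beta")]] <- bnb$dbeta
    cb <- .conv_bwd(cache$Xcol, cache$in_dim,
                    p[[paste0("conv", i, "_W")]], bnb$dA)
    grads[[paste0("conv", i, "_W")]] <- cb$dW
    dA <- cb$dA
  }
  grads
}

.cross_entropy <- function(probs, y) {
  pt <- probs[cbind(seq_len(nrow(probs)), y + 1L)]
  -mean(log(pmax(pt, 1e-12)))
}

#' Save/load a network as a single-file archive
#'
#' The archive (an RDS file) embeds the model configuration, all learned
#' parameters, the batch-norm running statistics and the initialization
#' seed, so a reloaded network predicts identically.
#'
#' @param net a `cnn1d` network.
#' @param path archive file path.
#' @export
save_network <- function(net, path) {
  stopifnot(inherits(net, "cnn1d"))
  saveRDS(unclass(net), path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  raw <- readRDS(path)
  needed <- c("config", "params", "state", "trace", "init_seed")
  if (!is.list(raw) || !all(needed %in% names(raw))) {
    stop_("not a saved network archive: ", path)
  }
  structure(raw[needed], class = "cnn1d")
}

#' Realized forward-pass shapes of a built network
#'
#' Runs a dummy batch through the network and records the actual
#' (length, channels) of every conv and pool output — the structural
#' counterpart to the arithmetic of [shape_trace()].
#'
#' @param net a [build_network()] result.
#' @return list with `layers` data.frame and `flatten_size`, same shape as
#'   [shape_trace()].
#' @export
realized_shape_trace <- function(net) {
  stopifnot(inherits(net, "cnn1d"))
  X <- matrix(0, 2L, net$config$input_len)
  fwd <- .forward_cnn(net, X, training = FALSE)
  nm <- names(fwd$shapes)
  layers <- data.frame(
    layer = nm,
    length = vapply(fwd$shapes, `[`, integer(1), 1L),
    channels = vapply(fwd$shapes, `[`, integer(1), 2L),
    row.names = NULL)
  list(layers = layers,
       flatten_size = as.integer(prod(fwd$flat_dim)))
}
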