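test_that("layer length arithmetic matches the reference architecture", {
  expect_identical(conv_valid_length(178, 40), 139L)
  expect_identical(conv_valid_length(70, 20), 51L)
  expect_identical(conv_valid_length(55, 1), 55L)
  expect_error(conv_valid_length(10, 11), "shape error")

  expect_identical(pool_ceil_length(139), 70L)
  expect_identical(pool_ceil_length(17), 9L)
  expect_identical(pool_ceil_length(10), 5L)
})

test_that("cross_correlate is the sliding dot product without kernel flip", {
  expect_equal(cross_correlate(c(1, 2, 3, 4), c(1, 1)), c(3, 5, 7))
  x <- rnorm(20)
  expect_equal(cross_correlate(x, 1), x)
  expect_equal(cross_correlate(c(1, 0, 0), c(0, 1)), c(0, 0))
  expect_error(cross_correlate(1:3, numeric(0)), "empty kernel")
})

test_that("batch normalization centers and scales with the delta stabilizer", {
  expect_equal(batch_normalize(c(1, 2, 3), delta = 0),
               c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_true(all(batch_normalize(rep(4, 10), delta = 1e-3) == 0))
  H <- matrix(rnorm(50 * 8, mean = 3, sd = 2), 50, 8)
  Hn <- batch_normalize(H)
  expect_lt(max(abs(colMeans(Hn))), 1e-6)
  # sigma never drops below sqrt(delta): columns only shrink toward zero
  expect_true(all(apply(Hn, 2, sd) <= apply(H, 2, sd)))
  expect_error(batch_normalize(3), "batch-size")
})

test_that("softmax is a stable probability transform", {
  expect_equal(softmax(c(0, 0)), c(0.5, 0.5))
  expect_equal(softmax(c(log(2), 0)), c(2 / 3, 1 / 3))
  big <- softmax(c(1000, 0))
  expect_true(all(is.finite(big)))
  expect_equal(big[1], 1, tolerance = 1e-12)
  for (i in 1:20) {
    p <- softmax(rnorm(sample(2:6, 1), sd = 10))
    expect_lt(abs(sum(p) - 1), 1e-6)
    expect_true(all(p > 0 & p < 1))
  }
})

test_that("shape traces reproduce the reference table and reject misfits", {
  m7 <- shape_trace(model_config("M7", n_classes = 5))
  expect_identical(m7$layers$length, c(139L, 70L, 51L, 26L, 17L, 9L))
  expect_identical(m7$layers$channels, c(20L, 20L, 40L, 40L, 80L, 80L))
  expect_identical(m7$flatten_size, 720L)

  m1 <- shape_trace(model_config("M1", n_classes = 5))
  expect_identical(m1$layers$length, c(174L, 87L, 85L, 43L, 41L, 21L))
  expect_identical(m1$flatten_size, 1680L)

  expect_error(
    model_config("big", n_classes = 2,
                 blocks = list(conv_block_spec(4, 179), conv_block_spec(4, 3),
                               conv_block_spec(4, 3)),
                 fc = list(dense_spec(8), dense_spec(4))),
    "shape error")
})

test_that("preset registry matches the configuration grid", {
  expect_identical(list_model_presets(), paste0("M", 1:8))
  for (nm in list_model_presets()) {
    cfg <- model_config(nm, n_classes = 5)
    expect_identical(vapply(cfg$blocks, `[[`, integer(1), "n_kernels"),
                     c(20L, 40L, 80L))
    expect_identical(vapply(cfg$blocks, `[[`, numeric(1), "dropout_rate"),
                     rep(0.2, 3))
    fields <- vapply(cfg$blocks, `[[`, integer(1), "receptive_field")
    expect_identical(fields,
                     if (nm %in% c("M1", "M2", "M3", "M4")) c(5L, 3L, 3L)
                     else c(40L, 20L, 10L))
    fc_n <- vapply(cfg$fc, `[[`, integer(1), "n_neurons")
    expect_identical(fc_n[1:2],
                     if (nm %in% c("M1", "M2", "M5", "M6")) c(32L, 16L)
                     else c(64L, 32L))
    fc_drop <- vapply(cfg$fc[1:2], `[[`, numeric(1), "dropout_rate")
    expect_identical(fc_drop,
                     rep(if (nm %in% c("M1", "M3", "M5", "M7")) 0.2 else 0.5, 2))
    expect_identical(cfg$fc[[3]]$activation, "softmax")
    expect_identical(cfg$fc[[3]]$n_neurons, 5L)
  }
  expect_error(model_config("M9"), "unknown model")
})

test_that("realized forward shapes equal the arithmetic trace for all presets", {
  for (nm in list_model_presets()) {
    cfg <- model_config(nm, n_classes = 3)
    net <- build_network(cfg, seed = 1)
    expect_identical(realized_shape_trace(net), shape_trace(cfg), label = nm)
  }
})

test_that("the built network emits probability vectors of the right width", {
  for (k in c(2L, 3L, 5L)) {
    net <- build_network(model_config("M7", n_classes = k), seed = 2)
    out <- predict(net, matrix(rnorm(3 * 178), 3))
    expect_identical(dim(out$probs), c(3L, k))
    expect_lt(max(abs(rowSums(out$probs) - 1)), 1e-6)
    expect_true(all(out$probs > 0 & out$probs < 1))
  }
})

test_that("the conv layer agrees with cross_correlate on single channels", {
  cfg <- tiny_cfg()
  net <- build_network(cfg, seed = 3)
  x <- rnorm(178)
  fwd <- eegcnn:::.conv_fwd(array(x, dim = c(1, 178, 1)),
                            net$params$conv1_W)
  for (o in 1:4) {
    expect_equal(fwd$out[1, , o],
                 cross_correlate(x, net$params$conv1_W[, 1, o]))
  }
})

test_that("model configs and trained networks round-trip through files", {
  dir <- withr::local_tempdir()
  cfg_path <- file.path(dir, "m7.yaml")
  write_model_config(model_config("M7", n_classes = 3), cfg_path)
  back <- read_model_config(cfg_path)
  expect_identical(back$name, "M7")
  expect_identical(shape_trace(back), shape_trace(model_config("M7", 3)))

  custom <- tiny_cfg()
  cfg_path2 <- file.path(dir, "tiny.yaml")
  write_model_config(custom, cfg_path2)
  back2 <- read_model_config(cfg_path2)
  expect_identical(shape_trace(back2), shape_trace(custom))
  expect_identical(vapply(back2$blocks, `[[`, integer(1), "n_kernels"),
                   vapply(custom$blocks, `[[`, integer(1), "n_kernels"))

  net <- build_network(tiny_cfg(), seed = 9)
  x <- matrix(rnorm(2 * 178), 2)
  net_path <- file.path(dir, "net.rds")
  save_network(net, net_path)
  reloaded <- load_network(net_path)
  expect_identical(predict(reloaded, x), predict(net, x))
  saveRDS(list(a = 1), net_path)
  expect_error(load_network(net_path), "not a saved network")
})

test_that("inference is deterministic: same chunk, same output", {
  net <- build_network(model_config("M5", n_classes = 2), seed = 4)
  x <- matrix(rnorm(178), 1)
  expect_identical(predict(net, x)$probs, predict(net, x)$probs)
  expect_error(predict(net, matrix(rnorm(100), 1)), "shape error")
})
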