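test_that("confusion matrices count (original, predicted) pairs", {
  cm <- confusion(c(0, 1, 2, 2), c(0, 1, 2, 2), 3)
  expect_true(all(cm == diag(c(1, 1, 2))))
  anti <- confusion(c(0, 1), c(1, 0), 2)
  expect_identical(as.integer(anti), c(0L, 1L, 1L, 0L))
  expect_error(confusion(0:1, 0L, 2), "length")
  expect_error(confusion(c(0, 2), c(0, 1), 2), "out of range")

  ref <- reference_cm()
  expect_identical(unname(rowSums(ref)), rep(2300, 3))
})

test_that("one_vs_rest decomposes the reference matrix correctly", {
  ref <- reference_cm()
  bc <- one_vs_rest(ref, "Normal")
  expect_identical(bc, list(TP = 2263, TN = 4521, FP = 79, FN = 37))
  # grand total conserved for every class of random matrices
  for (i in 1:25) {
    cm <- random_confusion(sample(2:5, 1))
    for (c in seq_len(nrow(cm)) - 1L) {
      expect_identical(do.call(sum, one_vs_rest(cm, c)), as.numeric(sum(cm)))
    }
  }
  dg <- as_confusion(diag(3L) * 5L)
  for (c in 0:2) {
    bc <- one_vs_rest(dg, c)
    expect_identical(bc$FP + bc$FN, 0)
  }
  # two-class symmetry: TP/TN swap between the classes
  cm2 <- random_confusion(2)
  b0 <- one_vs_rest(cm2, 0)
  b1 <- one_vs_rest(cm2, 1)
  expect_identical(b0$TP, b1$TN)
  expect_identical(b0$FP, b1$FN)
})

test_that("binary metrics reproduce the printed per-class rows", {
  normal <- binary_metrics(list(TP = 2263, TN = 4521, FP = 79, FN = 37))
  expect_equal(round_half_up(normal[c("acc", "sen", "spe", "pre", "f1")], 2),
               c(acc = 98.32, sen = 98.39, spe = 98.28, pre = 96.63,
                 f1 = 97.50))
  seizure <- binary_metrics(list(TP = 2216, TN = 4568, FP = 32, FN = 84))
  expect_equal(round_half_up(seizure[c("sen", "spe", "pre", "f1")], 2),
               c(sen = 96.35, spe = 99.30, pre = 98.58, f1 = 97.45))
  even <- binary_metrics(list(TP = 5, TN = 5, FP = 5, FN = 5))
  expect_true(all(even == 50))
  # zero denominators flag NA instead of silently reporting 0
  degenerate <- binary_metrics(list(TP = 0, TN = 10, FP = 0, FN = 0))
  expect_true(is.na(degenerate["pre"]))
  expect_true(is.na(degenerate["sen"]))
  expect_error(binary_metrics(list(TP = 0, TN = 0, FP = 0, FN = 0)), "zero")
})

test_that("macro averaging reproduces every printed overall figure", {
  ref <- reference_cm()
  per <- class_metrics(ref)
  expect_equal(round_half_up(per$acc, 2), c(98.32, 97.54, 98.32))
  expect_equal(round_half_up(per$sen, 2), c(98.39, 96.52, 96.35))
  expect_equal(round_half_up(per$spe, 2), c(98.28, 98.04, 99.30))
  expect_equal(round_half_up(per$pre, 2), c(96.63, 96.10, 98.58))
  expect_equal(round_half_up(per$f1, 2), c(97.50, 96.31, 97.45))
  ov <- overall_metrics(ref)
  expect_equal(round_half_up(ov[c("acc", "sen", "spe", "pre", "f1")], 2),
               c(acc = 98.06, sen = 97.09, spe = 98.54, pre = 97.10,
                 f1 = 97.09))
  expect_true(all(overall_metrics(as_confusion(diag(4L) * 7L)) == 100))
  # undefined per-class metrics propagate with a warning
  holey <- as_confusion(matrix(c(5L, 0L, 5L, 0L), 2))
  expect_warning(ovh <- overall_metrics(holey), "undefined")
  expect_true(is.na(ovh["sen"]))
})

test_that("macro accuracy equals 1 - 2*offdiag/(k*total) on random matrices", {
  withr::with_seed(404, {
    for (i in 1:1000) {
      cm <- random_confusion(sample(2:5, 1))
      k <- nrow(cm)
      macro <- suppressWarnings(overall_metrics(cm))[["acc"]]
      identity_val <- 100 * (1 - 2 * (sum(cm) - sum(diag(cm))) / (k * sum(cm)))
      expect_equal(macro, identity_val, tolerance = 1e-10)
    }
  })
})

test_that("macro and micro coincide where the algebra says they must", {
  ref <- reference_cm()
  # balanced classes: macro sensitivity = micro accuracy (trace/total)
  expect_equal(overall_metrics(ref)[["sen"]], micro_metrics(ref)[["acc"]])
  # two classes: macro accuracy = micro accuracy
  for (i in 1:20) {
    cm2 <- random_confusion(2)
    expect_equal(suppressWarnings(overall_metrics(cm2))[["acc"]],
                 micro_metrics(cm2)[["acc"]])
  }
})

test_that("mean fold accuracy reports the printed two-decimal means", {
  ae <- c(100, 99.57, 99.57, 99.35, 99.35, 99.57, 99.13, 99.57, 99.35, 99.78)
  expect_identical(mean_fold_accuracy(ae), 99.52)
  de <- c(97.61, 98.04, 98.26, 98.04, 97.17, 98.04, 96.52, 97.17, 96.52, 98.91)
  expect_identical(mean_fold_accuracy(de), 97.63)
  expect_identical(mean_fold_accuracy(rep(93.1, 10)), 93.1)
  expect_error(mean_fold_accuracy(ae[1:9]), "expected 10")
})

test_that("the CV harness tests every chunk once and aggregates correctly", {
  ds <- small_ae_dataset()
  plan <- make_folds(ds, n_folds = 10, seed = 3)
  # a degenerate classifier that always answers class 0
  always0 <- function(x_train, y_train, k, seed) function(x_new) {
    rep(0L, nrow(x_new))
  }
  # the empty predicted column makes precision undefined; that warning is the
  # documented behaviour and not under test here
  res <- suppressWarnings(cross_validate(ds, plan = plan, fit_fun = always0))
  expect_true(all(res$fold_accuracy == 50))
  expect_equal(res$mean_accuracy, mean(res$fold_accuracy))
  expect_identical(unname(rowSums(res$confusion)),
                   as.numeric(unname(class_counts(ds))))
  expect_identical(sum(res$confusion), n_chunks(ds))

  # a 1-nearest-neighbour fitter: waveform shape carries the class signal
  one_nn <- function(x_train, y_train, k, seed) function(x_new) {
    d <- -2 * x_new %*% t(x_train) +
      matrix(rowSums(x_train^2), nrow(x_new), nrow(x_train), byrow = TRUE)
    y_train[max.col(-d, ties.method = "first")]
  }
  res2 <- cross_validate(ds, plan = plan, fit_fun = one_nn)
  expect_gt(res2$mean_accuracy, 75)
})

test_that("report writers emit the expected tabular layouts", {
  dir <- withr::local_tempdir()
  ref <- reference_cm()
  p1 <- file.path(dir, "confusion.csv")
  write_confusion_report(ref, p1)
  rep1 <- read.csv(p1)
  expect_identical(nrow(rep1), 5L)  # 3 classes + macro + micro overall rows
  expect_identical(rep1$acc[4], 98.06)
  expect_identical(rep1$spe[4], 98.54)

  fake <- structure(
    list(fold_accuracy = rep(90, 10), fold_accuracy_micro = rep(88, 10),
         n_folds = 10L),
    class = "cv_result")
  p2 <- file.path(dir, "cv.csv")
  write_cv_report(list("A vs. E" = fake), p2)
  rep2 <- read.csv(p2)
  expect_identical(names(rep2), c("task", paste0("K", 1:10), "mean"))
  expect_equal(rep2$mean, 90)
})
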