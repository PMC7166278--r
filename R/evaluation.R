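#' @title Confusion-matrix metrics and cross-validation
#' @description A k-class result is decomposed into k one-vs-rest binary
#'   problems. Per class, accuracy, precision, sensitivity, specificity and
#'   F1 are computed from TP/TN/FP/FN; the headline "overall" figures are
#'   macro averages — unweighted means of the per-class one-vs-rest metrics.
#'   (For a 3x3 matrix with balanced classes this is forced by the reference
#'   result tables: the overall accuracy equals the mean of the per-class
#'   one-vs-rest accuracies, not trace/total.) Micro (pooled-count) variants
#'   are computed alongside and clearly labelled. Metrics with zero
#'   denominators are flagged as `NA`, never silently zero.
#' @name evaluation
NULL

#' Build a confusion matrix from label vectors
#'
#' @param true_labels,pred_labels 0-based integer labels of equal length.
#' @param k number of classes.
#' @param class_names optional class names (default "class0"...).
#' @return an object of class `confusion_matrix`: a k x k integer matrix,
#'   rows = original class, columns = predicted class.
#' @export
confusion <- function(true_labels, pred_labels, k,
                      class_names = NULL) {
  if (length(true_labels) != length(pred_labels)) {
    stop_("true and predicted label vectors differ in length")
  }
  true_labels <- as.integer(true_labels)
  pred_labels <- as.integer(pred_labels)
  if (any(c(true_labels, pred_labels) < 0L) ||
      any(c(true_labels, pred_labels) >= k)) {
    stop_("labels out of range 0..", k - 1L)
  }
  if (is.null(class_names)) class_names <- paste0("class", 0:(k - 1L))
  m <- matrix(0L, k, k, dimnames = list(original = class_names,
                                        predicted = class_names))
  tab <- table(factor(true_labels, levels = 0:(k - 1L)),
               factor(pred_labels, levels = 0:(k - 1L)))
  m[] <- as.integer(tab)
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Wrap an existing count matrix as a confusion matrix
#'
#' For feeding printed or externally computed confusion tables into the
#' metric functions.
#'
#' @param m square nonnegative integer matrix, rows = original class.
#' @param class_names optional class names.
#' @export
as_confusion <- function(m, class_names = NULL) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop_("confusion matrix must be square")
  if (any(m < 0) || any(m != floor(m))) {
    stop_("confusion matrix entries must be nonnegative integers")
  }
  storage.mode(m) <- "integer"
  if (!is.null(class_names)) {
    dimnames(m) <- list(original = class_names, predicted = class_names)
  }
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  y <- x
  attr(y, "class") <- NULL
  print(y)
  invisible(x)
}

#' One-vs-rest binary counts for one class
#'
#' @param cm a confusion matrix.
#' @param class class name or 0-based class index to treat as positive.
#' @return list with `TP`, `TN`, `FP`, `FN` (they sum to the grand total).
#' @export
one_vs_rest <- function(cm, class) {
  k <- nrow(cm)
  if (is.character(class)) {
    i <- match(class, rownames(cm))
    if (is.na(i)) stop_("unknown class '", class, "'")
  } else {
    if (class < 0 || class >= k) stop_("class index out of range 0..", k - 1L)
    i <- as.integer(class) + 1L
  }
  tp <- cm[i, i]
  fn <- sum(cm[i, ]) - tp
  fp <- sum(cm[, i]) - tp
  tn <- sum(cm) - tp - fn - fp
  list(TP = as.numeric(tp), TN = as.numeric(tn),
       FP = as.numeric(fp), FN = as.numeric(fn))
}

#' The five binary metrics from TP/TN/FP/FN
#'
#' Accuracy (TP+TN)/total, precision TP/(TP+FP), sensitivity TP/(TP+FN),
#' specificity TN/(FP+TN) and F1 = 2*Pre*Sen/(Pre+Sen), as percentages in
#' full precision. Zero-denominator cases come back as `NA` rather than 0.
#'
#' @param bc list with TP, TN, FP, FN (see [one_vs_rest()]).
#' @return named numeric vector `c(acc, pre, sen, spe, f1)` in percent.
#' @export
binary_metrics <- function(bc) {
  tot <- bc$TP + bc$TN + bc$FP + bc$FN
  if (tot == 0) stop_("all counts are zero")
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  acc <- ratio(bc$TP + bc$TN, tot)
  pre <- ratio(bc$TP, bc$TP + bc$FP)
  sen <- ratio(bc$TP, bc$TP + bc$FN)
  spe <- ratio(bc$TN, bc$FP + bc$TN)
  f1 <- if (is.na(pre) || is.na(sen) || pre + sen == 0) NA_real_ else
    2 * pre * sen / (pre + sen)
  c(acc = acc, pre = pre, sen = sen, spe = spe, f1 = f1)
}

#' Per-class one-vs-rest metrics of a confusion matrix
#'
#' @param cm a confusion matrix.
#' @return data.frame with one row per class and columns acc, pre, sen,
#'   spe, f1 (percent, full precision).
#' @export
class_metrics <- function(cm) {
  k <- nrow(cm)
  rows <- t(vapply(seq_len(k) - 1L,
                   function(i) binary_metrics(one_vs_rest(cm, i)),
                   numeric(5)))
  out <- as.data.frame(rows)
  out$class <- rownames(cm) %||% paste0("class", seq_len(k) - 1L)
  out[, c("class", "acc", "pre", "sen", "spe", "f1")]
}

#' Macro-averaged overall metrics
#'
#' Unweighted mean over classes of each one-vs-rest metric. An undefined
#' per-class metric propagates as `NA` with a warning.
#'
#' @param cm a confusion matrix (k >= 2).
#' @return named numeric vector `c(acc, pre, sen, spe, f1)` in percent.
#' @export
overall_metrics <- function(cm) {
  if (nrow(cm) < 2L) stop_("need at least two classes")
  per <- class_metrics(cm)
  vals <- as.matrix(per[, c("acc", "pre", "sen", "spe", "f1")])
  if (anyNA(vals)) {
    warning("undefined per-class metric(s); macro averages flagged NA",
            call. = FALSE)
  }
  colMeans(vals)
}

#' Micro (pooled-count) overall metrics
#'
#' Pools TP/TN/FP/FN over the one-vs-rest decompositions before forming the
#' ratios; micro accuracy additionally reports the plain trace/total
#' fraction of correctly classified chunks as `acc`.
#'
#' @param cm a confusion matrix.
#' @return named numeric vector `c(acc, pre, sen, spe, f1)` in percent,
#'   where `acc` is trace/total.
#' @export
micro_metrics <- function(cm) {
  k <- nrow(cm)
  pooled <- list(TP = 0, TN = 0, FP = 0, FN = 0)
  for (i in seq_len(k) - 1L) {
    bc <- one_vs_rest(cm, i)
    pooled <- Map(`+`, pooled, bc)
  }
  out <- binary_metrics(pooled)
  out["acc"] <- 100 * sum(diag(cm)) / sum(cm)
  out
}

#' Mean of per-fold accuracies
#'
#' The headline figure of a 10-fold run: the arithmetic mean of the fold
#' accuracies, reported to two decimals (half away from zero).
#'
#' @param values per-fold accuracy percentages.
#' @param n_folds expected number of folds.
#' @return the mean, rounded to 2 decimals.
#' @export
mean_fold_accuracy <- function(values, n_folds = 10L) {
  if (length(values) != n_folds) {
    stop_("expected ", n_folds, " fold values, got ", length(values))
  }
  round_half_up(mean(values), 2)
}

#' Run stratified k-fold cross-validation
#'
#' For each fold a fresh network is initialized and trained on the other
#' folds, then evaluated on the held-out fold. The per-fold accuracy is the
#' macro overall accuracy of that fold's confusion matrix; the micro
#' (trace/total) variant is reported alongside. Because every chunk is
#' tested exactly once, the fold confusion matrices sum to a single matrix
#' whose row sums are the class sizes.
#'
#' @param ds a standardized [chunk_dataset()].
#' @param cfg a [model_config()]; its `n_classes` must match the dataset.
#' @param tc a [train_config()]; fold-specific seeds are derived from
#'   `tc$seed`.
#' @param plan a [make_folds()] plan covering `ds`.
#' @param fit_fun optional custom fitter `function(x_train, y_train, k,
#'   seed)` returning a predictor `function(x_new) -> 0-based labels`;
#'   replaces the CNN train/predict route (used for harness testing).
#' @param verbose print per-fold progress.
#' @return an object of class `cv_result`: per-fold accuracies (macro and
#'   micro), their mean, the summed confusion matrix, per-class and overall
#'   metrics.
#' @export
cross_validate <- function(ds, cfg = NULL, tc = train_config(),
                           plan = NULL, fit_fun = NULL, verbose = FALSE) {
  stopifnot(inherits(ds, "chunk_dataset"))
  if (is.null(plan)) plan <- make_folds(ds, seed = tc$seed)
  stopifnot(inherits(plan, "fold_plan"))
  if (length(plan$assignment) != n_chunks(ds)) {
    stop_("fold plan does not cover the dataset")
  }
  k <- length(ds$class_names)
  if (is.null(fit_fun)) {
    stopifnot(inherits(cfg, "model_config"))
    if (cfg$n_classes != k) {
      stop_("model has ", cfg$n_classes, " classes but dataset has ", k)
    }
  }
  folds <- sort(unique(plan$assignment))
  fold_acc <- numeric(length(folds))
  fold_acc_micro <- numeric(length(folds))
  total_cm <- matrix(0L, k, k, dimnames = list(original = ds$class_names,
                                               predicted = ds$class_names))
  for (f in seq_along(folds)) {
    test_idx <- which(plan$assignment == folds[f])
    train_idx <- which(plan$assignment != folds[f])
    if (length(unique(ds$class_label[test_idx])) < k) {
      warning("fold ", folds[f], " is missing one or more classes; ",
              "its metrics are unreliable", call. = FALSE)
    }
    if (is.null(fit_fun)) {
      net <- build_network(cfg, seed = derive_seed(tc$seed, 101L, f))
      tc_fold <- tc
      tc_fold$seed <- derive_seed(tc$seed, 211L, f)
      train_ds <- chunk_dataset(ds$x[train_idx, , drop = FALSE],
                                ds$class_label[train_idx], ds$class_names,
                                source_record = ds$source_record[train_idx],
                                chunk_index = ds$chunk_index[train_idx])
      fitted <- train_network(net, train_ds, tc_fold)
      pred <- predict(fitted$net, ds$x[test_idx, , drop = FALSE])$labels
    } else {
      predictor <- fit_fun(ds$x[train_idx, , drop = FALSE],
                           ds$class_label[train_idx], k,
                           derive_seed(tc$seed, 101L, f))
      pred <- predictor(ds$x[test_idx, , drop = FALSE])
    }
    cm <- confusion(ds$class_label[test_idx], pred, k, ds$class_names)
    total_cm <- total_cm + unclass(cm)
    fold_acc[f] <- overall_metrics(cm)[["acc"]]
    fold_acc_micro[f] <- micro_metrics(cm)[["acc"]]
    if (verbose) {
      message(sprintf("fold %d/%d: macro acc %.2f%%", f, length(folds),
                      fold_acc[f]))
    }
  }
  total_cm <- as_confusion(total_cm, ds$class_names)
  structure(
    list(fold_accuracy = fold_acc,
         fold_accuracy_micro = fold_acc_micro,
         mean_accuracy = mean(fold_acc),
         mean_accuracy_micro = mean(fold_acc_micro),
         confusion = total_cm,
         per_class = class_metrics(total_cm),
         overall = overall_metrics(total_cm),
         overall_micro = micro_metrics(total_cm),
         class_names = ds$class_names,
         n_folds = plan$n_folds),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold CV over %d chunks, %d classes\n",
              x$n_folds, sum(x$confusion), length(x$class_names)))
  cat(sprintf("  mean accuracy (macro): %.2f%%  (micro: %.2f%%)\n",
              x$mean_accuracy, x$mean_accuracy_micro))
  cat("  fold accuracies:",
      paste(sprintf("%.2f", x$fold_accuracy), collapse = " "), "\n")
  invisible(x)
}

#' Write a confusion-matrix report (counts + per-class + overall metrics)
#'
#' One CSV row per class with the prediction counts and the five one-vs-rest
#' metrics rounded to 2 decimals, plus `Overall` rows for the macro and
#' micro averages.
#'
#' @param cm a confusion matrix, or a `cv_result` (its summed matrix is
#'   used).
#' @param path output CSV path.
#' @export
write_confusion_report <- function(cm, path) {
  if (inherits(cm, "cv_result")) cm <- cm$confusion
  per <- class_metrics(cm)
  counts <- as.data.frame(unclass(cm))
  names(counts) <- paste0("pred_", rownames(cm))
  body <- cbind(data.frame(original = per$class), counts,
                round_half_up(per[, c("acc", "sen", "spe", "pre", "f1")], 2))
  mk_overall <- function(label, vals) {
    row <- body[1, ]
    row[1, ] <- NA
    row$original <- label
    row[, c("acc", "sen", "spe", "pre", "f1")] <-
      round_half_up(vals[c("acc", "sen", "spe", "pre", "f1")], 2)
    row
  }
  body <- rbind(body,
                mk_overall("Overall (macro)", overall_metrics(cm)),
                mk_overall("Overall (micro)", micro_metrics(cm)))
  utils::write.csv(body, path, row.names = FALSE)
  invisible(path)
}

#' Write a fold-grid report (task x fold accuracies + mean)
#'
#' One row per task: the per-fold accuracy percentages (2 decimals) and
#' their mean, the layout of the standard 10-fold result grids.
#'
#' @param results named list of `cv_result`s, keyed by task name.
#' @param path output CSV path.
#' @param which "macro" or "micro" fold accuracies.
#' @export
write_cv_report <- function(results, path, which = c("macro", "micro")) {
  which <- match.arg(which)
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    acc <- if (which == "macro") r$fold_accuracy else r$fold_accuracy_micro
    row <- as.data.frame(as.list(round_half_up(acc, 2)))
    names(row) <- paste0("K", seq_along(acc))
    cbind(data.frame(task = nm), row,
          data.frame(mean = mean_fold_accuracy(acc, r$n_folds)))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
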