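#' @title Published reference results
#' @description The published Bonn-data results that this implementation
#'   targets: the summed three-class confusion matrix (normal B vs.
#'   preictal D vs. seizure E) and the 10-fold accuracy grid of the selected
#'   model M7 over all 20 set-combination tasks. They serve as reference
#'   inputs for the metric pipeline and as the comparison baseline for runs
#'   on the real corpus; reproducing them requires the real Bonn/UCI data
#'   and the full 300-epoch protocol.
#' @name reference
NULL

#' Published summed confusion matrix for B vs. D vs. E
#'
#' Counts accumulated over the ten test folds (2300 chunks per class).
#'
#' @return a [as_confusion()] matrix with classes Normal, Preictal, Seizure.
#' @export
reference_confusion_bde <- function() {
  as_confusion(rbind(c(2263, 36, 1),
                     c(49, 2220, 31),
                     c(30, 54, 2216)),
               class_names = c("Normal", "Preictal", "Seizure"))
}

.REFERENCE_FOLDS <- list(
  "A vs. E" = c(100, 99.57, 99.57, 99.35, 99.35, 99.57, 99.13, 99.57, 99.35, 99.78),
  "B vs. E" = c(99.78, 99.13, 99.57, 98.91, 99.13, 99.35, 98.70, 98.70, 98.70, 99.13),
  "C vs. E" = c(99.35, 98.04, 98.04, 96.96, 98.26, 97.39, 97.39, 97.83, 98.48, 98.48),
  "D vs. E" = c(97.61, 98.04, 98.26, 98.04, 97.17, 98.04, 96.52, 97.17, 96.52, 98.91),
  "AB vs. E" = c(99.57, 99.13, 99.57, 99.57, 99.57, 99.13, 99.57, 99.13, 99.57, 98.99),
  "AC vs. E" = c(99.28, 98.70, 99.13, 98.84, 99.13, 98.70, 98.99, 99.57, 99.42, 98.55),
  "AD vs. E" = c(98.12, 97.83, 98.41, 98.70, 98.41, 98.41, 98.55, 98.55, 99.13, 98.84),
  "BC vs. E" = c(98.70, 98.41, 97.68, 98.55, 98.55, 98.99, 98.84, 99.28, 99.57, 98.26),
  "BD vs. E" = c(97.39, 97.10, 97.54, 98.84, 98.26, 97.54, 98.41, 97.97, 97.83, 97.39),
  "CD vs. E" = c(97.68, 97.54, 98.41, 97.83, 98.41, 97.25, 98.84, 98.41, 97.97, 97.97),
  "ABC vs. E" = c(99.24, 98.26, 99.24, 98.91, 98.80, 99.02, 98.91, 99.24, 98.91, 98.37),
  "ABD vs. E" = c(98.80, 98.37, 98.80, 98.26, 98.80, 99.35, 98.48, 97.93, 98.15, 98.26),
  "BCD vs. E" = c(98.26, 97.61, 98.59, 98.26, 98.59, 99.24, 98.04, 98.70, 97.93, 98.37),
  "ABCD vs. E" = c(98.96, 99.22, 98.70, 98.52, 98.35, 99.22, 98.78, 98.61, 99.13, 98.09),
  "A vs. C vs. E" = c(96.04, 97.05, 97.00, 97.39, 94.98, 97.58, 97.00, 96.09, 96.81, 97.39),
  "A vs. D vs. E" = c(97.63, 97.10, 97.54, 95.94, 97.00, 96.67, 97.39, 97.87, 96.81, 96.43),
  "B vs. C vs. E" = c(97.63, 97.97, 98.12, 97.68, 98.36, 97.20, 97.87, 99.03, 97.68, 97.58),
  "B vs. D vs. E" = c(98.35, 98.30, 98.07, 97.49, 98.26, 97.97, 97.20, 98.45, 98.45, 98.06),
  "AB vs. CD vs. E" = c(96.70, 97.10, 97.74, 96.43, 96.72, 97.97, 94.96, 97.91, 96.96, 97.25),
  "A vs. B vs. C vs. D vs. E" = c(92.99, 94.37, 94.00, 93.41, 93.36, 92.73, 93.74, 93.25, 93.74, 93.91))

#' Published per-fold accuracies of model M7 on the real corpus
#'
#' @param task optional task name; default returns the full 20-task grid.
#' @return data.frame with task, K1..K10 and the two-decimal mean.
#' @export
reference_cv_accuracies <- function(task = NULL) {
  names_ <- if (is.null(task)) names(.REFERENCE_FOLDS) else find_task(task)$name
  rows <- lapply(names_, function(nm) {
    acc <- .REFERENCE_FOLDS[[nm]]
    row <- as.data.frame(as.list(acc))
    names(row) <- paste0("K", 1:10)
    cbind(data.frame(task = nm), row,
          data.frame(mean = mean_fold_accuracy(acc)))
  })
  do.call(rbind, rows)
}

#' Compare cross-validation results against the published reference
#'
#' @param results named list of `cv_result`s keyed by task name (e.g. from
#'   [run_crossval()] with `task_name = "all"`).
#' @return data.frame with per-task achieved mean accuracy, the reference
#'   mean, and the deviation (achieved - reference) in percentage points.
#' @export
compare_to_reference <- function(results) {
  ref <- reference_cv_accuracies()
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    achieved <- mean_fold_accuracy(r$fold_accuracy, r$n_folds)
    ref_mean <- ref$mean[match(find_task(nm)$name, ref$task)]
    data.frame(task = nm, achieved = achieved, reference = ref_mean,
               deviation = round_half_up(achieved - ref_mean, 2))
  })
  do.call(rbind, rows)
}
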