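#!/usr/bin/env Rscript
# Optional full-protocol experiment on the real Bonn/UCI corpus.
#
# Runs the complete published protocol — M7, 300 epochs, Adam(5e-4), batch
# 100, stratified 10-fold CV — over all 20 set-combination tasks and reports
# the deviation of each mean accuracy from the published reference grid.
# The real corpus is NOT redistributed with this package; point --data at
# either a Bonn-layout directory (subdirectories A..E or Z/O/N/F/S of
# one-integer-per-line .txt files) or the chunked 178-column CSV table.
#
#   Rscript scripts/full_protocol.R --data <path> --out <dir> [--seed N]
#                                   [--epochs N] [--task NAME|all]
#
# Expect a long run: 20 tasks x 10 folds x 300 epochs on CPU.

suppressPackageStartupMessages(library(eegcnn))

args <- commandArgs(trailingOnly = TRUE)
get_opt <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1L && i < length(args)) args[i + 1L] else default
}

data_path <- get_opt("--data")
out_dir <- get_opt("--out", "full_protocol_results")
seed <- as.integer(get_opt("--seed", "1"))
epochs <- as.integer(get_opt("--epochs", "300"))
task <- get_opt("--task", "all")

if (is.null(data_path) || !(dir.exists(data_path) || file.exists(data_path))) {
  message("full_protocol.R: --data must point at the real Bonn corpus ",
          "(directory) or its chunked CSV table; it is not bundled and must ",
          "be downloaded separately.")
  quit(status = 1)
}

results <- run_crossval(data_path, task_name = task, model_name = "M7",
                        seed = seed, epochs = epochs, out_dir = out_dir)
comparison <- compare_to_reference(results)
write.csv(comparison, file.path(out_dir, "reference_comparison.csv"),
          row.names = FALSE)
print(comparison)
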