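# Shared fixtures, all built in code at test time.

# A deliberately small custom architecture for fast training tests.
tiny_cfg <- function(n_classes = 2L) {
  model_config("tiny", n_classes = n_classes,
               blocks = list(conv_block_spec(4L, 9L, 0.2),
                             conv_block_spec(8L, 5L, 0.2),
                             conv_block_spec(8L, 3L, 0.2)),
               fc = list(dense_spec(16L, 0.2), dense_spec(8L, 0.2)))
}

# Write a Bonn-format text file; `values` recycled to `n` lines.
write_bonn_fixture <- function(values, n = 4097L, dir = withr::local_tempdir(),
                               name = "A001.txt",
                               .local_envir = parent.frame()) {
  path <- file.path(dir, name)
  writeLines(format(rep_len(values, n), scientific = FALSE, trim = TRUE), path)
  path
}

# The printed three-class (B vs. D vs. E) summed confusion matrix used as a
# reference input for the metric functions.
reference_cm <- function() {
  as_confusion(rbind(c(2263, 36, 1),
                     c(49, 2220, 31),
                     c(30, 54, 2216)),
               class_names = c("Normal", "Preictal", "Seizure"))
}

# Small standardized two-class synthetic dataset, cached per session.
.fixture_env <- new.env()
small_ae_dataset <- function() {
  if (is.null(.fixture_env$ae)) {
    ds <- simulate_chunk_dataset(46, seed = 7, classes = c("A", "E"))
    .fixture_env$ae <- standardize_chunks(assemble_task(ds, "A vs. E"))
  }
  .fixture_env$ae
}

random_confusion <- function(k, max_count = 20L) {
  repeat {
    m <- matrix(sample.int(max_count + 1L, k * k, replace = TRUE) - 1L, k, k)
    if (sum(m) > 0) return(as_confusion(m))
  }
}
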