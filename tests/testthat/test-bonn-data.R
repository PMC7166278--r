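test_that("read_bonn_segment parses well-formed files and infers set labels", {
  dir <- withr::local_tempdir()
  p0 <- write_bonn_fixture(0L, dir = dir, name = "A001.txt")
  seg <- read_bonn_segment(p0)
  expect_s3_class(seg, "eeg_segment")
  expect_length(seg$samples, 4097L)
  expect_true(all(seg$samples == 0L))
  expect_identical(seg$set_label, "A")
  expect_identical(seg$record_id, "A001")

  p_ramp <- write_bonn_fixture(1:4097, dir = dir, name = "ramp.txt")
  ramp <- read_bonn_segment(p_ramp, set_label = "B")
  expect_identical(ramp$samples[1], 1L)
  expect_identical(ramp$samples[4097], 4097L)

  # set letter from the parent directory, including Z/O/N/F/S synonyms
  zdir <- file.path(dir, "Z")
  dir.create(zdir)
  pz <- write_bonn_fixture(5L, dir = zdir, name = "Z017.txt")
  expect_identical(read_bonn_segment(pz)$set_label, "A")
})

test_that("read_bonn_segment rejects short and non-numeric files", {
  dir <- withr::local_tempdir()
  short <- file.path(dir, "short.txt")
  writeLines(as.character(1:4096), short)
  expect_error(read_bonn_segment(short), "4097")

  bad <- file.path(dir, "bad.txt")
  lines <- as.character(1:4097)
  lines[123] <- "not-a-number"
  writeLines(lines, bad)
  expect_error(read_bonn_segment(bad), "line 123")
})

test_that("segments round-trip through the Bonn writer bit-exactly", {
  seg <- simulate_segment(default_signal_params()$C, seed = 11)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "C001.txt")
  write_bonn_segment(seg, path)
  back <- read_bonn_segment(path, set_label = "C")
  expect_identical(back$samples, seg$samples)
})

test_that("chunk_segment cuts 23 consecutive windows and drops the tail", {
  seg <- eeg_segment(1:4097, set_label = "A", record_id = "r1")
  chunks <- chunk_segment(seg)
  expect_length(chunks, 23L)
  expect_true(all(vapply(chunks, function(c) length(c$values), numeric(1)) == 178))
  expect_identical(vapply(chunks, `[[`, integer(1), "chunk_index"), 0:22)
  # concatenation reproduces the first 23*178 = 4094 samples exactly
  expect_identical(unlist(lapply(chunks, `[[`, "values")), as.numeric(1:4094))

  one <- chunk_segment(1:178, n_chunks = 1)
  expect_identical(one[[1]]$values, as.numeric(1:178))

  two <- chunk_segment(1:400, chunk_len = 178, n_chunks = 2)
  expect_length(two, 2L)
  expect_identical(two[[2]]$values[178], 356)

  expect_error(chunk_segment(1:400, chunk_len = 178, n_chunks = 3), "size error")
})

test_that("load_chunk_table reads 178-sample rows with tolerant framing", {
  dir <- withr::local_tempdir()
  base <- matrix(rep(1:178, 5), nrow = 5, byrow = TRUE) + 0:4
  path <- file.path(dir, "chunks.csv")
  write.table(cbind(base, 1:5), path, sep = ",", row.names = FALSE,
              col.names = FALSE)
  ds <- suppressMessages(load_chunk_table(path))
  expect_s3_class(ds, "chunk_dataset")
  expect_identical(ds$class_names, c("A", "B", "C", "D", "E"))
  expect_identical(unname(class_counts(ds)), rep(1L, 5))
  # default label map: file label 1 -> set E, 5 -> set A
  expect_identical(ds$class_names[ds$class_label[1] + 1L], "E")
  expect_identical(ds$class_names[ds$class_label[5] + 1L], "A")

  # header line and a leading row-id column are both tolerated
  path2 <- file.path(dir, "with_header.csv")
  hdr <- c("id", paste0("X", 1:178), "y")
  writeLines(c(paste(hdr, collapse = ","),
               paste(c("r1", 1:178, 2), collapse = ",")), path2)
  ds2 <- suppressMessages(load_chunk_table(path2))
  expect_identical(n_chunks(ds2), 1L)
  expect_identical(ds2$class_names[ds2$class_label + 1L], "D")
  expect_identical(ds2$source_record, "r1")

  # wrong column count and unmapped labels are format errors
  path3 <- file.path(dir, "short_row.csv")
  write.table(cbind(matrix(1:177, nrow = 1), 1), path3, sep = ",",
              row.names = FALSE, col.names = FALSE)
  expect_error(suppressMessages(load_chunk_table(path3)), "format error")
  path4 <- file.path(dir, "bad_label.csv")
  write.table(cbind(matrix(1:178, nrow = 1), 9), path4, sep = ",",
              row.names = FALSE, col.names = FALSE)
  expect_error(suppressMessages(load_chunk_table(path4)), "unmapped")
})

test_that("chunk tables round-trip through the writer", {
  ds <- simulate_chunk_dataset(23, seed = 3, classes = c("A", "E"))
  path <- file.path(withr::local_tempdir(), "rt.csv")
  write_chunk_table(ds, path)
  back <- suppressMessages(load_chunk_table(path))
  expect_equal(back$x, ds$x, ignore_attr = TRUE)
  expect_identical(back$class_label, ds$class_label)
  expect_identical(back$class_names, ds$class_names)
})

test_that("standardization gives zero mean and unit population sd per chunk", {
  expect_equal(standardize_chunk(c(0, 2)), c(-1, 1))
  z <- standardize_chunk(rnorm(178, mean = 40, sd = 9))
  expect_lt(abs(mean(z)), 1e-6)
  expect_lt(abs(sqrt(mean((z - mean(z))^2)) - 1), 1e-6)
  expect_error(standardize_chunk(rep(5, 178)), "degenerate")

  ds <- simulate_chunk_dataset(23, seed = 5, classes = c("A", "E"))
  std <- standardize_chunks(ds)
  expect_lt(max(abs(rowMeans(std$x))), 1e-6)
  expect_lt(max(abs(sqrt(rowMeans(std$x^2)) - 1)), 1e-6)
  # idempotent
  twice <- standardize_chunks(std)
  expect_lt(max(abs(twice$x - std$x)), 1e-6)
})

test_that("dataset-level standardization can reuse training-fold statistics", {
  ds <- simulate_chunk_dataset(23, seed = 5, classes = c("A", "E"))
  std <- standardize_chunks(ds, method = "dataset")
  st <- attr(std, "standardize")
  expect_identical(st$method, "dataset")
  other <- standardize_chunks(ds, method = "dataset",
                              stats = list(mean = st$mean, sd = st$sd))
  expect_equal(other$x, std$x)
})

test_that("assemble_task relabels by group in task order without resampling", {
  ds <- simulate_chunk_dataset(23, seed = 9)
  ae <- assemble_task(ds, "A vs. E")
  expect_identical(unname(class_counts(ae)), c(23L, 23L))
  expect_identical(ae$class_names, c("A", "E"))

  abe <- assemble_task(ds, "AB vs. E")
  expect_identical(unname(class_counts(abe)), c(46L, 23L))

  bde <- assemble_task(ds, "B vs. D vs. E")
  expect_identical(bde$class_names, c("B", "D", "E"))
  five <- assemble_task(ds, "A vs. B vs. C vs. D vs. E")
  expect_identical(unname(class_counts(five)), rep(23L, 5))
  expect_identical(n_chunks(five), 115L)

  only_ae <- assemble_task(ds, "A vs. E")
  expect_error(assemble_task(only_ae, "B vs. E"), "assembly error")
})

test_that("fold plans are stratified partitions, deterministic in the seed", {
  ds <- simulate_chunk_dataset(46, seed = 2, classes = c("A", "E"))
  plan <- make_folds(ds, n_folds = 10, seed = 123)
  expect_identical(sort(unique(plan$assignment)), 0:9)
  expect_length(plan$assignment, n_chunks(ds))
  # per-class fold sizes differ by at most one (46 = 4 folds of 5, 6 of 4... )
  for (k in 0:1) {
    sizes <- table(plan$assignment[ds$class_label == k])
    expect_lte(max(sizes) - min(sizes), 1)
  }
  expect_identical(make_folds(ds, n_folds = 10, seed = 123)$assignment,
                   plan$assignment)
  expect_false(identical(make_folds(ds, n_folds = 10, seed = 124)$assignment,
                         plan$assignment))

  # 20 chunks of one class into 10 folds -> exactly 2 per fold
  small <- chunk_dataset(matrix(rnorm(20 * 178), 20), rep(0L, 20), "A")
  p2 <- make_folds(small, n_folds = 10, seed = 1)
  expect_true(all(table(p2$assignment) == 2))

  tiny <- chunk_dataset(matrix(rnorm(5 * 178), 5), rep(0L, 5), "A")
  expect_error(make_folds(tiny, n_folds = 10, seed = 1), "stratification")
})

test_that("record-level folds keep whole recordings together", {
  ds <- simulate_chunk_dataset(10 * 23, seed = 4, classes = c("A", "E"))
  plan <- make_folds(ds, n_folds = 10, seed = 5, level = "record")
  tab <- fold_table(ds, plan)
  per_record <- tapply(tab$fold, tab$source_record, function(f) length(unique(f)))
  expect_true(all(per_record == 1))
})

test_that("the task registry holds exactly the 20 standard combinations", {
  tasks <- list_tasks()
  expect_length(tasks, 20L)
  ncls <- vapply(tasks, `[[`, integer(1), "n_classes")
  expect_identical(as.integer(table(ncls)[c("2", "3", "5")]), c(14L, 5L, 1L))
  # every task includes the seizure set E
  expect_true(all(vapply(tasks, function(t) "E" %in% unlist(t$groups),
                         logical(1))))
  ae <- find_task("A vs. E")
  expect_identical(ae$groups, list("A", "E"))
  expect_error(find_task("A vs. Q"), "unknown")
  expect_error(task_spec("AB vs. BE"), "disjoint")
})
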