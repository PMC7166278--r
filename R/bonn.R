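#' @title Bonn EEG data handling
#' @description Readers, writers and dataset assembly for the Bonn University
#'   EEG corpus layout (five sets A-E, 100 single-channel recordings each, one
#'   integer sample per line, 4097 samples at 173.61 Hz) and for its chunked
#'   tabular redistribution (rows of 178 samples plus a class label).
#' @name bonn
NULL

#' Sampling rate of the Bonn recordings, in Hz
#' @export
BONN_SAMPLING_RATE <- 173.61

#' Number of samples per Bonn recording
#' @export
BONN_SEGMENT_LENGTH <- 4097L

#' Samples per chunk in the tabular redistribution (1 second of signal)
#' @export
CHUNK_LENGTH <- 178L

#' Chunks cut from one recording (the trailing 3 samples are discarded)
#' @export
CHUNKS_PER_SEGMENT <- 23L

.SET_LETTERS <- c("A", "B", "C", "D", "E")
.SET_SYNONYMS <- c(Z = "A", O = "B", N = "C", F = "D", S = "E")

#' Canonicalize a Bonn set label
#'
#' The five sets are distributed both as A-E and under their original
#' directory names Z, O, N, F, S; both spellings are accepted everywhere.
#'
#' @param x a single letter (case-insensitive).
#' @return one of "A".."E".
#' @export
normalize_set_label <- function(x) {
  if (length(x) != 1L || is.na(x)) stop_("set label must be a single letter")
  u <- toupper(trimws(as.character(x)))
  if (u %in% names(.SET_SYNONYMS)) u <- unname(.SET_SYNONYMS[u])
  if (!u %in% .SET_LETTERS) {
    stop_("unknown set label '", x, "' (expected A-E or Z/O/N/F/S)")
  }
  u
}

#' Construct an EEG segment
#'
#' @param samples integer vector of ADC counts, length 4097.
#' @param set_label set letter (A-E or a Z/O/N/F/S synonym), or NA.
#' @param record_id identifier string for the recording.
#' @param sampling_rate sampling rate in Hz; fixed at 173.61 for Bonn data.
#' @return an object of class `eeg_segment`.
#' @export
eeg_segment <- function(samples, set_label = NA, record_id = "record",
                        sampling_rate = BONN_SAMPLING_RATE) {
  samples <- as.integer(samples)
  if (length(samples) != BONN_SEGMENT_LENGTH) {
    stop_("an EEG segment must hold exactly ", BONN_SEGMENT_LENGTH,
          " samples, got ", length(samples))
  }
  if (anyNA(samples)) stop_("segment contains missing samples")
  if (!is.na(set_label)) set_label <- normalize_set_label(set_label)
  structure(
    list(samples = samples, set_label = set_label,
         record_id = as.character(record_id), sampling_rate = sampling_rate),
    class = "eeg_segment")
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment> set %s, record %s: %d samples @ %.2f Hz\n",
              ifelse(is.na(x$set_label), "?", x$set_label), x$record_id,
              length(x$samples), x$sampling_rate))
  invisible(x)
}

.infer_set_label <- function(path) {
  dir_letter <- toupper(basename(dirname(normalizePath(path, mustWork = FALSE))))
  if (dir_letter %in% c(.SET_LETTERS, names(.SET_SYNONYMS))) {
    return(normalize_set_label(dir_letter))
  }
  first <- toupper(substr(basename(path), 1L, 1L))
  if (first %in% c(.SET_LETTERS, names(.SET_SYNONYMS))) {
    return(normalize_set_label(first))
  }
  NA_character_
}

#' Read one Bonn-format recording
#'
#' Bonn files are plain text with one integer ADC sample per line. The first
#' 4097 parseable lines are kept. The set letter is taken from `set_label`,
#' else inferred from the parent directory name or the file-name prefix
#' (accepting the Z/O/N/F/S synonyms).
#'
#' @param path path to a `.txt`/`.TXT` file.
#' @param set_label optional set letter override.
#' @param record_id optional record id; defaults to the file name.
#' @return an [eeg_segment()].
#' @export
read_bonn_segment <- function(path, set_label = NULL, record_id = NULL) {
  if (!file.exists(path)) stop_("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  # drop trailing blank lines only; blanks inside the data are an error
  while (length(lines) && !nzchar(trimws(lines[length(lines)]))) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) < BONN_SEGMENT_LENGTH) {
    stop_("parse error in ", path, ": expected at least ",
          BONN_SEGMENT_LENGTH, " sample lines, found ", length(lines))
  }
  lines <- lines[seq_len(BONN_SEGMENT_LENGTH)]
  vals <- suppressWarnings(as.numeric(trimws(lines)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    stop_("parse error in ", path, ": line ", bad,
          " is not numeric: '", lines[bad], "'")
  }
  if (is.null(set_label)) set_label <- .infer_set_label(path)
  if (is.null(record_id)) {
    record_id <- sub("\\.[^.]*$", "", basename(path))
  }
  eeg_segment(vals, set_label = set_label, record_id = record_id)
}

#' Write one recording in Bonn format
#' @param seg an [eeg_segment()].
#' @param path output file path.
#' @export
write_bonn_segment <- function(seg, path) {
  stopifnot(inherits(seg, "eeg_segment"))
  writeLines(format(seg$samples, scientific = FALSE, trim = TRUE), path)
  invisible(path)
}

#' Read a whole Bonn set directory
#'
#' @param dir directory holding the `.txt` files of one set.
#' @param set_label optional set letter; defaults to the directory name.
#' @return list of [eeg_segment()]s, in file-name order.
#' @export
read_bonn_set <- function(dir, set_label = NULL) {
  if (!dir.exists(dir)) stop_("no such directory: ", dir)
  if (is.null(set_label)) set_label <- normalize_set_label(basename(dir))
  files <- sort(list.files(dir, pattern = "\\.[tT][xX][tT]$", full.names = TRUE))
  if (!length(files)) stop_("no .txt files in ", dir)
  lapply(files, read_bonn_segment, set_label = set_label)
}

#' Write a list of segments as one Bonn set directory
#' @param segments list of [eeg_segment()]s sharing a set label.
#' @param dir output directory (created if needed).
#' @export
write_bonn_set <- function(segments, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labels <- vapply(segments, function(s) s$set_label, character(1))
  for (i in seq_along(segments)) {
    fn <- sprintf("%s%03d.txt", labels[i], i)
    write_bonn_segment(segments[[i]], file.path(dir, fn))
  }
  invisible(dir)
}

#' Cut a recording into consecutive non-overlapping chunks
#'
#' A 4097-sample recording yields 23 chunks of 178 samples; the trailing
#' 3 samples are discarded, mirroring the chunked redistribution of the
#' corpus. Chunk indices are 0-based.
#'
#' @param seg an [eeg_segment()] or a plain numeric vector.
#' @param chunk_len samples per chunk.
#' @param n_chunks number of chunks to cut.
#' @return list of `eeg_chunk` objects (fields `values`, `class_label`,
#'   `source_record`, `chunk_index`).
#' @export
chunk_segment <- function(seg, chunk_len = CHUNK_LENGTH,
                          n_chunks = CHUNKS_PER_SEGMENT) {
  if (inherits(seg, "eeg_segment")) {
    samples <- seg$samples
    rec <- seg$record_id
  } else if (is.numeric(seg)) {
    samples <- seg
    rec <- "vector"
  } else {
    stop_("seg must be an eeg_segment or a numeric vector")
  }
  if (!is_count(chunk_len) || !is_count(n_chunks)) {
    stop_("chunk_len and n_chunks must be positive integers")
  }
  if (chunk_len * n_chunks > length(samples)) {
    stop_("size error: ", n_chunks, " chunks of ", chunk_len,
          " samples need ", chunk_len * n_chunks,
          " samples but the segment has ", length(samples))
  }
  lapply(seq_len(n_chunks), function(i) {
    from <- (i - 1L) * chunk_len + 1L
    structure(
      list(values = as.numeric(samples[from:(from + chunk_len - 1L)]),
           class_label = NA_integer_, source_record = rec,
           chunk_index = i - 1L),
      class = "eeg_chunk")
  })
}

#' Construct a chunk dataset
#'
#' The unit of classification: a matrix of fixed-length signal windows with a
#' 0-based class label per row indexing `class_names`.
#'
#' @param x numeric matrix, one chunk per row.
#' @param class_label integer vector of 0-based labels, one per row.
#' @param class_names ordered character vector of class names.
#' @param source_record optional per-chunk recording ids.
#' @param chunk_index optional per-chunk 0-based position within its recording.
#' @return an object of class `chunk_dataset`.
#' @export
chunk_dataset <- function(x, class_label, class_names,
                          source_record = NULL, chunk_index = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  class_label <- as.integer(class_label)
  if (length(class_label) != n) stop_("one label per chunk required")
  if (anyNA(class_label)) stop_("missing class labels")
  k <- length(class_names)
  if (any(class_label < 0L | class_label >= k)) {
    stop_("class labels must lie in 0..", k - 1L)
  }
  if (is.null(source_record)) source_record <- sprintf("chunk%06d", seq_len(n))
  if (is.null(chunk_index)) chunk_index <- rep(NA_integer_, n)
  structure(
    list(x = x, class_label = class_label,
         class_names = as.character(class_names),
         source_record = as.character(source_record),
         chunk_index = as.integer(chunk_index)),
    class = "chunk_dataset")
}

#' @export
print.chunk_dataset <- function(x, ...) {
  cat(sprintf("<chunk_dataset> %d chunks x %d samples, %d classes\n",
              nrow(x$x), ncol(x$x), length(x$class_names)))
  cnt <- class_counts(x)
  cat(paste(sprintf("  %s: %d", names(cnt), cnt), collapse = "\n"), "\n")
  invisible(x)
}

#' Chunks per class of a dataset
#' @param ds a [chunk_dataset()].
#' @return named integer vector in `class_names` order.
#' @export
class_counts <- function(ds) {
  stopifnot(inherits(ds, "chunk_dataset"))
  cnt <- tabulate(ds$class_label + 1L, nbins = length(ds$class_names))
  names(cnt) <- ds$class_names
  cnt
}

#' Number of chunks in a dataset
#' @param ds a [chunk_dataset()].
#' @export
n_chunks <- function(ds) nrow(ds$x)

#' Chunk a collection of segments into a set-labelled dataset
#'
#' @param segments list of [eeg_segment()]s with set labels, possibly from
#'   several sets.
#' @return a [chunk_dataset()] whose classes are the set letters present,
#'   in A..E order.
#' @export
chunk_segments <- function(segments) {
  sets <- vapply(segments, function(s) s$set_label, character(1))
  if (anyNA(sets)) stop_("all segments need a set label")
  class_names <- .SET_LETTERS[.SET_LETTERS %in% sets]
  chunks <- unlist(lapply(segments, chunk_segment), recursive = FALSE)
  x <- do.call(rbind, lapply(chunks, `[[`, "values"))
  rec <- vapply(chunks, `[[`, character(1), "source_record")
  idx <- vapply(chunks, `[[`, integer(1), "chunk_index")
  seg_of_chunk <- rep(seq_along(segments), each = CHUNKS_PER_SEGMENT)
  labels <- match(sets[seg_of_chunk], class_names) - 1L
  chunk_dataset(x, labels, class_names, source_record = rec, chunk_index = idx)
}

#' Load a Bonn-layout corpus directory
#'
#' Expects one subdirectory per set, named A-E or Z/O/N/F/S.
#'
#' @param root corpus root directory.
#' @param sets set letters to load (default: all present).
#' @return a set-labelled [chunk_dataset()].
#' @export
load_bonn_dir <- function(root, sets = NULL) {
  if (!dir.exists(root)) stop_("no such directory: ", root)
  subdirs <- list.dirs(root, recursive = FALSE)
  letter <- vapply(subdirs, function(d) {
    b <- toupper(basename(d))
    if (b %in% c(.SET_LETTERS, names(.SET_SYNONYMS))) normalize_set_label(b)
    else NA_character_
  }, character(1))
  keep <- !is.na(letter)
  subdirs <- subdirs[keep]; letter <- letter[keep]
  if (!is.null(sets)) {
    sets <- vapply(sets, normalize_set_label, character(1))
    miss <- setdiff(sets, letter)
    if (length(miss)) stop_("set(s) missing from ", root, ": ",
                            paste(miss, collapse = ", "))
    subdirs <- subdirs[letter %in% sets]; letter <- letter[letter %in% sets]
  }
  if (!length(subdirs)) stop_("no set subdirectories under ", root)
  ord <- order(match(letter, .SET_LETTERS))
  segments <- unlist(lapply(ord, function(i) {
    read_bonn_set(subdirs[i], set_label = letter[i])
  }), recursive = FALSE)
  chunk_segments(segments)
}

#' Default mapping from tabular labels to set letters
#'
#' The chunked redistribution encodes its classes as integers 1-5; the
#' original source does not document the correspondence, so the mapping used
#' here (1 = seizure set E down to 5 = set A) is a configurable default and is
#' echoed whenever a table is read.
#' @export
DEFAULT_LABEL_MAP <- c("1" = "E", "2" = "D", "3" = "C", "4" = "B", "5" = "A")

#' Load a chunked EEG table
#'
#' Comma-separated text with 178 numeric sample columns followed by one label
#' column; an optional header line and an optional leading row-id column are
#' tolerated.
#'
#' @param path path to the CSV file.
#' @param label_map named character vector mapping file labels to set letters;
#'   see [DEFAULT_LABEL_MAP].
#' @param quiet suppress the class-composition message.
#' @return a set-labelled [chunk_dataset()] with the applied `label_map`
#'   attached as attribute `"label_map"`.
#' @export
load_chunk_table <- function(path, label_map = DEFAULT_LABEL_MAP,
                             quiet = FALSE) {
  if (!file.exists(path)) stop_("no such file: ", path)
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         strip.white = TRUE)
  if (!ncol(raw) %in% c(CHUNK_LENGTH + 1L, CHUNK_LENGTH + 2L)) {
    stop_("format error: expected ", CHUNK_LENGTH,
          " sample columns plus a label (and optionally a row id), got ",
          ncol(raw), " columns")
  }
  has_id <- ncol(raw) == CHUNK_LENGTH + 2L
  feat_cols <- seq_len(CHUNK_LENGTH) + as.integer(has_id)
  # header line: its feature fields do not parse as numbers
  first_numeric <- suppressWarnings(as.numeric(unlist(raw[1L, feat_cols])))
  if (anyNA(first_numeric)) raw <- raw[-1L, , drop = FALSE]
  if (!nrow(raw)) stop_("format error: no data rows in ", path)
  feats <- suppressWarnings(
    matrix(as.numeric(as.matrix(raw[, feat_cols])), nrow = nrow(raw)))
  if (anyNA(feats)) {
    bad <- which(rowSums(is.na(feats)) > 0)[1L]
    stop_("format error: non-numeric sample value in data row ", bad)
  }
  labs_raw <- trimws(raw[[ncol(raw)]])
  unmapped <- setdiff(unique(labs_raw), names(label_map))
  if (length(unmapped)) {
    stop_("format error: unmapped label(s): ", paste(unmapped, collapse = ", "))
  }
  sets <- unname(label_map[labs_raw])
  class_names <- .SET_LETTERS[.SET_LETTERS %in% sets]
  ids <- if (has_id) raw[[1L]] else sprintf("row%06d", seq_len(nrow(raw)))
  ds <- chunk_dataset(feats, match(sets, class_names) - 1L, class_names,
                      source_record = ids)
  if (!quiet) {
    message("loaded ", nrow(feats), " chunks; label map [",
            paste(names(label_map), label_map, sep = "->", collapse = " "),
            "]; composition: ",
            paste(names(class_counts(ds)), class_counts(ds),
                  sep = "=", collapse = " "))
  }
  attr(ds, "label_map") <- label_map
  ds
}

#' Write a chunk dataset as a chunked EEG table
#'
#' Inverse of [load_chunk_table()]: the set letter of each chunk is encoded
#' through the reverse of `label_map`. Only datasets whose classes are set
#' letters can be written this way.
#'
#' @param ds a set-labelled [chunk_dataset()].
#' @param path output CSV path.
#' @param label_map forward map as in [load_chunk_table()].
#' @export
write_chunk_table <- function(ds, path, label_map = DEFAULT_LABEL_MAP) {
  stopifnot(inherits(ds, "chunk_dataset"))
  sets <- ds$class_names[ds$class_label + 1L]
  rev_map <- stats::setNames(names(label_map), label_map)
  if (any(!sets %in% names(rev_map))) {
    stop_("dataset classes are not set letters covered by label_map")
  }
  out <- cbind(ds$x, as.numeric(rev_map[sets]))
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Standardize one chunk to zero mean, unit variance
#'
#' Uses the population (divide-by-m) standard deviation. A constant chunk has
#' zero variance and is rejected as degenerate.
#'
#' @param x numeric vector.
#' @return standardized numeric vector.
#' @export
standardize_chunk <- function(x) {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s < 1e-12) stop_("degenerate input: constant chunk has zero variance")
  (x - m) / s
}

#' Standardize every chunk of a dataset
#'
#' `method = "chunk"` (the default) standardizes each window independently,
#' which cannot leak information between cross-validation folds.
#' `method = "dataset"` applies a single global mean/sd, either computed from
#' `ds` or supplied via `stats` (e.g. fitted on training folds only).
#'
#' @param ds a [chunk_dataset()].
#' @param method "chunk" or "dataset".
#' @param stats optional `list(mean =, sd =)` for `method = "dataset"`.
#' @return the dataset with standardized `x`; the applied statistics are kept
#'   in attribute `"standardize"`.
#' @export
standardize_chunks <- function(ds, method = c("chunk", "dataset"),
                               stats = NULL) {
  stopifnot(inherits(ds, "chunk_dataset"))
  method <- match.arg(method)
  x <- ds$x
  if (method == "chunk") {
    m <- rowMeans(x)
    xc <- x - m
    s <- sqrt(rowMeans(xc^2))
    if (any(s < 1e-12)) {
      stop_("degenerate input: constant chunk(s) at row(s) ",
            paste(utils::head(which(s < 1e-12), 5), collapse = ", "))
    }
    ds$x <- xc / s
    attr(ds, "standardize") <- list(method = "chunk")
  } else {
    if (is.null(stats)) {
      mu <- mean(x)
      sd_ <- sqrt(mean((x - mu)^2))
      stats <- list(mean = mu, sd = sd_)
    }
    if (stats$sd < 1e-12) stop_("degenerate input: zero global variance")
    ds$x <- (x - stats$mean) / stats$sd
    attr(ds, "standardize") <- c(list(method = "dataset"), stats)
  }
  ds
}

# ---- classification tasks ----------------------------------------------

#' Define a set-combination classification task
#'
#' A task groups the five sets into 2, 3 or 5 disjoint classes; the class
#' order follows the name left to right, so in "AB vs. CD vs. E" the class
#' labels are AB = 0, CD = 1, E = 2.
#'
#' @param name task name, groups of set letters separated by " vs. "
#'   (e.g. "ABCD vs. E").
#' @return an object of class `task_spec` with fields `name`, `groups`
#'   (list of character vectors) and `n_classes`.
#' @export
task_spec <- function(name) {
  parts <- strsplit(name, "vs\\.?", perl = TRUE)[[1]]
  groups <- lapply(parts, function(p) {
    letters_ <- strsplit(gsub("[^A-Za-z]", "", p), "")[[1]]
    vapply(letters_, normalize_set_label, character(1), USE.NAMES = FALSE)
  })
  if (length(groups) < 2L) stop_("a task needs at least two class groups")
  if (any(lengths(groups) == 0L)) stop_("empty class group in task '", name, "'")
  flat <- unlist(groups)
  if (anyDuplicated(flat)) {
    stop_("task groups must be disjoint: '", name, "'")
  }
  canonical <- paste(vapply(groups, paste, character(1), collapse = ""),
                     collapse = " vs. ")
  structure(
    list(name = canonical, groups = groups, n_classes = length(groups)),
    class = "task_spec")
}

#' @export
print.task_spec <- function(x, ...) {
  cat(sprintf("<task_spec> %s (%d classes)\n", x$name, x$n_classes))
  invisible(x)
}

.TASK_NAMES <- c(
  "A vs. E", "B vs. E", "C vs. E", "D vs. E",
  "AB vs. E", "AC vs. E", "AD vs. E", "BC vs. E", "BD vs. E", "CD vs. E",
  "ABC vs. E", "ABD vs. E", "BCD vs. E", "ABCD vs. E",
  "A vs. C vs. E", "A vs. D vs. E", "B vs. C vs. E", "B vs. D vs. E",
  "AB vs. CD vs. E", "A vs. B vs. C vs. D vs. E")

#' The 20 standard set-combination tasks
#'
#' Fourteen two-class, five three-class and one five-class combination; every
#' task includes the seizure set E.
#'
#' @return named list of 20 [task_spec()]s.
#' @export
list_tasks <- function() {
  tasks <- lapply(.TASK_NAMES, task_spec)
  names(tasks) <- vapply(tasks, `[[`, character(1), "name")
  tasks
}

#' Look up a task by name
#' @param name a task name as in [list_tasks()] (spacing/periods flexible).
#' @export
find_task <- function(name) {
  spec <- tryCatch(task_spec(name), error = function(e) NULL)
  tasks <- list_tasks()
  if (is.null(spec) || !spec$name %in% names(tasks)) {
    stop_("unknown task '", name, "'; valid tasks: ",
          paste(names(tasks), collapse = "; "))
  }
  tasks[[spec$name]]
}

#' Assemble the dataset for a classification task
#'
#' @param x a set-labelled [chunk_dataset()] (classes are set letters), or a
#'   named list of per-set datasets.
#' @param task a [task_spec()] or task name.
#' @return a [chunk_dataset()] whose classes are the task groups, in task
#'   order. Grouped tasks are left imbalanced; no resampling is done.
#' @export
assemble_task <- function(x, task) {
  if (is.character(task)) task <- task_spec(task)
  stopifnot(inherits(task, "task_spec"))
  if (is.list(x) && !inherits(x, "chunk_dataset")) {
    names(x) <- vapply(names(x), normalize_set_label, character(1))
    needed <- unique(unlist(task$groups))
    miss <- setdiff(needed, names(x))
    if (length(miss)) stop_("assembly error: set(s) not loaded: ",
                            paste(miss, collapse = ", "))
    x <- do.call(.bind_set_datasets, list(x[needed]))
  }
  stopifnot(inherits(x, "chunk_dataset"))
  if (!all(x$class_names %in% .SET_LETTERS)) {
    stop_("assemble_task needs a set-labelled dataset (classes A-E)")
  }
  sets <- x$class_names[x$class_label + 1L]
  miss <- setdiff(unique(unlist(task$groups)), unique(sets))
  if (length(miss)) stop_("assembly error: set(s) not loaded: ",
                          paste(miss, collapse = ", "))
  group_names <- vapply(task$groups, paste, character(1), collapse = "")
  group_of_set <- rep(NA_integer_, 5L)
  names(group_of_set) <- .SET_LETTERS
  for (g in seq_along(task$groups)) group_of_set[task$groups[[g]]] <- g
  keep <- !is.na(group_of_set[sets])
  chunk_dataset(x$x[keep, , drop = FALSE],
                group_of_set[sets[keep]] - 1L,
                group_names,
                source_record = x$source_record[keep],
                chunk_index = x$chunk_index[keep])
}

.bind_set_datasets <- function(sets) {
  mats <- lapply(sets, function(d) d$x)
  letters_ <- rep(names(sets), vapply(mats, nrow, integer(1)))
  x <- do.call(rbind, mats)
  class_names <- .SET_LETTERS[.SET_LETTERS %in% names(sets)]
  rec <- unlist(lapply(sets, function(d) d$source_record), use.names = FALSE)
  idx <- unlist(lapply(sets, function(d) d$chunk_index), use.names = FALSE)
  chunk_dataset(x, match(letters_, class_names) - 1L, class_names,
                source_record = rec, chunk_index = idx)
}

# ---- cross-validation folds --------------------------------------------

#' Plan stratified cross-validation folds
#'
#' Within each class, chunks are shuffled with the seeded generator and dealt
#' round-robin into folds, so per-class fold sizes differ by at most one.
#' `level = "record"` deals whole recordings instead, avoiding within-record
#' correlation between training and test chunks.
#'
#' @param ds a [chunk_dataset()].
#' @param n_folds number of folds (10 for the standard protocol).
#' @param seed integer seed; the same seed always yields the same plan.
#' @param level "chunk" (the protocol default) or "record".
#' @return an object of class `fold_plan` with a 0-based fold id per chunk.
#' @export
make_folds <- function(ds, n_folds = 10L, seed = 1L,
                       level = c("chunk", "record")) {
  stopifnot(inherits(ds, "chunk_dataset"))
  level <- match.arg(level)
  n_folds <- as.integer(n_folds)
  assignment <- rep(NA_integer_, n_chunks(ds))
  withr::with_seed(as.integer(seed), {
    for (k in seq_along(ds$class_names)) {
      idx <- which(ds$class_label == k - 1L)
      if (level == "chunk") {
        if (length(idx) < n_folds) {
          stop_("stratification error: class '", ds$class_names[k],
                "' has ", length(idx), " chunks < ", n_folds, " folds")
        }
        idx <- idx[sample.int(length(idx))]
        assignment[idx] <- (seq_along(idx) - 1L) %% n_folds
      } else {
        recs <- unique(ds$source_record[idx])
        if (length(recs) < n_folds) {
          stop_("stratification error: class '", ds$class_names[k],
                "' has ", length(recs), " records < ", n_folds, " folds")
        }
        recs <- recs[sample.int(length(recs))]
        fold_of_rec <- stats::setNames((seq_along(recs) - 1L) %% n_folds, recs)
        assignment[idx] <- fold_of_rec[ds$source_record[idx]]
      }
    }
  })
  structure(
    list(n_folds = n_folds, assignment = assignment,
         seed = as.integer(seed), level = level),
    class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d folds over %d chunks (%s-level, seed %d)\n",
              x$n_folds, length(x$assignment), x$level, x$seed))
  invisible(x)
}

#' Audit table of a fold plan
#'
#' @param ds the [chunk_dataset()] the plan was drawn for.
#' @param plan a [fold_plan()].
#' @return data.frame with one row per chunk: id, source record, class, fold.
#' @export
fold_table <- function(ds, plan) {
  stopifnot(inherits(ds, "chunk_dataset"), inherits(plan, "fold_plan"))
  if (length(plan$assignment) != n_chunks(ds)) {
    stop_("fold plan does not match dataset size")
  }
  data.frame(
    chunk = seq_len(n_chunks(ds)) - 1L,
    source_record = ds$source_record,
    chunk_index = ds$chunk_index,
    class = ds$class_names[ds$class_label + 1L],
    fold = plan$assignment,
    stringsAsFactors = FALSE)
}
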