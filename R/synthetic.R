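#' @title Synthetic five-class EEG generator
#' @description Seeded surrogate EEG so that every pipeline stage — both file
#'   readers, chunking, training, cross-validation — is exercisable without
#'   the real corpus. The signal model is deliberately simple: a sum of
#'   fixed-frequency sinusoids with random phases, Poisson-placed biphasic
#'   spike transients, and white Gaussian noise, rounded to integer ADC
#'   counts. The default parameters are NOT fitted to real EEG; they only
#'   encode the qualitative picture of the five sets (E high-amplitude
#'   rhythmic seizure activity, C/D interictal records with spikes, A/B
#'   low-amplitude background differing in alpha power).
#' @name synthetic
NULL

#' Per-class parameters of the synthetic signal model
#'
#' @param class_label set letter A-E.
#' @param osc_freqs sinusoid frequencies in Hz (each below the 86.8 Hz
#'   Nyquist limit of the 173.61 Hz sampling rate).
#' @param osc_amps one amplitude (ADC counts) per frequency.
#' @param spike_rate expected number of spike transients per 4097-sample
#'   segment (Poisson).
#' @param spike_amp peak spike amplitude in counts.
#' @param noise_sd standard deviation of the white noise, in counts.
#' @return an object of class `signal_params`.
#' @export
signal_params <- function(class_label, osc_freqs = numeric(), osc_amps = numeric(),
                          spike_rate = 0, spike_amp = 0, noise_sd = 0) {
  class_label <- normalize_set_label(class_label)
  if (length(osc_freqs) != length(osc_amps)) {
    stop_("osc_freqs and osc_amps must have the same length")
  }
  if (any(osc_freqs >= BONN_SAMPLING_RATE / 2)) {
    stop_("oscillation frequencies must stay below the Nyquist frequency")
  }
  if (any(c(osc_amps, spike_rate, spike_amp, noise_sd) < 0)) {
    stop_("amplitudes, rates and noise sd must be non-negative")
  }
  structure(
    list(class_label = class_label, osc_freqs = as.numeric(osc_freqs),
         osc_amps = as.numeric(osc_amps), spike_rate = spike_rate,
         spike_amp = spike_amp, noise_sd = noise_sd),
    class = "signal_params")
}

#' Default synthetic parameters for the five classes
#'
#' E is large-amplitude rhythmic delta/theta activity with frequent sharp
#' transients; C and D are moderate-amplitude slow backgrounds with
#' interictal-like spikes (D spikier and slower than C); A and B are
#' low-amplitude alpha-band backgrounds, B (eyes closed) with much stronger
#' and cleaner alpha than A. Because chunks are standardized before
#' classification, the classes are separated by waveform shape — relative
#' noise level, spectral content, spike density — not by absolute scale.
#'
#' @return named list of five [signal_params()].
#' @export
default_signal_params <- function() {
  list(
    A = signal_params("A", osc_freqs = c(10, 21),  osc_amps = c(18, 8),
                      spike_rate = 0,  spike_amp = 0,   noise_sd = 22),
    B = signal_params("B", osc_freqs = c(10),      osc_amps = c(55),
                      spike_rate = 0,  spike_amp = 0,   noise_sd = 10),
    C = signal_params("C", osc_freqs = c(4, 8),    osc_amps = c(45, 25),
                      spike_rate = 6,  spike_amp = 250, noise_sd = 18),
    D = signal_params("D", osc_freqs = c(2, 5),    osc_amps = c(60, 35),
                      spike_rate = 14, spike_amp = 350, noise_sd = 14),
    E = signal_params("E", osc_freqs = c(3, 5, 7), osc_amps = c(380, 260, 160),
                      spike_rate = 10, spike_amp = 500, noise_sd = 45))
}

#' Read/write signal-parameter tables as YAML
#'
#' @param path YAML file with one block per class.
#' @return named list of [signal_params()].
#' @export
read_signal_params <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(cl) {
    p <- raw[[cl]]
    signal_params(cl,
                  osc_freqs = unlist(p$osc_freqs) %||% numeric(),
                  osc_amps = unlist(p$osc_amps) %||% numeric(),
                  spike_rate = p$spike_rate %||% 0,
                  spike_amp = p$spike_amp %||% 0,
                  noise_sd = p$noise_sd %||% 0)
  })
  names(out) <- vapply(out, `[[`, character(1), "class_label")
  out
}

#' @rdname read_signal_params
#' @param params named list of [signal_params()].
#' @export
write_signal_params <- function(params, path) {
  yaml::write_yaml(lapply(params, function(p) {
    list(osc_freqs = p$osc_freqs, osc_amps = p$osc_amps,
         spike_rate = p$spike_rate, spike_amp = p$spike_amp,
         noise_sd = p$noise_sd)
  }), path)
  invisible(path)
}

# Biphasic spike template: triangular positive lobe, smaller negative
# rebound, 15 samples (~86 ms), peak amplitude 1.
.SPIKE_SHAPE <- c(0, 1, 2, 3, 4, 3, 2, 1, 0,
                  -1.4, -2.8, -2.1, -1.4, -0.7, 0) / 4

#' Simulate one surrogate EEG recording
#'
#' Deterministic for a given (parameters, seed) pair. The signal is the sum
#' of the class sinusoids with uniformly random phases, `Poisson(spike_rate)`
#' spike transients at uniform positions, and `N(0, noise_sd^2)` samples,
#' rounded to integers.
#'
#' @param params a [signal_params()].
#' @param seed integer seed.
#' @param record_id identifier for the generated recording.
#' @return an [eeg_segment()] of 4097 samples.
#' @export
simulate_segment <- function(params, seed = 1L, record_id = NULL) {
  stopifnot(inherits(params, "signal_params"))
  n <- BONN_SEGMENT_LENGTH
  tt <- (seq_len(n) - 1L) / BONN_SAMPLING_RATE
  if (is.null(record_id)) {
    record_id <- sprintf("%s_sim%08d", params$class_label, as.integer(seed))
  }
  x <- withr::with_seed(as.integer(seed), {
    sig <- numeric(n)
    for (i in seq_along(params$osc_freqs)) {
      phase <- stats::runif(1, 0, 2 * pi)
      sig <- sig + params$osc_amps[i] *
        sin(2 * pi * params$osc_freqs[i] * tt + phase)
    }
    if (params$spike_rate > 0 && params$spike_amp > 0) {
      n_spikes <- stats::rpois(1, params$spike_rate)
      if (n_spikes > 0) {
        len <- length(.SPIKE_SHAPE)
        starts <- sample.int(n - len + 1L, n_spikes, replace = TRUE)
        for (s in starts) {
          span <- s:(s + len - 1L)
          sig[span] <- sig[span] + params$spike_amp * .SPIKE_SHAPE
        }
      }
    }
    if (params$noise_sd > 0) sig <- sig + stats::rnorm(n, 0, params$noise_sd)
    sig
  })
  eeg_segment(round(x), set_label = params$class_label, record_id = record_id)
}

#' Simulate a full set of surrogate recordings
#'
#' Per-record seeds are derived from `(seed, class, record index)`, so the
#' same call always reproduces the same set and different records are
#' independent.
#'
#' @param class_label set letter A-E.
#' @param n_records number of recordings (100 emulates a full Bonn set).
#' @param seed integer master seed.
#' @param params parameter table; defaults to [default_signal_params()].
#' @return list of [eeg_segment()]s.
#' @export
simulate_set <- function(class_label, n_records = 100L, seed = 1L,
                         params = default_signal_params()) {
  class_label <- normalize_set_label(class_label)
  if (!is_count(n_records)) stop_("n_records must be a positive integer")
  p <- params[[class_label]]
  if (is.null(p)) stop_("no parameters for class ", class_label)
  lapply(seq_len(n_records), function(i) {
    simulate_segment(p, seed = derive_seed(seed, match(class_label, LETTERS), i),
                     record_id = sprintf("%s%03d", class_label, i))
  })
}

#' Simulate a ready-to-train chunk dataset
#'
#' Generates just enough whole recordings per class, chunks them, and trims
#' to `chunks_per_class` chunks per class.
#'
#' @param chunks_per_class chunks to keep per class.
#' @param seed integer master seed.
#' @param classes set letters to include.
#' @param params parameter table.
#' @return a set-labelled [chunk_dataset()].
#' @export
simulate_chunk_dataset <- function(chunks_per_class = 200L, seed = 1L,
                                   classes = c("A", "B", "C", "D", "E"),
                                   params = default_signal_params()) {
  classes <- vapply(classes, normalize_set_label, character(1),
                    USE.NAMES = FALSE)
  n_records <- ceiling(chunks_per_class / CHUNKS_PER_SEGMENT)
  per_set <- lapply(classes, function(cl) {
    segs <- simulate_set(cl, n_records = n_records, seed = seed,
                         params = params)
    ds <- chunk_segments(segs)
    keep <- seq_len(chunks_per_class)
    chunk_dataset(ds$x[keep, , drop = FALSE], ds$class_label[keep],
                  cl, source_record = ds$source_record[keep],
                  chunk_index = ds$chunk_index[keep])
  })
  names(per_set) <- classes
  .bind_set_datasets(per_set)
}

#' Write a complete synthetic corpus to disk
#'
#' Emits both interchange forms: the Bonn directory layout (one subdirectory
#' per set, one integer per line) and the single chunked CSV table, plus the
#' parameter table used.
#'
#' @param out_dir output directory (created).
#' @param seed integer master seed.
#' @param n_records recordings per set.
#' @param params parameter table.
#' @return invisibly, a list of the paths written.
#' @export
simulate_bonn_corpus <- function(out_dir, seed = 1L, n_records = 100L,
                                 params = default_signal_params()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sets <- names(params)
  all_segments <- list()
  for (cl in sets) {
    segs <- simulate_set(cl, n_records = n_records, seed = seed,
                         params = params)
    write_bonn_set(segs, file.path(out_dir, cl))
    all_segments <- c(all_segments, segs)
  }
  ds <- chunk_segments(all_segments)
  table_path <- file.path(out_dir, "chunks.csv")
  write_chunk_table(ds, table_path)
  params_path <- file.path(out_dir, "signal_params.yaml")
  write_signal_params(params, params_path)
  invisible(list(root = out_dir,
                 set_dirs = file.path(out_dir, sets),
                 chunk_table = table_path,
                 params = params_path))
}
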