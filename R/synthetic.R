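# Synthetic data: an oddball experiment emulator with a planted,
# recoverable spatial pattern, and a two-class Gaussian feature generator.
# These are first-class generators (not test fixtures): they define the
# stated world every stage of the framework is validated against.

#' Generate a synthetic oddball-paradigm recording
#'
#' White Gaussian noise (`noise_sigma` per channel) carries a stereotyped
#' evoked deflection after each rare "Target" stimulus: a half-sine bump of
#' the given amplitude, latency and width, projected onto a seeded random
#' unit-norm spatial pattern across channels.  Frequent "Standard" stimuli
#' add nothing.  Stimuli are presented in randomized order at a fixed
#' inter-stimulus interval and marked at their onsets, so the stream can be
#' segmented by markers into labelled epochs.  Everything is a pure
#' function of the seed.
#'
#' @param n_channels number of channels (default 8).
#' @param sampling_frequency Hz (default 100).
#' @param n_targets number of rare Target stimuli (default 50).
#' @param n_standards number of frequent Standard stimuli (default 200).
#' @param isi_ms inter-stimulus interval in ms (default 1000; must cover
#'   the evoked response).
#' @param amplitude evoked-response peak amplitude (default 2; 0 plants no
#'   signal, making the two classes identically distributed).
#' @param noise_sigma noise standard deviation per channel (default 1).
#' @param erp_latency_ms deflection onset after the stimulus (default 300).
#' @param erp_width_ms deflection duration (default 200).
#' @param seed integer seed.
#' @return list with `stream` (a [raw_stream()]) and `truth` (the planted
#'   ground truth: `spatial_pattern`, `erp_amplitude`, `erp_latency_ms`,
#'   `erp_width_ms`, `noise_sigma`, `schedule`).
#' @export
generate_oddball_stream <- function(n_channels = 8L,
                                    sampling_frequency = 100,
                                    n_targets = 50L, n_standards = 200L,
                                    isi_ms = 1000, amplitude = 2,
                                    noise_sigma = 1,
                                    erp_latency_ms = 300,
                                    erp_width_ms = 200, seed = 0L) {
  if (!is_count(n_channels) || !is_count(n_targets) || !is_count(n_standards))
    stop_sigspace("counts must be positive integers")
  if (amplitude < 0 || noise_sigma < 0) stop_sigspace("negative scale")
  if (erp_latency_ms + erp_width_ms > isi_ms)
    stop_sigspace("evoked response (%g ms) does not fit the ISI (%g ms)",
                  erp_latency_ms + erp_width_ms, isi_ms)
  fs <- sampling_frequency
  isi <- ms_to_samples(isi_ms, fs)
  n_stim <- n_targets + n_standards
  n_samples <- n_stim * isi + isi       # tail so the last window fits
  with_seed(seed, {
    pattern <- stats::rnorm(n_channels)
    pattern <- pattern / sqrt(sum(pattern^2))
    order_labels <- sample(c(rep("Target", n_targets),
                             rep("Standard", n_standards)))
    noise <- matrix(stats::rnorm(n_samples * n_channels, sd = noise_sigma),
                    n_samples, n_channels)
  })
  onsets <- (seq_len(n_stim) - 1L) * isi
  lat <- ms_to_samples(erp_latency_ms, fs)
  wid <- ms_to_samples(erp_width_ms, fs)
  bump <- amplitude * sin(pi * (seq_len(wid) - 0.5) / wid)  # half-sine
  for (i in which(order_labels == "Target")) {
    rows <- onsets[i] + lat + seq_len(wid)
    noise[rows, ] <- noise[rows, ] + outer(bump, pattern)
  }
  stream <- raw_stream(
    noise, sprintf("ch%02d", seq_len(n_channels)), fs,
    markers = data.frame(sample_index = onsets, name = order_labels,
                         stringsAsFactors = FALSE))
  truth <- list(spatial_pattern = pattern, erp_amplitude = amplitude,
                erp_latency_ms = erp_latency_ms, erp_width_ms = erp_width_ms,
                noise_sigma = noise_sigma,
                schedule = data.frame(sample_index = onsets,
                                      name = order_labels,
                                      stringsAsFactors = FALSE))
  list(stream = stream, truth = truth)
}

#' Generate a two-class Gaussian feature-vector dataset
#'
#' Class means sit at `+/- (separation / 2) * u` for a seeded random unit
#' direction `u`, with identity covariance; labels are `Standard` and
#' `Target`.  `separation = 0` makes the Bayes accuracy exactly 0.5.
#'
#' @param n_per_class samples per class.
#' @param n_features feature dimensionality.
#' @param separation distance between the class means (`>= 0`).
#' @param seed integer seed.
#' @return a feature-vector [sp_dataset()] of `2 * n_per_class` samples.
#' @export
generate_gaussian_features <- function(n_per_class = 50L, n_features = 5L,
                                       separation = 2, seed = 0L) {
  if (separation < 0) stop_sigspace("separation must be >= 0")
  with_seed(seed, {
    u <- stats::rnorm(n_features)
    u <- u / sqrt(sum(u^2))
    X <- matrix(stats::rnorm(2 * n_per_class * n_features),
                2 * n_per_class, n_features)
  })
  labels <- rep(c("Standard", "Target"), each = n_per_class)
  shift <- outer(ifelse(labels == "Target", 1, -1), u) * separation / 2
  X <- X + shift
  feats <- sprintf("f%02d", seq_len(n_features))
  fvs <- lapply(seq_len(nrow(X)), function(i)
    feature_vector(X[i, ], feats, label = labels[i]))
  sp_dataset("feature_vector", fvs,
             metadata = list(feature_names = feats,
                             history = "generate_gaussian_features"))
}

#' Write a ready-to-use synthetic oddball summary to disk
#'
#' Generates oddball streams, segments them into labelled epochs around the
#' Target/Standard markers, and writes one windowed time-series dataset per
#' requested configuration into `root`, so operations can run on it
#' directly.
#'
#' @param root target summary directory.
#' @param datasets named list; each element is a list of arguments for
#'   [generate_oddball_stream()].
#' @param window_ms epoch length after each marker (default 800 ms).
#' @return the written [sp_summary()], invisibly.
#' @export
write_synthetic_summary <- function(root, datasets, window_ms = 800) {
  out <- list()
  for (nm in names(datasets)) {
    gen <- do.call(generate_oddball_stream, datasets[[nm]])
    rules <- list(cutting_rule("Target", 0, window_ms, "Target"),
                  cutting_rule("Standard", 0, window_ms, "Standard"))
    seg <- segment_by_markers(gen$stream, rules)
    ds <- sp_dataset("time_series", seg$windows,
                     metadata = list(history = "synthetic_oddball"))
    out[[nm]] <- ds
  }
  summary <- sp_summary(out)
  write_summary(summary, root)
  summary$root_path <- root
  invisible(summary)
}
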