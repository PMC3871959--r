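# Dataset and summary containers.  A dataset holds all samples of one
# experimental run plus metadata; a summary is a named collection of
# datasets living in one directory tree and processed jointly.

DATASET_KINDS <- c("stream", "time_series", "feature_vector", "prediction")

#' Collection of data samples from one experimental run
#'
#' @param kind one of `"stream"`, `"time_series"`, `"feature_vector"`,
#'   `"prediction"`.
#' @param samples list of samples of the matching type (a single
#'   [raw_stream()] for `kind = "stream"`).
#' @param metadata named list; recognised entries are `sampling_frequency`,
#'   `channel_names`, `feature_names`, `class_column`, `storage_format` and
#'   `history` (ordered character vector of prior processing steps).
#' @return an object of class `sp_dataset`.
#' @export
sp_dataset <- function(kind, samples, metadata = list()) {
  kind <- match.arg(kind, DATASET_KINDS)
  if (kind == "stream") {
    if (inherits(samples, "raw_stream")) samples <- list(samples)
    stopifnot(length(samples) == 1L)
  }
  if (!is.list(samples)) stop_sigspace("samples must be a list")
  for (s in samples) {
    if (sample_kind(s) != kind)
      stop_sigspace("sample of kind '%s' in a '%s' dataset",
                    sample_kind(s), kind)
  }
  # homogeneity of names / sampling rate across samples
  if (length(samples) > 1L && kind == "time_series") {
    cn <- samples[[1]]$channel_names
    fs <- samples[[1]]$sampling_frequency
    for (s in samples[-1]) {
      if (!identical(s$channel_names, cn) || s$sampling_frequency != fs)
        stop_sigspace("windows disagree in channel names or sampling rate")
    }
  }
  if (length(samples) > 1L && kind == "feature_vector") {
    fn <- samples[[1]]$feature_names
    for (s in samples[-1]) {
      if (!identical(s$feature_names, fn))
        stop_sigspace("feature vectors disagree in feature names")
    }
  }
  md <- metadata
  md$kind <- kind
  if (is.null(md$history)) md$history <- character()
  if (kind %in% c("stream", "time_series") && is.null(md$sampling_frequency)
      && length(samples))
    md$sampling_frequency <- samples[[1]]$sampling_frequency
  if (kind %in% c("stream", "time_series") && is.null(md$channel_names)
      && length(samples))
    md$channel_names <- samples[[1]]$channel_names
  if (kind == "feature_vector" && is.null(md$feature_names) && length(samples))
    md$feature_names <- samples[[1]]$feature_names
  structure(list(kind = kind, samples = samples, metadata = md),
            class = "sp_dataset")
}

#' @export
print.sp_dataset <- function(x, ...) {
  cat(sprintf("<sp_dataset kind=%s> %d samples; history: %s\n", x$kind,
              length(x$samples),
              if (length(x$metadata$history))
                paste(x$metadata$history, collapse = " -> ") else "<none>"))
  invisible(x)
}

dataset_labels <- function(dataset) {
  vapply(dataset$samples, function(s) {
    lb <- if (dataset$kind == "prediction") s$true_label else s$label
    lb %||% NA_character_
  }, character(1))
}

append_history <- function(dataset, entry) {
  dataset$metadata$history <- c(dataset$metadata$history, entry)
  dataset
}

#' Named collection of datasets under one root directory
#'
#' @param datasets named list of [sp_dataset()] objects; names play the role
#'   of sub-directory names when the summary is stored.
#' @param root_path directory the summary lives in (may be `NA` for purely
#'   in-memory summaries).
#' @return an object of class `sp_summary`.
#' @export
sp_summary <- function(datasets, root_path = NA_character_) {
  if (is.null(names(datasets)) || anyDuplicated(names(datasets)) ||
      any(!nzchar(names(datasets))))
    stop_sigspace("summary entries must have unique non-empty names")
  for (d in datasets) stopifnot(inherits(d, "sp_dataset"))
  structure(list(root_path = root_path, datasets = datasets),
            class = "sp_summary")
}

#' @export
print.sp_summary <- function(x, ...) {
  cat(sprintf("<sp_summary> %d datasets at %s\n", length(x$datasets),
              x$root_path))
  for (nm in names(x$datasets))
    cat(sprintf("  %s: %s, %d samples\n", nm, x$datasets[[nm]]$kind,
                length(x$datasets[[nm]]$samples)))
  invisible(x)
}

#' Concatenate groups of compatible datasets
#'
#' Emulates the data-preparation step in which the several recordings of one
#' session are concatenated into a single dataset before splitting.  Members
#' of a group must agree in kind, channel/feature names and sampling rate.
#'
#' @param summary an [sp_summary()].
#' @param group_by function mapping a dataset name to a group key; defaults
#'   to everything in one group named `"merged"`.
#' @return a new in-memory [sp_summary()], one dataset per group, each with a
#'   history entry noting the merge.
#' @export
merge_datasets <- function(summary, group_by = function(name) "merged") {
  stopifnot(inherits(summary, "sp_summary"))
  keys <- vapply(names(summary$datasets), group_by, character(1))
  out <- list()
  for (key in unique(keys)) {
    members <- summary$datasets[keys == key]
    kinds <- unique(vapply(members, function(d) d$kind, character(1)))
    if (length(kinds) != 1L)
      stop_sigspace("group '%s' mixes dataset kinds (%s)", key,
                    paste(kinds, collapse = ", "))
    first <- members[[1]]
    for (i in seq_along(members)[-1]) {
      d <- members[[i]]
      ok <- identical(d$metadata$channel_names, first$metadata$channel_names) &&
        identical(d$metadata$feature_names, first$metadata$feature_names) &&
        identical(d$metadata$sampling_frequency %||% NA,
                  first$metadata$sampling_frequency %||% NA)
      if (!ok)
        stop_sigspace("datasets '%s' and '%s' are incompatible for merging",
                      names(members)[1], names(members)[i])
    }
    merged <- sp_dataset(first$kind,
                         unname(do.call(c, lapply(members,
                                                  function(d) d$samples))),
                         metadata = first$metadata)
    merged <- append_history(
      merged, sprintf("merge(%s)", paste(names(members), collapse = "+")))
    out[[key]] <- merged
  }
  sp_summary(out)
}

#' Permute the sample order of every dataset in a summary
#'
#' @param summary an [sp_summary()].
#' @param seed integer seed; the same seed always yields the same
#'   permutations.
#' @return a new in-memory [sp_summary()] with shuffled sample order (the
#'   multiset of samples is unchanged).
#' @export
shuffle_datasets <- function(summary, seed) {
  stopifnot(inherits(summary, "sp_summary"))
  out <- summary$datasets
  for (i in seq_along(out)) {
    d <- out[[i]]
    n <- length(d$samples)
    perm <- with_seed(derive_node_seed(seed, i, names(out)[i]), sample.int(n))
    d$samples <- d$samples[perm]
    out[[i]] <- append_history(d, sprintf("shuffle(seed=%d)", seed))
  }
  sp_summary(out)
}
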