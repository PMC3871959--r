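# Data-sample types.  Four granularities of a single observation flow
# through a node chain: a continuous raw stream, a windowed (epoched)
# time series, a feature vector, and a classifier prediction.

#' Continuous multichannel recording with event markers
#'
#' @param samples numeric matrix, one row per sample point, one column per
#'   channel (rows = time, columns = sensors everywhere in this package).
#' @param channel_names character vector of unique channel names, one per
#'   column.
#' @param sampling_frequency sampling rate in Hz, `> 0`.
#' @param markers data frame with columns `sample_index` (0-based integer
#'   position in the stream) and `name` (event label).  Markers are kept in
#'   `sample_index` order; ties preserve their original order.
#' @return an object of class `raw_stream`.
#' @export
raw_stream <- function(samples, channel_names, sampling_frequency,
                       markers = data.frame(sample_index = integer(),
                                            name = character())) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!is.character(channel_names) || anyDuplicated(channel_names))
    stop_sigspace("channel_names must be unique strings")
  if (ncol(samples) != length(channel_names))
    stop_sigspace("stream has %d columns but %d channel names",
                  ncol(samples), length(channel_names))
  if (!is_number(sampling_frequency) || sampling_frequency <= 0)
    stop_sigspace("sampling_frequency must be a positive number")
  markers <- as.data.frame(markers)
  if (!all(c("sample_index", "name") %in% names(markers)))
    stop_sigspace("markers need columns sample_index and name")
  if (nrow(markers)) {
    idx <- markers$sample_index
    if (any(idx < 0 | idx >= nrow(samples)))
      stop_sigspace("marker sample_index outside [0, %d)", nrow(samples))
    markers <- markers[order(markers$sample_index), , drop = FALSE]  # stable
    rownames(markers) <- NULL
  }
  structure(
    list(samples = samples, channel_names = as.character(channel_names),
         sampling_frequency = sampling_frequency, markers = markers),
    class = "raw_stream"
  )
}

#' One segmented epoch of a multichannel recording
#'
#' @param values numeric matrix, time points in rows, channels in columns.
#' @param channel_names character vector naming the columns.
#' @param sampling_frequency Hz, `> 0`.
#' @param start_time_ms offset of the first sample relative to the start of
#'   the source stream, in milliseconds.
#' @param label optional class label (e.g. `"Target"`).
#' @param tag free-form provenance string.
#' @return an object of class `ts_window`.
#' @export
ts_window <- function(values, channel_names, sampling_frequency,
                      start_time_ms = 0, label = NULL, tag = "") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) != length(channel_names))
    stop_sigspace("window has %d columns but %d channel names",
                  ncol(values), length(channel_names))
  if (anyDuplicated(channel_names))
    stop_sigspace("duplicate channel names")
  if (!is_number(sampling_frequency) || sampling_frequency <= 0)
    stop_sigspace("sampling_frequency must be a positive number")
  if (!all(is.finite(values)))
    stop_sigspace("window values must all be finite")
  structure(
    list(values = values, channel_names = as.character(channel_names),
         sampling_frequency = sampling_frequency,
         start_time_ms = start_time_ms, label = label, tag = tag),
    class = "ts_window"
  )
}

#' Named vector of feature values
#'
#' @param values numeric vector of finite feature values.
#' @param feature_names unique names, one per value.
#' @param label optional class label.
#' @return an object of class `feature_vector`.
#' @export
feature_vector <- function(values, feature_names = names(values),
                           label = NULL) {
  values <- as.numeric(values)
  if (is.null(feature_names))
    stop_sigspace("feature names are required")
  if (length(values) != length(feature_names))
    stop_sigspace("%d values but %d feature names",
                  length(values), length(feature_names))
  if (anyDuplicated(feature_names))
    stop_sigspace("duplicate feature names")
  if (!all(is.finite(values)))
    stop_sigspace("feature values must all be finite")
  structure(
    list(values = values, feature_names = as.character(feature_names),
         label = label),
    class = "feature_vector"
  )
}

#' Classifier output for one sample
#'
#' @param score real decision value (distance from the decision boundary, or
#'   a mapped probability).
#' @param assigned_label label the classifier assigned.
#' @param true_label optional true label carried along for evaluation.
#' @param classifier_name name of the producing classifier.
#' @return an object of class `prediction_vector`.
#' @export
prediction_vector <- function(score, assigned_label, true_label = NULL,
                              classifier_name = "") {
  if (!is_number(score)) stop_sigspace("score must be a finite number")
  structure(
    list(score = score, assigned_label = assigned_label,
         true_label = true_label, classifier_name = classifier_name),
    class = "prediction_vector"
  )
}

#' Rule for cutting labelled windows around a marker
#'
#' A window for marker `m` (0-based sample index) spans the half-open sample
#' range `[m + start, m + end)` where `start`/`end` are the millisecond
#' offsets converted to whole samples.
#'
#' @param marker_name marker to cut around.
#' @param window_start_ms signed start offset relative to the marker, ms.
#' @param window_end_ms signed end offset, must exceed `window_start_ms`.
#' @param class_label label given to the resulting windows.
#' @return an object of class `cutting_rule`.
#' @export
cutting_rule <- function(marker_name, window_start_ms, window_end_ms,
                         class_label) {
  if (window_end_ms <= window_start_ms)
    stop_sigspace("window_end_ms must exceed window_start_ms")
  structure(
    list(marker_name = marker_name, window_start_ms = window_start_ms,
         window_end_ms = window_end_ms, class_label = class_label),
    class = "cutting_rule"
  )
}

sample_kind <- function(x) {
  if (inherits(x, "raw_stream")) "stream"
  else if (inherits(x, "ts_window")) "time_series"
  else if (inherits(x, "feature_vector")) "feature_vector"
  else if (inherits(x, "prediction_vector")) "prediction"
  else stop_sigspace("not a data sample: %s", paste(class(x), collapse = "/"))
}

#' @export
print.raw_stream <- function(x, ...) {
  cat(sprintf("<raw_stream> %d samples x %d channels @ %g Hz, %d markers\n",
              nrow(x$samples), ncol(x$samples), x$sampling_frequency,
              nrow(x$markers)))
  invisible(x)
}

#' @export
print.ts_window <- function(x, ...) {
  cat(sprintf("<ts_window> %d x %d @ %g Hz, label=%s\n",
              nrow(x$values), ncol(x$values), x$sampling_frequency,
              x$label %||% "<none>"))
  invisible(x)
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> %d features, label=%s\n",
              length(x$values), x$label %||% "<none>"))
  invisible(x)
}

#' @export
print.prediction_vector <- function(x, ...) {
  cat(sprintf("<prediction_vector> score=%g label=%s true=%s\n",
              x$score, x$assigned_label, x$true_label %||% "<none>"))
  invisible(x)
}
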