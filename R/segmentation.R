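# Stream segmentation: cutting labelled epochs around event markers, or
# equidistant snippets.  Offsets in milliseconds are converted to whole
# samples as round(ms * fs / 1000); a rule must convert exactly so that no
# window boundary silently shifts.

ms_to_samples <- function(ms, fs) {
  x <- ms * fs / 1000
  r <- round(x)
  if (abs(x - r) > 1e-9)
    stop_sigspace("offset %g ms is not a whole number of samples at %g Hz",
                  ms, fs)
  as.integer(r)
}

#' Cut labelled windows around event markers
#'
#' For every marker and every rule matching its name, a window spanning the
#' half-open sample range `[m + start, m + end)` (0-based, `m` the marker's
#' sample index) is extracted and labelled with the rule's class label.
#' Windows that would extend beyond the stream are dropped silently and
#' counted.  A marker may match several rules; each match emits a window.
#'
#' @param stream a [raw_stream()].
#' @param rules list of [cutting_rule()] objects (non-empty).
#' @return list with `windows` (list of [ts_window()], ordered by onset) and
#'   `dropped` (number of windows discarded at the stream boundary).
#' @export
segment_by_markers <- function(stream, rules) {
  stopifnot(inherits(stream, "raw_stream"))
  if (!length(rules)) stop_sigspace("at least one cutting rule is required")
  fs <- stream$sampling_frequency
  n <- nrow(stream$samples)
  onsets <- integer(); specs <- list()
  for (rule in rules) {
    stopifnot(inherits(rule, "cutting_rule"))
    s0 <- ms_to_samples(rule$window_start_ms, fs)
    s1 <- ms_to_samples(rule$window_end_ms, fs)
    if (s1 - s0 < 1L)
      stop_sigspace("rule for marker '%s' yields a zero-length window",
                    rule$marker_name)
    hit <- which(stream$markers$name == rule$marker_name)
    for (i in hit) {
      m <- stream$markers$sample_index[i]
      specs[[length(specs) + 1L]] <-
        list(from = m + s0, to = m + s1, label = rule$class_label, marker = m)
      onsets <- c(onsets, m + s0)
    }
  }
  windows <- list(); dropped <- 0L
  for (sp in specs[order(onsets)]) {
    if (sp$from < 0L || sp$to > n) { dropped <- dropped + 1L; next }
    windows[[length(windows) + 1L]] <- ts_window(
      values = stream$samples[(sp$from + 1L):sp$to, , drop = FALSE],
      channel_names = stream$channel_names,
      sampling_frequency = fs,
      start_time_ms = sp$from * 1000 / fs,
      label = sp$label,
      tag = sprintf("marker@%d", sp$marker)
    )
  }
  list(windows = windows, dropped = dropped)
}

#' Cut equally spaced windows from a stream
#'
#' Windows of `window_ms` start at samples `0, step, 2*step, ...`; only
#' fully contained windows are returned (a window longer than the stream
#' yields an empty result, not an error).
#'
#' @param stream a [raw_stream()].
#' @param window_ms window length in ms (`> 0`, whole samples).
#' @param step_ms distance between window starts in ms (`> 0`, whole
#'   samples).
#' @param label optional class label given to every window.
#' @return list of [ts_window()] objects.
#' @export
segment_equidistant <- function(stream, window_ms, step_ms, label = NULL) {
  stopifnot(inherits(stream, "raw_stream"))
  fs <- stream$sampling_frequency
  w <- ms_to_samples(window_ms, fs)
  s <- ms_to_samples(step_ms, fs)
  if (w < 1L || s < 1L) stop_sigspace("window and step must be positive")
  n <- nrow(stream$samples)
  if (n < w) return(list())
  starts <- seq.int(0L, n - w, by = s)
  lapply(starts, function(from) {
    ts_window(stream$samples[(from + 1L):(from + w), , drop = FALSE],
              stream$channel_names, fs,
              start_time_ms = from * 1000 / fs, label = label,
              tag = sprintf("equidistant@%d", from))
  })
}
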