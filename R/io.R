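# On-disk formats.  Everything is plain text: CSV for streams, windowed
# time series, feature vectors and results; ARFF for feature vectors; YAML
# for metadata and specification files.  The CSV dialect is fixed (comma
# separator, '.' decimal point, mandatory header, UTF-8, no quoting of
# numerics) and floats are serialized with 17 significant digits so that
# write/read round trips are bit-exact for doubles.

read_csv_strict <- function(path) {
  if (!file.exists(path)) stop_sigspace("no such file: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) stop_sigspace("%s: empty file", path)
  fields <- strsplit(lines, ",", fixed = TRUE)
  header <- fields[[1]]
  ncols <- length(header)
  rows <- fields[-1]
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) != ncols)
      stop_sigspace("%s: ragged row, line %d (%d fields, expected %d)",
                    path, i + 1L, length(rows[[i]]), ncols)
  }
  list(header = trimws(header),
       rows = rows, n = length(rows))
}

csv_numeric_matrix <- function(parsed, path) {
  m <- matrix(NA_real_, nrow = parsed$n, ncol = length(parsed$header))
  for (i in seq_len(parsed$n)) {
    v <- suppressWarnings(as.numeric(parsed$rows[[i]]))
    if (any(is.na(v)))
      stop_sigspace("%s: non-numeric cell, line %d", path, i + 1L)
    m[i, ] <- v
  }
  if (length(m) && !all(is.finite(m)))
    stop_sigspace("%s: non-finite value", path)
  colnames(m) <- parsed$header
  m
}

write_csv_lines <- function(header, rows, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(header, collapse = ","), rows), con, useBytes = TRUE)
}

# streams --------------------------------------------------------------------

#' Read a continuous recording from a CSV sample table plus marker file
#'
#' The data file must have a header row of channel names and one numeric row
#' per sample point; the marker file has the header `sample_index,name`.
#' Ragged rows, non-numeric cells and out-of-range marker indices are
#' format errors naming the offending line.
#'
#' @param data_path CSV file of samples.
#' @param marker_path CSV file of markers.
#' @param sampling_frequency sampling rate in Hz.
#' @return a [raw_stream()].
#' @export
read_stream_csv <- function(data_path, marker_path, sampling_frequency) {
  parsed <- read_csv_strict(data_path)
  m <- csv_numeric_matrix(parsed, data_path)
  mk <- read_csv_strict(marker_path)
  if (!identical(mk$header, c("sample_index", "name")))
    stop_sigspace("%s: expected header 'sample_index,name'", marker_path)
  idx <- integer(mk$n); nm <- character(mk$n)
  for (i in seq_len(mk$n)) {
    v <- suppressWarnings(as.integer(mk$rows[[i]][1]))
    if (is.na(v))
      stop_sigspace("%s: non-integer marker index, line %d", marker_path,
                    i + 1L)
    if (v < 0L || v >= parsed$n)
      stop_sigspace("marker out of range, line %d", i + 1L)
    idx[i] <- v; nm[i] <- mk$rows[[i]][2]
  }
  raw_stream(m, parsed$header, sampling_frequency,
             markers = data.frame(sample_index = idx, name = nm,
                                  stringsAsFactors = FALSE))
}

#' Write a stream as CSV sample table, marker file and metadata
#'
#' Inverse of [read_stream_csv()]; writes `data.csv`, `markers.csv` and
#' `metadata.yaml` into `dir`.
#'
#' @param stream a [raw_stream()].
#' @param dir target directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_stream_csv <- function(stream, dir) {
  stopifnot(inherits(stream, "raw_stream"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- apply(stream$samples, 1L,
                function(r) paste(format_num(r), collapse = ","))
  write_csv_lines(stream$channel_names, rows, file.path(dir, "data.csv"))
  mrows <- sprintf("%d,%s", stream$markers$sample_index, stream$markers$name)
  write_csv_lines(c("sample_index", "name"), mrows,
                  file.path(dir, "markers.csv"))
  write_metadata(list(kind = "stream", storage_format = "csv",
                      sampling_frequency = stream$sampling_frequency,
                      channel_names = stream$channel_names,
                      history = character()),
                 file.path(dir, "metadata.yaml"))
  invisible(dir)
}

# metadata -------------------------------------------------------------------

write_metadata <- function(metadata, path) {
  md <- metadata
  md$history <- as.list(md$history %||% character())
  yaml::write_yaml(md, path)
}

read_metadata <- function(path) {
  if (!file.exists(path)) stop_sigspace("missing metadata file: %s", path)
  md <- yaml::read_yaml(path)
  if (is.null(md$kind) || !md$kind %in% DATASET_KINDS)
    stop_sigspace("%s: missing or unknown dataset kind", path)
  md$history <- as.character(unlist(md$history %||% character()))
  md
}

# datasets -------------------------------------------------------------------

#' Write a dataset directory (`metadata.yaml` plus `data.csv`)
#'
#' Windowed time series are stored long: columns `window_id, label,
#' time_index, <channel...>`.  Feature-vector datasets store one row per
#' sample with columns `<feature...>, label`.  Prediction datasets store
#' `score, assigned_label, true_label, classifier_name`.  Streams are
#' handled by [write_stream_csv()] instead.
#'
#' @param dataset an [sp_dataset()].
#' @param dir target directory, absent or empty.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sp_dataset"))
  if (dataset$kind == "stream")
    return(write_stream_csv(dataset$samples[[1]], dir))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  md <- dataset$metadata
  md$storage_format <- "csv"
  md$class_column <- "label"
  path <- file.path(dir, "data.csv")
  if (dataset$kind == "time_series") {
    header <- c("window_id", "label", "time_index", md$channel_names)
    rows <- character()
    for (i in seq_along(dataset$samples)) {
      w <- dataset$samples[[i]]
      lab <- w$label %||% ""
      for (t in seq_len(nrow(w$values))) {
        rows[[length(rows) + 1L]] <- paste(
          c(i - 1L, lab, t - 1L, format_num(w$values[t, ])), collapse = ",")
      }
    }
    write_csv_lines(header, rows, path)
  } else if (dataset$kind == "feature_vector") {
    header <- c(md$feature_names, "label")
    rows <- vapply(dataset$samples, function(fv) {
      paste(c(format_num(fv$values), fv$label %||% ""), collapse = ",")
    }, character(1))
    write_csv_lines(header, rows, path)
  } else {  # prediction
    header <- c("score", "assigned_label", "true_label", "classifier_name")
    rows <- vapply(dataset$samples, function(p) {
      paste(c(format_num(p$score), p$assigned_label, p$true_label %||% "",
              p$classifier_name), collapse = ",")
    }, character(1))
    write_csv_lines(header, rows, path)
  }
  write_metadata(md, file.path(dir, "metadata.yaml"))
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir dataset directory containing `metadata.yaml`.
#' @return an [sp_dataset()] (or, for `kind = "stream"`, a dataset wrapping
#'   the stream read back from `data.csv`/`markers.csv`).
#' @export
read_dataset <- function(dir) {
  md <- read_metadata(file.path(dir, "metadata.yaml"))
  if (md$kind == "stream") {
    stream <- read_stream_csv(file.path(dir, "data.csv"),
                              file.path(dir, "markers.csv"),
                              md$sampling_frequency)
    return(sp_dataset("stream", list(stream), metadata = md))
  }
  path <- file.path(dir, "data.csv")
  parsed <- read_csv_strict(path)
  if (md$kind == "time_series") {
    chans <- as.character(unlist(md$channel_names))
    expected <- c("window_id", "label", "time_index", chans)
    if (!identical(parsed$header, expected))
      stop_sigspace("%s: header does not match metadata channels", path)
    if (parsed$n == 0L)
      return(sp_dataset("time_series", list(), metadata = md))
    ids <- vapply(parsed$rows, function(r) r[[1]], character(1))
    labs <- vapply(parsed$rows, function(r) r[[2]], character(1))
    vals <- t(vapply(parsed$rows, function(r) {
      v <- suppressWarnings(as.numeric(r[-(1:3)]))
      if (any(is.na(v))) stop_sigspace("%s: non-numeric cell", path)
      v
    }, numeric(length(chans))))
    if (length(chans) == 1L) vals <- matrix(vals, ncol = 1L)
    windows <- list()
    for (id in unique(ids)) {
      sel <- ids == id
      lab <- unique(labs[sel])
      windows[[length(windows) + 1L]] <- ts_window(
        vals[sel, , drop = FALSE], chans, md$sampling_frequency,
        label = if (nzchar(lab[1])) lab[1] else NULL)
    }
    return(sp_dataset("time_series", windows, metadata = md))
  }
  if (md$kind == "feature_vector") {
    feats <- as.character(unlist(md$feature_names))
    if (!identical(parsed$header, c(feats, "label")))
      stop_sigspace("%s: header does not match metadata features", path)
    fvs <- lapply(parsed$rows, function(r) {
      v <- suppressWarnings(as.numeric(r[seq_along(feats)]))
      if (any(is.na(v))) stop_sigspace("%s: non-numeric cell", path)
      lab <- r[[length(feats) + 1L]]
      feature_vector(v, feats, label = if (nzchar(lab)) lab else NULL)
    })
    return(sp_dataset("feature_vector", fvs, metadata = md))
  }
  # prediction
  if (!identical(parsed$header,
                 c("score", "assigned_label", "true_label",
                   "classifier_name")))
    stop_sigspace("%s: unexpected prediction header", path)
  preds <- lapply(parsed$rows, function(r) {
    prediction_vector(as.numeric(r[[1]]), r[[2]],
                      true_label = if (nzchar(r[[3]])) r[[3]] else NULL,
                      classifier_name = r[[4]])
  })
  sp_dataset("prediction", preds, metadata = md)
}

# summaries ------------------------------------------------------------------

#' Read every dataset sub-directory of a summary folder
#'
#' @param root directory whose immediate sub-directories each contain a
#'   `metadata.yaml`.
#' @return an [sp_summary()].
#' @export
read_summary <- function(root) {
  if (!dir.exists(root)) stop_sigspace("no such summary directory: %s", root)
  subs <- list.dirs(root, recursive = FALSE)
  subs <- subs[file.exists(file.path(subs, "metadata.yaml"))]
  if (!length(subs)) stop_sigspace("summary %s contains no datasets", root)
  datasets <- lapply(subs, read_dataset)
  names(datasets) <- basename(subs)
  sp_summary(datasets, root_path = root)
}

#' Write every dataset of a summary into sub-directories of `root`
#'
#' @param summary an [sp_summary()].
#' @param root target directory.
#' @return `root`, invisibly.
#' @export
write_summary <- function(summary, root) {
  stopifnot(inherits(summary, "sp_summary"))
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(summary$datasets))
    write_dataset(summary$datasets[[nm]], file.path(root, nm))
  invisible(root)
}

# ARFF -----------------------------------------------------------------------

#' Write a feature-vector dataset in ARFF
#'
#' One numeric attribute per feature, then a nominal `class` attribute
#' listing the finite label set; the relation name defaults to the target
#' file's base name.
#'
#' @param dataset feature-vector [sp_dataset()] whose samples are all
#'   labelled.
#' @param path target `.arff` file.
#' @return `path`, invisibly.
#' @export
write_arff <- function(dataset, path) {
  stopifnot(inherits(dataset, "sp_dataset"), dataset$kind == "feature_vector")
  labels <- dataset_labels(dataset)
  if (anyNA(labels))
    stop_sigspace("ARFF requires every sample to carry a class label")
  classes <- sort(unique(labels))
  feats <- dataset$metadata$feature_names
  lines <- c(
    sprintf("@relation %s",
            sub("\\.arff$", "", basename(path))),
    "",
    sprintf("@attribute %s numeric", feats),
    sprintf("@attribute class {%s}", paste(classes, collapse = ",")),
    "",
    "@data",
    vapply(dataset$samples, function(fv) {
      paste(c(format_num(fv$values), fv$label), collapse = ",")
    }, character(1))
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Read a feature-vector dataset from ARFF
#'
#' Accepts the subset of ARFF written by [write_arff()]: numeric attributes
#' plus one nominal class attribute (which must be present).
#'
#' @param path `.arff` file.
#' @return a feature-vector [sp_dataset()].
#' @export
read_arff <- function(path) {
  if (!file.exists(path)) stop_sigspace("no such file: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  attr_names <- character(); attr_nominal <- list(); class_attr <- NULL
  data_at <- NA_integer_
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln) || startsWith(ln, "%")) next
    low <- tolower(ln)
    if (startsWith(low, "@attribute")) {
      m <- regmatches(ln, regexec(
        "^@[aA][tT][tT][rR][iI][bB][uU][tT][eE]\\s+(\\S+)\\s+(.*)$", ln))[[1]]
      if (length(m) != 3L) stop_sigspace("%s: malformed @attribute, line %d",
                                         path, i)
      nm <- m[2]; typ <- trimws(m[3])
      if (nm %in% attr_names)
        stop_sigspace("%s: duplicate attribute '%s'", path, nm)
      attr_names <- c(attr_names, nm)
      if (startsWith(typ, "{")) {
        vals <- trimws(strsplit(gsub("[{}]", "", typ), ",")[[1]])
        attr_nominal[[nm]] <- vals
      } else if (!tolower(typ) %in% c("numeric", "real", "integer")) {
        stop_sigspace("%s: unsupported attribute type '%s'", path, typ)
      }
    } else if (startsWith(low, "@data")) {
      data_at <- i; break
    }
  }
  if (is.na(data_at)) stop_sigspace("%s: missing @data section", path)
  if (!length(attr_nominal) || !"class" %in% names(attr_nominal))
    stop_sigspace("%s: missing nominal class attribute", path)
  class_idx <- which(attr_names == "class")
  feats <- attr_names[-class_idx]
  rows <- lines[-seq_len(data_at)]
  rows <- trimws(rows)
  rows <- rows[nzchar(rows) & !startsWith(rows, "%")]
  fvs <- lapply(seq_along(rows), function(i) {
    parts <- trimws(strsplit(rows[[i]], ",", fixed = TRUE)[[1]])
    if (length(parts) != length(attr_names))
      stop_sigspace("%s: wrong field count in data row %d", path, i)
    v <- suppressWarnings(as.numeric(parts[-class_idx]))
    if (any(is.na(v)))
      stop_sigspace("%s: non-numeric feature in data row %d", path, i)
    lab <- parts[class_idx]
    if (!lab %in% attr_nominal$class)
      stop_sigspace("%s: label '%s' outside declared class set", path, lab)
    feature_vector(v, feats, label = lab)
  })
  sp_dataset("feature_vector", fvs,
             metadata = list(feature_names = feats, storage_format = "arff",
                             class_column = "class"))
}
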