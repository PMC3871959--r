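# Evaluation: confusion-matrix metrics from prediction collections, the
# consolidated results table, and simple grouped queries over it.

#' Binary classification metrics for a set of predictions
#'
#' Counts the confusion matrix against `positive_class` and derives
#' accuracy, precision (TP / (TP + FP)), recall (TP / (TP + FN)), balanced
#' accuracy ((recall + specificity) / 2) and the F-measure
#' (2PR / (P + R)).  Empty denominators yield 0 by convention so that
#' result tables stay numeric.
#'
#' @param predictions list of [prediction_vector()] objects, each with a
#'   true label.
#' @param positive_class label counted as positive.
#' @return a named list (class `metrics_record`) with entries `tp`, `fp`,
#'   `tn`, `fn`, `accuracy`, `balanced_accuracy`, `precision`, `recall`,
#'   `f_measure`, `n_samples`.
#' @export
compute_metrics <- function(predictions, positive_class) {
  if (!length(predictions)) stop_sigspace("no predictions to evaluate")
  tp <- fp <- tn <- fn <- 0L
  for (p in predictions) {
    stopifnot(inherits(p, "prediction_vector"))
    if (is.null(p$true_label))
      stop_sigspace("prediction without a true label")
    pos_pred <- identical(p$assigned_label, positive_class)
    pos_true <- identical(p$true_label, positive_class)
    if (pos_pred && pos_true) tp <- tp + 1L
    else if (pos_pred && !pos_true) fp <- fp + 1L
    else if (!pos_pred && pos_true) fn <- fn + 1L
    else tn <- tn + 1L
  }
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  specificity <- safe_div(tn, tn + fp)
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         accuracy = safe_div(tp + tn, tp + fp + tn + fn),
         balanced_accuracy = (recall + specificity) / 2,
         precision = precision, recall = recall,
         f_measure = safe_div(2 * precision * recall, precision + recall),
         n_samples = tp + fp + tn + fn),
    class = "metrics_record"
  )
}

METRIC_COLUMNS <- c("accuracy", "balanced_accuracy", "precision", "recall",
                    "f_measure", "n_samples")

#' Combine per-process outcomes into one results table
#'
#' One row per successful process, keyed by dataset, parameter binding and
#' run index, with `Train_*` and `Test_*` metric columns.  Rows are sorted
#' by (Dataset, parameters, Run) so the table is independent of execution
#' order and back-end.
#'
#' @param outcomes list of process outcomes as returned by
#'   [execute_processes()].
#' @param parameter_names tokens varied by the operation (underscores
#'   already stripped in the column names).
#' @return a `data.frame` (class `results_table`).
#' @export
aggregate_results <- function(outcomes, parameter_names = character()) {
  rows <- list()
  for (oc in outcomes) {
    if (!isTRUE(oc$success)) next
    row <- list(Dataset = oc$dataset, Run = oc$run_index)
    for (tok in parameter_names)
      row[[strip_token(tok)]] <- oc$binding[[tok]]
    for (phase in c("Train", "Test")) {
      m <- oc$metrics[[tolower(phase)]]
      for (col in METRIC_COLUMNS)
        row[[paste0(phase, "_", col)]] <-
          if (is.null(m)) NA_real_ else m[[col]]
    }
    rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) {
    tbl <- data.frame(Dataset = character(), Run = integer())
  } else {
    tbl <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  }
  key_cols <- c("Dataset", vapply(parameter_names, strip_token, character(1)),
                "Run")
  key_cols <- intersect(key_cols, names(tbl))
  if (nrow(tbl))
    tbl <- tbl[do.call(order, tbl[key_cols]), , drop = FALSE]
  rownames(tbl) <- NULL
  class(tbl) <- c("results_table", "data.frame")
  tbl
}

strip_token <- function(tok) gsub("_", "", tok)

#' Write a results table as `results.csv`
#'
#' @param table a `results_table`.
#' @param path target CSV path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(table, path) {
  cols <- names(table)
  rows <- vapply(seq_len(nrow(table)), function(i) {
    paste(vapply(cols, function(cl) {
      v <- table[i, cl]
      if (is.numeric(v)) format_num(v) else as.character(v)
    }, character(1)), collapse = ",")
  }, character(1))
  write_csv_lines(cols, rows, path)
  invisible(path)
}

#' Read back a `results.csv`
#'
#' @param path CSV path written by [write_results_csv()].
#' @return a `results_table` data frame.
#' @export
read_results_csv <- function(path) {
  parsed <- read_csv_strict(path)
  cols <- parsed$header
  tbl <- as.data.frame(
    setNames(lapply(seq_along(cols), function(j) {
      v <- vapply(parsed$rows, function(r) r[[j]], character(1))
      num <- suppressWarnings(as.numeric(v))
      if (length(v) && !anyNA(num)) num else v
    }), cols),
    stringsAsFactors = FALSE, check.names = FALSE)
  class(tbl) <- c("results_table", "data.frame")
  tbl
}

#' Filter, group and average a results table
#'
#' @param table a `results_table`.
#' @param filters named list `column -> value`; rows must match all of
#'   them.
#' @param group_by character vector of grouping columns.
#' @param metric metric column to average (e.g. `"Test_balanced_accuracy"`).
#' @return data frame with the grouping columns, `mean_<metric>` and `n`;
#'   groups in deterministic (sorted) order.  An empty filter result yields
#'   an empty table.
#' @export
query_results <- function(table, filters = list(), group_by = character(),
                          metric = "Test_balanced_accuracy") {
  stopifnot(is.data.frame(table))
  for (cl in c(names(filters), group_by, metric)) {
    if (!cl %in% names(table)) stop_sigspace("unknown column '%s'", cl)
  }
  keep <- rep(TRUE, nrow(table))
  for (cl in names(filters)) keep <- keep & (table[[cl]] == filters[[cl]])
  sub <- table[keep, , drop = FALSE]
  if (!length(group_by)) {
    out <- data.frame(mean = mean(sub[[metric]]), n = nrow(sub))
    names(out)[1] <- paste0("mean_", metric)
    if (!nrow(sub)) out <- out[0, , drop = FALSE]
    return(out)
  }
  if (!nrow(sub)) {
    out <- sub[, group_by, drop = FALSE]
    out[[paste0("mean_", metric)]] <- numeric(0)
    out$n <- integer(0)
    return(out)
  }
  key <- interaction(sub[group_by], drop = TRUE, lex.order = TRUE)
  agg <- lapply(split(seq_len(nrow(sub)), key), function(ix)
    c(mean(sub[[metric]][ix]), length(ix)))
  first <- vapply(split(seq_len(nrow(sub)), key), `[`, integer(1), 1L)
  out <- sub[first, group_by, drop = FALSE]
  out[[paste0("mean_", metric)]] <- vapply(agg, `[`, numeric(1), 1L)
  out$n <- vapply(agg, function(a) as.integer(a[2]), integer(1))
  out <- out[do.call(order, out[group_by]), , drop = FALSE]
  rownames(out) <- NULL
  out
}
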