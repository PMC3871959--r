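# Built-in node library.  Registration happens in .onLoad so the registry
# is populated whenever the package is attached or used via `::`.

identity_execute <- function(node, sample) sample

register_builtin_nodes <- function() {
  reg <- function(...) register_node(..., overwrite = TRUE)

  # sources and sinks ---------------------------------------------------
  reg("TimeSeriesSourceNode", "time_series", "same", "source",
      execute = identity_execute)
  reg("FeatureVectorSourceNode", "feature_vector", "same", "source",
      execute = identity_execute)
  reg("TimeSeriesSinkNode", "time_series", "same", "sink",
      execute = identity_execute)
  reg("FeatureVectorSinkNode", "feature_vector", "same", "sink",
      execute = identity_execute)
  reg("PerformanceSinkNode", "prediction", "same", "sink",
      execute = identity_execute)

  # identity baseline: accepts (and ignores) arbitrary parameters so that
  # it can stand in for any spatial filter inside a parameterized template
  reg("NoopNode", "any", "same", "spatial_filter",
      execute = identity_execute)

  # preprocessing -------------------------------------------------------
  reg("StandardizationNode", "time_series", "same", "preprocessing",
      execute = function(node, sample) standardize_window(sample))
  reg("DecimationNode", "time_series", "same", "preprocessing",
      execute = function(node, sample)
        decimate_window(sample, node$params$factor %||% 1L))
  reg("LowpassFilterNode", "time_series", "same", "preprocessing",
      execute = function(node, sample)
        lowpass_filter_window(sample, node$params$cutoff_hz))

  # spatial filters -----------------------------------------------------
  reg("XDAWNNode", "time_series", "same", "spatial_filter",
      trainable = TRUE,
      train = function(node, samples) {
        node$state <- fit_xdawn(samples,
                                node$params$target_label %||% "Target",
                                node$params$retained_channels)
        node
      },
      execute = function(node, sample)
        apply_spatial_filter(node$state, sample))
  reg("CSPNode", "time_series", "same", "spatial_filter",
      trainable = TRUE,
      train = function(node, samples) {
        node$state <- fit_csp(samples, node$params$retained_channels)
        node
      },
      execute = function(node, sample)
        apply_spatial_filter(node$state, sample))
  reg("PCANode", "time_series", "same", "spatial_filter",
      trainable = TRUE,
      train = function(node, samples) {
        node$state <- fit_pca(samples, node$params$retained_channels)
        node
      },
      execute = function(node, sample)
        apply_spatial_filter(node$state, sample))

  # feature generation / postprocessing ---------------------------------
  reg("TimeDomainFeaturesNode", "time_series", "feature_vector",
      "feature_generation",
      execute = function(node, sample) extract_time_features(sample))
  reg("FeatureNormalizationNode", "feature_vector", "same", "postprocessing",
      trainable = TRUE,
      train = function(node, samples) {
        node$state <- fit_normalization(samples)
        node
      },
      execute = function(node, sample)
        apply_normalization(node$state, sample))
  reg("SigmoidMappingNode", "prediction", "same", "postprocessing",
      execute = function(node, sample)
        map_score_sigmoid(sample, node$params$scale %||% 1))

  # classification ------------------------------------------------------
  reg("LinearClassifierNode", "feature_vector", "prediction",
      "classification", trainable = TRUE,
      train = function(node, samples) {
        node$state <- train_linear_classifier(
          samples,
          complexity = node$params$complexity %||% 1,
          class_labels = unlist(node$params$class_labels) %||% NULL)
        node
      },
      execute = function(node, sample) classify(node$state, sample))

  # splitting -----------------------------------------------------------
  reg("TrainTestSplitterNode", "any", "same", "splitter", randomized = TRUE,
      execute = identity_execute)

  # meta ----------------------------------------------------------------
  reg("GridSearchNode", "feature_vector", "prediction", "meta",
      trainable = TRUE, randomized = TRUE,
      train = function(node, samples) {
        res <- grid_search(
          inner_chain_tail = node$params$nodes,
          grid = node$params$grid,
          k = node$params$folds %||% 5L,
          metric = node$params$metric %||% "balanced_accuracy",
          train = samples,
          seed = node$seed,
          positive_class = node$params$positive_class %||% "Target")
        node$state <- res
        node
      },
      execute = function(node, sample)
        apply_tail(node$state$tail, sample))

  invisible(NULL)
}

# --- inner-chain helpers for meta nodes -------------------------------------

train_tail <- function(specs, train_samples, seed) {
  nodes <- lapply(seq_along(specs), function(i)
    instantiate_node(specs[[i]], i, seed))
  cur <- train_samples
  for (i in seq_along(nodes)) {
    if (isTRUE(nodes[[i]]$meta$trainable))
      nodes[[i]] <- nodes[[i]]$meta$train(nodes[[i]], cur)
    cur <- lapply(cur, function(s) nodes[[i]]$meta$execute(nodes[[i]], s))
  }
  nodes
}

apply_tail <- function(nodes, sample) {
  for (node in nodes) sample <- node$meta$execute(node, sample)
  sample
}

#' Grid-search hyper-parameter optimization with inner cross-validation
#'
#' For every point of the parameter grid the tail of the chain (e.g. a
#' feature normalization followed by a classifier) is retrained on each of
#' `k` stratified folds of the training data and evaluated on the held-out
#' fold; the grid point with the highest mean validation metric wins (ties
#' go to the earliest point in listed order) and the tail is retrained on
#' all training data with the winning parameters.  Test samples are never
#' seen.
#'
#' @param inner_chain_tail list of node specs containing `__token__`
#'   placeholders for the tuned parameters (e.g. `complexity: __C__`).
#' @param grid named list `token -> value list` (tokens with or without the
#'   `__` delimiters).
#' @param k number of stratified folds.
#' @param metric metric name from [compute_metrics()] (e.g.
#'   `"balanced_accuracy"`).
#' @param train list of labelled training samples entering the tail.
#' @param seed integer seed for the fold assignment.
#' @param positive_class positive class for metric computation.
#' @return list with `best` (winning binding), `scores` (mean validation
#'   metric per grid point, in grid order) and `tail` (nodes retrained on
#'   all training data).
#' @export
grid_search <- function(inner_chain_tail, grid, k = 5L,
                        metric = "balanced_accuracy", train, seed = 0L,
                        positive_class = "Target") {
  if (!length(grid)) stop_sigspace("empty parameter grid")
  names(grid) <- vapply(names(grid), function(nm) {
    if (grepl("^__.*__$", nm)) nm else paste0("__", nm, "__")
  }, character(1))
  bindings <- expand_parameter_grid(grid, character())
  labels <- vapply(train, function(s) s$label %||% NA_character_,
                   character(1))
  if (anyNA(labels)) stop_sigspace("grid search needs labelled samples")
  scores <- numeric(length(bindings))
  if (length(bindings) > 1L) {
    folds <- kfold_splits(labels, k, seed = seed)
    for (bi in seq_along(bindings)) {
      specs <- substitute_binding(inner_chain_tail, bindings[[bi]])
      fold_scores <- vapply(seq_len(k), function(fi) {
        tail_nodes <- train_tail(specs, train[folds != fi], seed)
        preds <- lapply(train[folds == fi], function(s)
          apply_tail(tail_nodes, s))
        compute_metrics(preds, positive_class)[[metric]]
      }, numeric(1))
      scores[bi] <- mean(fold_scores)
    }
    best_i <- which.max(scores)   # ties: earliest listed
  } else {
    best_i <- 1L
    scores <- NA_real_
  }
  best <- bindings[[best_i]]
  tail_nodes <- train_tail(substitute_binding(inner_chain_tail, best),
                           train, seed)
  list(best = best, scores = scores, tail = tail_nodes)
}
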