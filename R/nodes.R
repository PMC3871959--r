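# Node framework.  A node is one signal-processing step with an optional
# training phase; nodes are registered under a unique name ending in
# "Node" and concatenated into chains running from a source to a sink.
# Training is strictly sequential: each trainable node sees the training
# samples as transformed by all (already trained) upstream nodes, and test
# samples never influence any trained state.

.node_registry <- new.env(parent = emptyenv())

#' Register a processing node
#'
#' Nodes register under a unique name ending in `"Node"`; lookup accepts
#' the name with or without the suffix.  Packages or analysis scripts can
#' add their own nodes at runtime.
#'
#' @param name unique node name ending in `"Node"`.
#' @param input sample kind consumed (`"stream"`, `"time_series"`,
#'   `"feature_vector"`, `"prediction"`, or `"any"`).
#' @param output sample kind produced, or `"same"` for kind-preserving
#'   nodes.
#' @param category one of `"source"`, `"sink"`, `"splitter"`,
#'   `"preprocessing"`, `"spatial_filter"`, `"feature_generation"`,
#'   `"postprocessing"`, `"classification"`, `"meta"`.
#' @param trainable does the node learn from training samples?
#' @param randomized does the node consume the run-derived random seed?
#' @param train `function(node, samples)` returning the trained node
#'   (`NULL` for non-trainable nodes).
#' @param execute `function(node, sample)` returning the processed sample.
#' @param overwrite allow re-registration (duplicate registration is an
#'   error otherwise).
#' @return the registered name, invisibly.
#' @export
register_node <- function(name, input, output, category,
                          trainable = FALSE, randomized = FALSE,
                          train = NULL, execute = NULL, overwrite = FALSE) {
  if (!grepl("Node$", name))
    stop_sigspace("node name '%s' must end with 'Node'", name)
  if (!overwrite && exists(name, envir = .node_registry, inherits = FALSE))
    stop_sigspace("node '%s' is already registered", name)
  assign(name, list(name = name, input = input, output = output,
                    category = category, trainable = trainable,
                    randomized = randomized, train = train,
                    execute = execute),
         envir = .node_registry)
  invisible(name)
}

#' List all registered node names
#' @return character vector of node names.
#' @export
list_nodes <- function() sort(ls(.node_registry))

#' Resolve a node name to its registry entry
#'
#' @param name node name, with or without the `"Node"` suffix.
#' @return the registry entry (a list with the fields of
#'   [register_node()]).  Unknown names raise an error listing the nearest
#'   registered matches.
#' @export
resolve_node <- function(name) {
  if (!is_string(name)) stop_sigspace("node name must be a string")
  full <- if (grepl("Node$", name)) name else paste0(name, "Node")
  if (exists(full, envir = .node_registry, inherits = FALSE))
    return(get(full, envir = .node_registry))
  all <- list_nodes()
  near <- all[utils::adist(tolower(full), tolower(all)) <=
                max(3L, nchar(full) %/% 3L)]
  stop_sigspace("unknown node '%s'%s", name,
                if (length(near)) paste0("; did you mean: ",
                                         paste(near, collapse = ", "))
                else "")
}

node_spec <- function(node, parameters = list()) {
  list(node = node, parameters = parameters)
}

# instantiate one chain element: registry entry + bound parameters
instantiate_node <- function(spec, position, run_index) {
  entry <- resolve_node(spec$node)
  list(name = entry$name, meta = entry,
       params = spec$parameters %||% list(),
       position = position,
       seed = derive_node_seed(run_index, position, entry$name),
       state = NULL)
}

# --- chain specs ------------------------------------------------------------

#' Read a node-chain specification from YAML
#'
#' The file holds a top-level `node_chain:` key with a list of
#' `- node: <name>` records, each with an optional `parameters:` mapping.
#' Parameter types follow YAML's automatic detection (integers stay
#' integers, strings stay strings).
#'
#' @param path YAML file, or `text` as a YAML string.
#' @param text YAML source given directly (overrides `path`).
#' @return list of node specs (each `list(node, parameters)`).
#' @export
read_node_chain <- function(path = NULL, text = NULL) {
  doc <- if (!is.null(text)) yaml::yaml.load(text) else yaml::read_yaml(path)
  chain <- doc$node_chain
  if (is.null(chain) || !length(chain))
    stop_sigspace("specification has no non-empty 'node_chain' key")
  lapply(chain, function(el) {
    if (is.null(el$node)) stop_sigspace("chain element without 'node' key")
    node_spec(el$node, el$parameters %||% list())
  })
}

#' Validate the composition of a node chain
#'
#' Checks that the chain starts with a source, ends with a sink, and that
#' each node receives the sample kind it consumes.  A trainable node with
#' no splitter upstream is flagged with a warning (all samples default to
#' test, so such a node would see no training data).
#'
#' @param chain list of node specs (see [read_node_chain()]).
#' @param input_kind kind of the input dataset.
#' @return list with `ok` (logical), `errors` and `warnings` (character
#'   vectors); the first offending edge is named in `errors`.
#' @export
check_chain <- function(chain, input_kind) {
  errors <- character(); warnings <- character()
  if (length(chain) < 2L)
    return(list(ok = FALSE, errors = "chain needs at least source and sink",
                warnings = warnings))
  entries <- lapply(chain, function(sp) resolve_node(sp$node))
  if (entries[[1]]$category != "source")
    errors <- c(errors, "chain must start with a source node")
  if (entries[[length(entries)]]$category != "sink")
    errors <- c(errors, "chain must end with a sink node")
  n_sources <- sum(vapply(entries, function(e) e$category == "source",
                          logical(1)))
  n_sinks <- sum(vapply(entries, function(e) e$category == "sink",
                        logical(1)))
  if (n_sources != 1L || n_sinks != 1L)
    errors <- c(errors, "chain must contain exactly one source and one sink")
  kind <- input_kind
  seen_splitter <- FALSE
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    if (!identical(e$input, "any") && !identical(e$input, kind)) {
      errors <- c(errors, sprintf(
        "edge %d: %s needs %s input but receives %s",
        i - 1L, e$name, e$input, kind))
      break
    }
    if (e$category == "splitter") seen_splitter <- TRUE
    if (e$trainable && !seen_splitter)
      warnings <- c(warnings, sprintf(
        "%s: no splitter upstream; all samples default to test", e$name))
    kind <- if (identical(e$output, "same")) kind else e$output
  }
  list(ok = !length(errors), errors = errors, warnings = warnings)
}

# --- chain execution --------------------------------------------------------

#' Execute a node chain on a dataset
#'
#' Samples start flagged as test data; a splitter node reassigns flags.
#' Each trainable node is trained (in chain order) on the training samples
#' as transformed by all upstream nodes, then every sample is pushed
#' through.  The sink gathers the output dataset; a performance sink also
#' computes metrics separately for the training and test samples.  The run
#' index seeds every randomized node, so `(chain, dataset, run_index)`
#' fully determines the output.
#'
#' @param chain list of node specs (see [read_node_chain()]).
#' @param dataset input [sp_dataset()].
#' @param run_index repetition index used for seeding (default 0).
#' @return list with `dataset` (the sink's output [sp_dataset()]),
#'   `metrics` (list with `train`/`test` [compute_metrics()] records, or
#'   `NULL` for plain sinks) and `flags` (final train/test assignment).
#' @export
run_node_chain <- function(chain, dataset, run_index = 0L) {
  stopifnot(inherits(dataset, "sp_dataset"))
  report <- check_chain(chain, dataset$kind)
  if (!report$ok)
    stop_sigspace("invalid chain: %s", paste(report$errors, collapse = "; "))
  nodes <- lapply(seq_along(chain), function(i)
    instantiate_node(chain[[i]], i, run_index))
  samples <- dataset$samples
  flags <- rep("test", length(samples))
  metrics <- NULL
  out_dataset <- NULL
  for (i in seq_along(nodes)) {
    node <- nodes[[i]]
    cat_i <- node$meta$category
    if (cat_i == "source") next
    if (cat_i == "splitter") {
      labels <- vapply(samples, function(s) {
        lb <- if (inherits(s, "prediction_vector")) s$true_label else s$label
        lb %||% NA_character_
      }, character(1))
      if (anyNA(labels))
        stop_sigspace("%s: unlabelled samples cannot be split", node$name)
      flags <- split_train_test(
        labels,
        train_fraction = node$params$train_fraction %||% 0.5,
        seed = node$seed)
      next
    }
    if (cat_i == "sink") {
      kind <- sample_kind(samples[[1]])
      out_dataset <- sp_dataset(kind, samples,
                                metadata = dataset$metadata[
                                  setdiff(names(dataset$metadata),
                                          c("kind", "channel_names",
                                            "feature_names"))])
      out_dataset <- append_history(out_dataset, "node_chain")
      if (identical(node$name, "PerformanceSinkNode")) {
        if (kind != "prediction")
          stop_sigspace("PerformanceSinkNode requires prediction input")
        pos <- node$params$positive_class %||% "Target"
        metrics <- list(
          train = if (any(flags == "train"))
            compute_metrics(samples[flags == "train"], pos) else NULL,
          test = if (any(flags == "test"))
            compute_metrics(samples[flags == "test"], pos) else NULL)
      }
      next
    }
    if (isTRUE(node$meta$trainable)) {
      train_samples <- samples[flags == "train"]
      if (!length(train_samples))
        stop_sigspace("%s: no training data; insert a splitter upstream",
                      node$name)
      node <- node$meta$train(node, train_samples)
    }
    samples <- lapply(samples, function(s) {
      out <- node$meta$execute(node, s)
      if (sample_kind(out) != sample_kind(s) &&
          !identical(node$meta$output, sample_kind(out)) &&
          !identical(node$meta$output, "same"))
        stop_sigspace("%s produced unexpected sample kind", node$name)
      out
    })
    nodes[[i]] <- node
  }
  list(dataset = out_dataset, metrics = metrics, flags = flags)
}
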