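# Operations: high-level jobs that map an input summary of datasets to an
# output summary by expanding a parameterized node-chain template over a
# constrained parameter grid with seeded repetitions, running the
# resulting independent processes on a back-end, and consolidating the
# per-process metrics into one results table.

# --- range expressions ------------------------------------------------------

#' Expand a `range(a, b[, s])` expression
#'
#' Mirrors Python's `range` semantics: the arithmetic sequence
#' `a, a + s, ...` strictly below `b` for positive step (strictly above for
#' negative step).  `range(2, 63, 2)` gives the even numbers from 2 to 62.
#' An empty result is a configuration error, as is a zero step.
#'
#' @param expr string of the form `"range(a, b)"` or `"range(a, b, s)"`
#'   with integer literals.
#' @return integer vector.
#' @export
expand_range_expression <- function(expr) {
  m <- regmatches(expr, regexec(
    "^\\s*range\\(\\s*(-?\\d+)\\s*,\\s*(-?\\d+)\\s*(?:,\\s*(-?\\d+)\\s*)?\\)\\s*$",
    expr))[[1]]
  if (length(m) == 0L)
    stop_sigspace("malformed range expression: '%s'", expr)
  a <- as.integer(m[2]); b <- as.integer(m[3])
  s <- if (nzchar(m[4])) as.integer(m[4]) else 1L
  if (s == 0L) stop_sigspace("range step must not be zero")
  vals <- if (s > 0L) {
    if (a >= b) integer() else seq.int(a, b - 1L, by = s)
  } else {
    if (a <= b) integer() else seq.int(a, b + 1L, by = s)
  }
  if (!length(vals))
    stop_sigspace("empty parameter range: '%s'", expr)
  vals
}

expand_value_set <- function(v) {
  if (is.character(v) && length(v) == 1L && grepl("^\\s*range\\(", v))
    return(as.list(expand_range_expression(v)))
  if (is.list(v)) v else as.list(v)
}

# --- constraint mini-language -----------------------------------------------
# Boolean combinations (and / or / not, parentheses) of comparisons
# (==, !=, <, <=, >, >=) between `__token__` references and literals.
# Evaluated by a recursive-descent interpreter; no code execution.

tokenize_constraint <- function(src) {
  pats <- c(
    ws = "^\\s+",
    num = "^-?\\d+(\\.\\d+)?",
    str = "^(\"[^\"]*\"|'[^']*')",
    op = "^(==|!=|<=|>=|<|>)",
    lpar = "^\\(", rpar = "^\\)",
    ident = "^[A-Za-z_][A-Za-z0-9_]*"
  )
  toks <- list()
  while (nzchar(src)) {
    matched <- FALSE
    for (ty in names(pats)) {
      m <- regmatches(src, regexpr(pats[[ty]], src, perl = TRUE))
      if (length(m) && nzchar(m)) {
        if (ty != "ws") {
          val <- m
          if (ty == "ident" && tolower(val) %in% c("and", "or", "not"))
            ty <- tolower(val)
          toks[[length(toks) + 1L]] <- list(type = ty, text = m)
        }
        src <- substring(src, nchar(m) + 1L)
        matched <- TRUE
        break
      }
    }
    if (!matched) stop_sigspace("cannot tokenize constraint near '%s'", src)
  }
  toks
}

parse_constraint <- function(src) {
  toks <- tokenize_constraint(src)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  advance <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }
  expect <- function(type) {
    t <- peek()
    if (is.null(t) || t$type != type)
      stop_sigspace("constraint parse error: expected %s in '%s'", type, src)
    advance()
  }
  parse_primary <- function() {
    t <- peek()
    if (is.null(t)) stop_sigspace("unexpected end of constraint '%s'", src)
    if (t$type == "lpar") {
      advance(); e <- parse_or(); expect("rpar"); return(e)
    }
    if (t$type == "num") { advance(); return(list(k = "num", v = as.numeric(t$text))) }
    if (t$type == "str") {
      advance()
      return(list(k = "str", v = substr(t$text, 2L, nchar(t$text) - 1L)))
    }
    if (t$type == "ident") { advance(); return(list(k = "ref", v = t$text)) }
    stop_sigspace("constraint parse error at '%s'", t$text)
  }
  parse_cmp <- function() {
    lhs <- parse_primary()
    t <- peek()
    if (!is.null(t) && t$type == "op") {
      advance()
      rhs <- parse_primary()
      return(list(k = "cmp", op = t$text, lhs = lhs, rhs = rhs))
    }
    lhs
  }
  parse_not <- function() {
    t <- peek()
    if (!is.null(t) && t$type == "not") { advance(); return(list(k = "not", e = parse_not())) }
    parse_cmp()
  }
  parse_and <- function() {
    e <- parse_not()
    while (!is.null(peek()) && peek()$type == "and") {
      advance(); e <- list(k = "and", lhs = e, rhs = parse_not())
    }
    e
  }
  parse_or <- function() {
    e <- parse_and()
    while (!is.null(peek()) && peek()$type == "or") {
      advance(); e <- list(k = "or", lhs = e, rhs = parse_and())
    }
    e
  }
  out <- parse_or()
  if (pos <= length(toks))
    stop_sigspace("trailing input in constraint '%s'", src)
  out
}

eval_constraint_ast <- function(ast, binding) {
  value_of <- function(node) {
    switch(node$k,
      num = node$v,
      str = node$v,
      ref = {
        key <- if (grepl("^__.*__$", node$v)) node$v
               else paste0("__", node$v, "__")
        if (!key %in% names(binding))
          stop_sigspace("constraint references unknown token '%s'", node$v)
        binding[[key]]
      },
      stop_sigspace("constraint value expected"))
  }
  ev <- function(node) {
    switch(node$k,
      "and" = ev(node$lhs) && ev(node$rhs),
      "or" = ev(node$lhs) || ev(node$rhs),
      "not" = !ev(node$e),
      "cmp" = {
        a <- value_of(node$lhs); b <- value_of(node$rhs)
        if (is.numeric(a) && is.numeric(b)) { a <- as.numeric(a); b <- as.numeric(b) }
        else { a <- as.character(a); b <- as.character(b) }
        switch(node$op,
               "==" = isTRUE(a == b), "!=" = isTRUE(a != b),
               "<" = isTRUE(a < b), "<=" = isTRUE(a <= b),
               ">" = isTRUE(a > b), ">=" = isTRUE(a >= b))
      },
      stop_sigspace("constraint must be a boolean expression"))
  }
  ev(ast)
}

#' Evaluate one constraint expression against a parameter binding
#'
#' @param expr constraint source, e.g.
#'   `'__alg__ != "Noop" or __channels__ == 2'`.
#' @param binding named list `token -> value`.
#' @return logical scalar.
#' @export
evaluate_constraint <- function(expr, binding) {
  eval_constraint_ast(parse_constraint(expr), binding)
}

# --- grid expansion ---------------------------------------------------------

#' Expand parameter ranges into the constrained Cartesian grid
#'
#' The product is enumerated in token-declaration order (the first token
#' varies slowest) with values in listed order; each binding is kept iff
#' all constraint expressions evaluate to true.
#'
#' @param ranges named list `token -> value list` (values may be given as a
#'   `"range(a, b, s)"` string).
#' @param constraints character vector of constraint expressions.
#' @return list of bindings (named lists), deterministic order.
#' @export
expand_parameter_grid <- function(ranges, constraints = character()) {
  if (!length(ranges)) stop_sigspace("parameter_ranges must be non-empty")
  sets <- lapply(ranges, expand_value_set)
  for (nm in names(sets)) {
    if (!length(sets[[nm]]))
      stop_sigspace("empty parameter range for token '%s'", nm)
  }
  bindings <- list(structure(list(), names = character()))
  for (nm in names(sets)) {
    nxt <- list()
    for (b in bindings) {
      for (v in sets[[nm]]) {
        b2 <- b; b2[[nm]] <- v
        nxt[[length(nxt) + 1L]] <- b2
      }
    }
    bindings <- nxt
  }
  asts <- lapply(constraints, parse_constraint)
  if (length(asts)) {
    keep <- vapply(bindings, function(b)
      all(vapply(asts, eval_constraint_ast, logical(1), binding = b)),
      logical(1))
    bindings <- bindings[keep]
  }
  if (!length(bindings))
    stop_sigspace("all bindings removed: empty final grid")
  bindings
}

# --- template instantiation -------------------------------------------------

# Recursively substitute __token__ placeholders.  A string equal to a token
# takes the bound value with its type preserved; tokens embedded in longer
# strings are textually replaced.
substitute_binding <- function(x, binding) {
  if (is.list(x)) return(lapply(x, substitute_binding, binding = binding))
  if (is.character(x) && length(x) == 1L) {
    for (tok in names(binding)) {
      if (identical(x, tok)) return(binding[[tok]])
    }
    for (tok in names(binding)) {
      x <- gsub(tok, as.character(binding[[tok]]), x, fixed = TRUE)
    }
  }
  x
}

find_unbound_tokens <- function(x) {
  toks <- character()
  walk <- function(v) {
    if (is.list(v)) { lapply(v, walk); return(invisible()) }
    if (is.character(v)) {
      m <- regmatches(v, gregexpr("__[A-Za-z][A-Za-z0-9_]*?__", v))[[1]]
      toks <<- c(toks, m)
    }
    invisible()
  }
  walk(x)
  unique(toks)
}

#' Bind a parameterized node-chain template
#'
#' Parses the YAML template, substitutes every `__token__` placeholder with
#' its bound value (numbers stay numbers, strings stay strings), and
#' optionally validates the resulting chain.
#'
#' @param template node-chain YAML text, or a pre-parsed chain spec list.
#' @param binding named list `token -> value` covering every token in the
#'   template.
#' @param input_kind if given, the bound chain is [check_chain()]-validated
#'   against this input kind.
#' @return list of node specs.
#' @export
instantiate_template <- function(template, binding, input_kind = NULL) {
  chain <- if (is.character(template)) read_node_chain(text = template)
           else template
  chain <- substitute_binding(chain, binding)
  left <- find_unbound_tokens(chain)
  if (length(left))
    stop_sigspace("unbound template token(s): %s",
                  paste(left, collapse = ", "))
  if (!is.null(input_kind)) {
    report <- check_chain(chain, input_kind)
    if (!report$ok)
      stop_sigspace("template instantiates to an invalid chain: %s",
                    paste(report$errors, collapse = "; "))
  }
  chain
}

# --- operation specs and processes ------------------------------------------

#' Read an operation specification from YAML
#'
#' Recognised keys: `type` (`node_chain`, `merge`, `shuffle`),
#' `input_path`, `template` (path to a node-chain YAML, resolved relative
#' to the spec file, or an inline `node_chain` mapping),
#' `parameter_ranges`, `constraints`, `runs`, and for the reorganizing
#' operations `seed` and `group_regex`.
#'
#' @param path operation YAML file.
#' @return an object of class `operation_spec`.
#' @export
read_operation_spec <- function(path) {
  doc <- yaml::read_yaml(path)
  template_text <- NULL
  if (!is.null(doc$template)) {
    if (is.character(doc$template)) {
      tpath <- doc$template
      if (!file.exists(tpath))
        tpath <- file.path(dirname(path), doc$template)
      if (!file.exists(tpath))
        stop_sigspace("template file not found: %s", doc$template)
      template_text <- paste(readLines(tpath), collapse = "\n")
    } else {
      template_text <- yaml::as.yaml(doc$template)
    }
  }
  operation_spec(
    type = doc$type %||% "node_chain",
    input_path = doc$input_path,
    template = template_text,
    parameter_ranges = doc$parameter_ranges %||% list(),
    constraints = as.character(unlist(doc$constraints %||% character())),
    runs = doc$runs %||% 1L,
    seed = doc$seed %||% 0L,
    group_regex = doc$group_regex,
    name = tools::file_path_sans_ext(basename(path)))
}

#' Construct an operation specification in code
#'
#' @param type operation type: `"node_chain"`, `"merge"` or `"shuffle"`.
#' @param input_path summary directory the operation consumes.
#' @param template node-chain YAML text with `__token__` placeholders
#'   (node-chain operations only).
#' @param parameter_ranges named list `token -> value list` or range
#'   expression string.
#' @param constraints character vector of constraint expressions.
#' @param runs number of seeded repetitions (`run_index` 0..runs-1; the
#'   run index seeds all randomized nodes).
#' @param seed seed for reorganizing operations (shuffle).
#' @param group_regex optional regex with one capture group mapping dataset
#'   names to merge groups.
#' @param name operation name used for the result folder.
#' @return an object of class `operation_spec`.
#' @export
operation_spec <- function(type = "node_chain", input_path = NULL,
                           template = NULL, parameter_ranges = list(),
                           constraints = character(), runs = 1L,
                           seed = 0L, group_regex = NULL,
                           name = "operation") {
  type <- match.arg(type, c("node_chain", "merge", "shuffle"))
  if (!is_count(runs)) stop_sigspace("runs must be a positive integer")
  if (type == "node_chain") {
    if (is.null(template)) stop_sigspace("node_chain operation needs a template")
    toks <- find_unbound_tokens(read_node_chain(text = template))
    missing <- setdiff(toks, names(parameter_ranges))
    if (length(missing))
      stop_sigspace("template token(s) missing from parameter_ranges: %s",
                    paste(missing, collapse = ", "))
  }
  structure(
    list(type = type, input_path = input_path, template = template,
         parameter_ranges = parameter_ranges, constraints = constraints,
         runs = as.integer(runs), seed = seed, group_regex = group_regex,
         name = name),
    class = "operation_spec")
}

encode_path_component <- function(x) {
  x <- as.character(x)
  gsub("[^A-Za-z0-9._=,+-]", "_", x)
}

binding_subpath <- function(binding) {
  if (!length(binding)) return("default")
  paste(vapply(names(binding), function(tok) {
    sprintf("%s=%s", strip_token(tok),
            encode_path_component(binding[[tok]]))
  }, character(1)), collapse = ",")
}

#' Expand an operation into its independent process descriptors
#'
#' One descriptor per (dataset, parameter binding, run index); the run
#' index doubles as the seed of the process.  The descriptor list is a
#' pure function of the specification and the summary.
#'
#' @param spec a node-chain [operation_spec()].
#' @param summary the input [sp_summary()] (non-empty).
#' @return list of process descriptors, each with fields `dataset`,
#'   `binding`, `run_index`, `chain`, `out_subpath`.
#' @export
create_processes <- function(spec, summary) {
  stopifnot(inherits(spec, "operation_spec"), inherits(summary, "sp_summary"))
  if (!length(summary$datasets)) stop_sigspace("input summary is empty")
  bindings <- if (length(spec$parameter_ranges)) {
    expand_parameter_grid(spec$parameter_ranges, spec$constraints)
  } else list(structure(list(), names = character()))
  template_chain <- read_node_chain(text = spec$template)
  processes <- list()
  for (ds in names(summary$datasets)) {
    for (b in bindings) {
      chain <- instantiate_template(template_chain, b)
      for (r in seq_len(spec$runs) - 1L) {
        processes[[length(processes) + 1L]] <- list(
          dataset = ds, binding = b, run_index = r, chain = chain,
          out_subpath = file.path(ds, binding_subpath(b),
                                  sprintf("run%d", r)))
      }
    }
  }
  processes
}

# executed by the back-end workers; must only touch its own sub-path
run_process <- function(pd, input_root, result_root) {
  tryCatch({
    dataset <- read_dataset(file.path(input_root, pd$dataset))
    res <- run_node_chain(pd$chain, dataset, run_index = pd$run_index)
    out_dir <- file.path(result_root, pd$out_subpath)
    write_dataset(res$dataset, out_dir)
    if (!is.null(res$metrics)) {
      yaml::write_yaml(
        lapply(Filter(Negate(is.null), res$metrics), unclass),
        file.path(out_dir, "metrics.yaml"))
    }
    list(success = TRUE, dataset = pd$dataset, binding = pd$binding,
         run_index = pd$run_index, out_subpath = pd$out_subpath,
         metrics = res$metrics, error = NULL)
  }, error = function(e) {
    list(success = FALSE, dataset = pd$dataset, binding = pd$binding,
         run_index = pd$run_index, out_subpath = pd$out_subpath,
         metrics = NULL, error = conditionMessage(e))
  })
}

# --- running operations -----------------------------------------------------

result_dir_name <- function(root, name) {
  stamp <- format(Sys.time(), "%Y%m%d_%H%M%S", tz = "UTC")
  path <- file.path(root, paste(name, stamp, sep = "_"))
  i <- 1L
  while (dir.exists(path)) {
    path <- file.path(root, paste(name, stamp, i, sep = "_"))
    i <- i + 1L
  }
  path
}

#' Run one operation
#'
#' Node-chain operations expand their template over the parameter grid,
#' execute every (dataset, binding, run) process on the back-end, and
#' consolidate metrics, spec archive and compressed process folders into a
#' time-stamped result directory.  Merge and shuffle operations reorganize
#' the input summary and write the new summary.
#'
#' @param spec an [operation_spec()].
#' @param backend a [backend()] (default serial).
#' @param output_root directory in which the time-stamped result folder is
#'   created.
#' @return list with `result_dir`, `outcomes` (node-chain only), `table`
#'   (the results table) and, for reorganizing operations, the output
#'   `summary`.
#' @export
run_operation <- function(spec, backend = backend("serial"),
                          output_root = ".") {
  stopifnot(inherits(spec, "operation_spec"))
  summary <- read_summary(spec$input_path)
  result_dir <- result_dir_name(output_root, spec$name)
  dir.create(result_dir, recursive = TRUE)
  if (spec$type == "merge") {
    group_by <- if (is.null(spec$group_regex)) function(name) "merged"
      else function(name) {
        m <- regmatches(name, regexec(spec$group_regex, name))[[1]]
        if (length(m) >= 2L) m[2] else name
      }
    out <- merge_datasets(summary, group_by)
    write_summary(out, result_dir)
    out$root_path <- result_dir
    return(list(result_dir = result_dir, summary = out))
  }
  if (spec$type == "shuffle") {
    out <- shuffle_datasets(summary, seed = spec$seed)
    write_summary(out, result_dir)
    out$root_path <- result_dir
    return(list(result_dir = result_dir, summary = out))
  }
  processes <- create_processes(spec, summary)
  outcomes <- execute_processes(processes, backend,
                                input_root = spec$input_path,
                                result_root = result_dir)
  table <- consolidate(result_dir, outcomes, spec)
  list(result_dir = result_dir, outcomes = outcomes, table = table)
}

#' Consolidate a finished operation's result directory
#'
#' Writes `results.csv` (one row per successful process), a `failures.yaml`
#' manifest, archives the operation spec and template for replicability
#' (`specs.tar.gz`), and compresses every process folder except the first,
#' which is kept uncompressed as an example.
#'
#' @param result_dir the operation's result directory.
#' @param outcomes outcome list from [execute_processes()].
#' @param spec the [operation_spec()] that produced the outcomes.
#' @return the results table, invisibly.
#' @export
consolidate <- function(result_dir, outcomes, spec) {
  table <- aggregate_results(outcomes, names(spec$parameter_ranges))
  write_results_csv(table, file.path(result_dir, "results.csv"))
  failures <- Filter(function(oc) !isTRUE(oc$success), outcomes)
  yaml::write_yaml(
    lapply(failures, function(oc)
      list(dataset = oc$dataset, run = oc$run_index,
           binding = oc$binding, error = oc$error)),
    file.path(result_dir, "failures.yaml"))
  # archive the processing specification for replicability
  spec_dir <- file.path(result_dir, "specs")
  dir.create(spec_dir, showWarnings = FALSE)
  yaml::write_yaml(
    list(type = spec$type, input_path = spec$input_path,
         parameter_ranges = spec$parameter_ranges,
         constraints = as.list(spec$constraints), runs = spec$runs,
         version = as.character(utils::packageVersion("sigspace"))),
    file.path(spec_dir, "operation.yaml"))
  if (!is.null(spec$template))
    writeLines(spec$template, file.path(spec_dir, "template.yaml"))
  archive_dir(result_dir, "specs", "specs.tar.gz")
  unlink(spec_dir, recursive = TRUE)
  # compress process folders, keeping the first as an uncompressed example
  ok <- Filter(function(oc) isTRUE(oc$success), outcomes)
  paths <- sort(vapply(ok, function(oc) oc$out_subpath, character(1)))
  for (sub in paths[-1]) {
    archive_dir(result_dir, sub, paste0(sub, ".tar.gz"))
    unlink(file.path(result_dir, sub), recursive = TRUE)
  }
  invisible(table)
}

# tar.gz a sub-directory of root (R's internal tar; no external zip needed)
archive_dir <- function(root, subdir, tarname) {
  old <- setwd(root)
  on.exit(setwd(old))
  utils::tar(tarname, files = subdir, compression = "gzip",
             tar = "internal")
}

#' Run a sequential chain of operations
#'
#' The first operation takes the given input summary; every following
#' operation consumes the output summary of its predecessor.  Operations
#' are never inter-parallelized; intermediate results are retained on disk.
#' The chain aborts at the first failing operation, keeping completed
#' outputs.
#'
#' @param specs list of [operation_spec()] objects; `input_path` of the
#'   first must be set.
#' @param backend a [backend()].
#' @param output_root directory for the result folders.
#' @return result list of the final operation, with `intermediate` holding
#'   the result directories of all operations.
#' @export
run_operation_chain <- function(specs, backend = backend("serial"),
                                output_root = ".") {
  if (!length(specs)) stop_sigspace("empty operation chain")
  dirs <- character()
  res <- NULL
  input <- specs[[1]]$input_path
  for (sp in specs) {
    sp$input_path <- input
    res <- run_operation(sp, backend, output_root)
    dirs <- c(dirs, res$result_dir)
    input <- res$result_dir
  }
  res$intermediate <- dirs
  res
}
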