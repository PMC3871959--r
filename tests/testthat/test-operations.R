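# Operations engine: range expressions, constrained grids, templating,
# process creation, execution, consolidation, operation chains.

test_that("range expressions mirror the printed semantics", {
  ev <- expand_range_expression("range(2, 63, 2)")
  expect_equal(ev, seq(2L, 62L, 2L))
  expect_equal(max(ev), 62L)
  expect_length(ev, 31L)
  expect_equal(expand_range_expression("range(0, 3)"), 0:2)
  expect_equal(expand_range_expression("range(5, 0, -2)"), c(5L, 3L, 1L))
  expect_error(expand_range_expression("range(5, 5)"), "empty")
  expect_error(expand_range_expression("range(1, 9, 0)"), "zero")
  expect_error(expand_range_expression("range(1; 9)"), "malformed")
})

test_that("grid expansion: order, constraints, brute-force equality", {
  grid <- expand_parameter_grid(list(`__alg__` = list("A", "B"),
                                     `__channels__` = list(2L, 4L, 6L)))
  expect_length(grid, 6L)
  # declaration order: first token slowest, values in listed order
  expect_equal(vapply(grid, `[[`, character(1), "__alg__"),
               rep(c("A", "B"), each = 3))
  expect_equal(vapply(grid, `[[`, integer(1), "__channels__"),
               rep(c(2L, 4L, 6L), 2))
  constrained <- expand_parameter_grid(
    list(`__alg__` = list("xDAWN", "Noop"), `__channels__` = list(2L, 4L)),
    constraints = '__alg__ != "Noop" or __channels__ == 2')
  expect_length(constrained, 3L)
  # brute-force enumeration oracle
  brute <- expand.grid(alg = c("xDAWN", "Noop"), ch = c(2L, 4L),
                       stringsAsFactors = FALSE)
  keep <- brute$alg != "Noop" | brute$ch == 2L
  expect_equal(length(constrained), sum(keep))
  expect_error(
    expand_parameter_grid(list(`__a__` = list(1)),
                          constraints = "__b__ == 1"),
    "unknown token")
  expect_error(
    expand_parameter_grid(list(`__a__` = list(1, 2)),
                          constraints = "__a__ > 5"),
    "empty final grid")
})

test_that("the channel-sweep constraint pattern yields 125 bindings", {
  grid <- expand_parameter_grid(
    list(`__alg__` = list("XDAWN", "CSP", "PCA", "ICA", "Noop"),
         `__channels__` = "range(2, 63, 2)"),
    constraints = '__alg__ != "Noop" or __channels__ == 2')
  expect_length(grid, 4 * 31 + 1)
  # brute force over the full 5 x 31 product
  full <- expand_parameter_grid(
    list(`__alg__` = list("XDAWN", "CSP", "PCA", "ICA", "Noop"),
         `__channels__` = "range(2, 63, 2)"))
  keep <- vapply(full, function(b)
    evaluate_constraint('__alg__ != "Noop" or __channels__ == 2', b),
    logical(1))
  expect_equal(length(grid), sum(keep))
})

test_that("constraint mini-language: boolean operators and errors", {
  b <- list(`__alg__` = "Noop", `__channels__` = 4L)
  expect_false(evaluate_constraint(
    '__alg__ != "Noop" or __channels__ == 2', b))
  expect_true(evaluate_constraint(
    'not (__alg__ == "Noop" and __channels__ > 2) or __channels__ >= 4', b))
  expect_true(evaluate_constraint("__channels__ <= 4 and __channels__ > 3",
                                  b))
  expect_error(evaluate_constraint("__channels__ ==", b), "constraint")
  expect_error(evaluate_constraint("__channels__ == 2 extra", b),
               "trailing")
})

test_that("template instantiation preserves value types", {
  tpl <- "
node_chain:
  - node: TimeSeriesSource
  - node: __alg__
    parameters: {retained_channels: __channels__}
  - node: TimeSeriesSink
"
  chain <- instantiate_template(tpl, list(`__alg__` = "XDAWN",
                                          `__channels__` = 8L))
  expect_equal(chain[[2]]$node, "XDAWN")
  expect_identical(chain[[2]]$parameters$retained_channels, 8L)  # not "8"
  expect_error(instantiate_template(tpl, list(`__alg__` = "XDAWN")),
               "__channels__")
  # validation of the instantiated chain
  expect_error(instantiate_template(tpl, list(`__alg__` = "LinearClassifier",
                                              `__channels__` = 2L),
                                    input_kind = "time_series"),
               "invalid chain")
})

make_summary_dir <- function(dir, n1 = 10L, n2 = 8L) {
  write_summary(sp_summary(list(
    setA = sp_dataset("feature_vector",
                      generate_gaussian_features(n1, 3L, 4, seed = 1)$samples),
    setB = sp_dataset("feature_vector",
                      generate_gaussian_features(n2, 3L, 4, seed = 2)$samples)
  )), dir)
  dir
}

fv_template <- "
node_chain:
  - node: FeatureVectorSource
  - node: TrainTestSplitter
    parameters: {train_fraction: 0.5}
  - node: LinearClassifier
    parameters: {complexity: __C__}
  - node: PerformanceSink
"

test_that("create_processes enumerates dataset x binding x run", {
  dir <- withr::local_tempdir()
  make_summary_dir(file.path(dir, "in"))
  spec <- operation_spec(input_path = file.path(dir, "in"),
                         template = fv_template,
                         parameter_ranges = list(`__C__` = list(0.1, 1, 10)),
                         runs = 2L, name = "op")
  summary <- read_summary(file.path(dir, "in"))
  procs <- create_processes(spec, summary)
  expect_length(procs, 2 * 3 * 2)
  expect_equal(unique(vapply(procs, `[[`, integer(1), "run_index")), 0:1)
  expect_length(unique(vapply(procs, `[[`, character(1), "out_subpath")),
                12L)
  expect_match(procs[[1]]$out_subpath, "^setA/C=0.1/run0$")
  # determinism of the descriptor list
  expect_identical(procs, create_processes(spec, summary))
  # template token missing from parameter_ranges is caught at spec time
  expect_error(operation_spec(input_path = file.path(dir, "in"),
                              template = fv_template,
                              parameter_ranges = list(),
                              name = "bad"),
               "__C__")
})

test_that("run_operation produces the consolidated result layout", {
  dir <- withr::local_tempdir()
  make_summary_dir(file.path(dir, "in"))
  spec <- operation_spec(input_path = file.path(dir, "in"),
                         template = fv_template,
                         parameter_ranges = list(`__C__` = list(0.1, 10)),
                         runs = 2L, name = "layout")
  res <- run_operation(spec, backend("serial"), output_root = dir)
  expect_true(dir.exists(res$result_dir))
  expect_match(basename(res$result_dir), "^layout_\\d{8}_\\d{6}")
  # results.csv: one row per successful process
  tbl <- read_results_csv(file.path(res$result_dir, "results.csv"))
  expect_equal(nrow(tbl), 8L)
  expect_true(all(tbl$Test_balanced_accuracy >= 0 &
                    tbl$Test_balanced_accuracy <= 1))
  # spec archive present
  expect_true(file.exists(file.path(res$result_dir, "specs.tar.gz")))
  # exactly one uncompressed example process folder remains
  run_dirs <- list.dirs(res$result_dir, recursive = TRUE)
  run_dirs <- run_dirs[grepl("run\\d+$", run_dirs)]
  expect_length(run_dirs, 1L)
  archives <- list.files(res$result_dir, pattern = "^run\\d+\\.tar\\.gz$",
                         recursive = TRUE)
  expect_length(archives, 7L)
  expect_true(file.exists(file.path(res$result_dir, "failures.yaml")))
})

test_that("a failing process never aborts its siblings", {
  dir <- withr::local_tempdir()
  make_summary_dir(file.path(dir, "in"))
  # classifier complexity -1 is invalid -> that binding's processes fail
  spec <- operation_spec(input_path = file.path(dir, "in"),
                         template = fv_template,
                         parameter_ranges = list(`__C__` = list(1, -1)),
                         runs = 1L, name = "failing")
  res <- run_operation(spec, backend("serial"), output_root = dir)
  ok <- vapply(res$outcomes, function(oc) isTRUE(oc$success), logical(1))
  expect_equal(sum(ok), 2L)
  expect_equal(sum(!ok), 2L)
  expect_equal(nrow(res$table), 2L)
  failures <- yaml::read_yaml(file.path(res$result_dir, "failures.yaml"))
  expect_length(failures, 2L)
  expect_match(failures[[1]]$error, "complexity")
})

test_that("operation YAML files load and launch end to end", {
  dir <- withr::local_tempdir()
  make_summary_dir(file.path(dir, "in"))
  writeLines(fv_template, file.path(dir, "chain.yaml"))
  writeLines(sprintf("
type: node_chain
input_path: %s
template: chain.yaml
parameter_ranges:
  __C__: [1]
runs: 1
", file.path(dir, "in")), file.path(dir, "op.yaml"))
  res <- launch(file.path(dir, "op.yaml"), output_root = dir)
  expect_equal(nrow(res$table), 2L)
  expect_match(basename(res$result_dir), "^op_")
})

test_that("operation chains feed each output summary forward", {
  dir <- withr::local_tempdir()
  # two feature datasets merged into one, then classified
  make_summary_dir(file.path(dir, "in"))
  chain_specs <- list(
    operation_spec(type = "merge", input_path = file.path(dir, "in"),
                   name = "merge"),
    operation_spec(type = "node_chain", template = fv_template,
                   parameter_ranges = list(`__C__` = list(1)),
                   runs = 1L, name = "classify"))
  res <- run_operation_chain(chain_specs, backend("serial"),
                             output_root = dir)
  expect_length(res$intermediate, 2L)
  tbl <- res$table
  expect_equal(nrow(tbl), 1L)               # one merged dataset, one run
  expect_equal(tbl$Dataset, "merged")
  # merged dataset saw all 36 samples
  expect_equal(tbl$Train_n_samples + tbl$Test_n_samples, 36)
})
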