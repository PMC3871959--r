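# Command-line style entry point mirroring `launch -o my_operation.yaml
# --mcore`: one function that takes an operation (or operation chain)
# specification file and a back-end flag.

#' Launch an operation or operation chain from a specification file
#'
#' The YAML file either holds a single operation (see
#' [read_operation_spec()]) or a top-level `operation_chain:` list of
#' operation file paths, executed sequentially.
#'
#' @param spec_file path to the YAML specification.
#' @param mcore use the multicore back-end instead of the serial default
#'   (mirrors the `--mcore` command-line flag).
#' @param worker_count workers for the multicore back-end.
#' @param output_root directory for time-stamped result folders.
#' @return the result of [run_operation()] / [run_operation_chain()].
#' @export
launch <- function(spec_file, mcore = FALSE, worker_count = NULL,
                   output_root = ".") {
  be <- backend(if (isTRUE(mcore)) "mcore" else "serial",
                worker_count = worker_count)
  doc <- yaml::read_yaml(spec_file)
  if (!is.null(doc$operation_chain)) {
    paths <- vapply(doc$operation_chain, as.character, character(1))
    paths <- ifelse(file.exists(paths), paths,
                    file.path(dirname(spec_file), paths))
    specs <- lapply(paths, read_operation_spec)
    return(run_operation_chain(specs, be, output_root))
  }
  run_operation(read_operation_spec(spec_file), be, output_root)
}
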