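# Execution back-ends.  Processes are pairwise independent (each writes
# only its own result sub-path), so they can run serially or fan out over
# local CPU cores; both back-ends must produce identical outcome payloads.

#' Construct an execution back-end
#'
#' @param name `"serial"` (default) or `"mcore"` for local multiprocessing.
#' @param worker_count number of workers for `mcore` (defaults to the CPU
#'   count).
#' @return an object of class `sp_backend`.
#' @export
backend <- function(name = c("serial", "mcore"), worker_count = NULL) {
  name <- match.arg(name)
  if (is.null(worker_count))
    worker_count <- max(1L, parallel::detectCores(logical = TRUE))
  if (!is_count(worker_count)) stop_sigspace("worker_count must be >= 1")
  structure(list(name = name, worker_count = as.integer(worker_count)),
            class = "sp_backend")
}

#' Execute independent processes on a back-end
#'
#' Every process runs exactly once; per-process errors are captured into a
#' failure outcome and never abort sibling processes.  The outcome list
#' follows the input order regardless of completion order, which is the
#' basis of the serial/multicore result-equivalence contract.
#'
#' @param processes list of process descriptors from [create_processes()].
#' @param backend a [backend()].
#' @param input_root summary directory the processes read from.
#' @param result_root result directory the processes write into.
#' @return list of outcomes (fields `success`, `dataset`, `binding`,
#'   `run_index`, `out_subpath`, `metrics`, `error`), one per process.
#' @export
execute_processes <- function(processes, backend, input_root, result_root) {
  stopifnot(inherits(backend, "sp_backend"))
  if (!length(processes)) return(list())
  subpaths <- vapply(processes, function(p) p$out_subpath, character(1))
  if (anyDuplicated(subpaths))
    stop_sigspace("processes share an output sub-path; not independent")
  worker <- function(pd) run_process(pd, input_root, result_root)
  if (backend$name == "serial" || backend$worker_count == 1L ||
      .Platform$OS.type == "windows") {
    lapply(processes, worker)
  } else {
    out <- parallel::mclapply(processes, worker,
                              mc.cores = backend$worker_count,
                              mc.preschedule = TRUE)
    # a worker crash (not an R error) surfaces as a try-error; record it
    lapply(seq_along(out), function(i) {
      oc <- out[[i]]
      if (inherits(oc, "try-error") || is.null(oc)) {
        pd <- processes[[i]]
        list(success = FALSE, dataset = pd$dataset, binding = pd$binding,
             run_index = pd$run_index, out_subpath = pd$out_subpath,
             metrics = NULL, error = "worker failure")
      } else oc
    })
  }
}
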