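# Internal helpers: seeded RNG scoping, stable seed derivation, misc checks.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's random-number state, seeds the generator, evaluates
#' `code`, and restores the previous state on exit.  All randomized
#' components of the framework draw their randomness through this helper so
#' that a run never perturbs (or is perturbed by) the user's RNG state.
#'
#' @param seed integer scalar in `[0, 2^31)`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  code
}

# 32-bit FNV-1a over a string, with exact double arithmetic (products are
# split into 16-bit halves so no intermediate exceeds 2^53).  Used to derive
# per-node seeds from (run_index, chain position, node name); R's set.seed
# takes a 32-bit integer, so the result is reduced mod 2^31 - 1.
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  m <- 2^32
  for (b in bytes) {
    # xor on values < 2^32 via 16-bit halves (bitwXor needs < 2^31)
    hi <- h %/% 65536; lo <- h %% 65536
    bhi <- b %/% 65536; blo <- b %% 65536
    h <- bitwXor(as.integer(hi), as.integer(bhi)) * 65536 +
      bitwXor(as.integer(lo), as.integer(blo))
    hi <- h %/% 65536; lo <- h %% 65536
    h <- ((hi * 16777619) %% m * 65536 + lo * 16777619) %% m
  }
  h
}

#' Derive a per-node seed from the run index and chain position
#'
#' Seeds of randomized nodes are a stable hash of the repetition index, the
#' node's position in the chain, and its name, so that two randomized nodes
#' in one chain never share a random stream while the whole run remains a
#' pure function of the run index.
#'
#' @param run_index repetition index (the `runs` counter).
#' @param position 1-based node position in the chain.
#' @param name node name.
#' @return integer seed in `[0, 2^31 - 1)`.
#' @export
derive_node_seed <- function(run_index, position, name) {
  fnv1a32(paste(run_index, position, name, sep = "\r")) %% 2147483647
}

# scalar type checks ---------------------------------------------------------

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_sigspace <- function(fmt, ..., class = "sigspace_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

# format a double so that read-back reproduces it exactly
format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (v == round(v) && abs(v) < 2^53) {
      # integral values print without exponent for readability
      sprintf("%.0f", v)
    } else {
      sprintf("%.17g", v)
    }
  }, character(1))
  out
}
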