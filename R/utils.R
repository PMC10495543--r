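# Internal helpers: scoped RNG, sub-seed derivation, logging.

# Evaluate `expr` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Derive a reproducible sub-seed from a base seed and a label
#'
#' One global seed is expanded into independent per-module streams by hashing
#' the seed together with a module label.  Results are below 2^31 so they are
#' always valid R integer seeds.
#'
#' @param seed Integer base seed.
#' @param label Character label naming the consumer (e.g. "simulate_reads").
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  as.integer(cpp_murmur_mod(paste0(label, ":", format(seed)), 104729L,
                            2147483630) + 1)
}

rf_log <- function(level, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [", level, "] ",
                paste0(..., collapse = ""))
  message(msg)
  invisible(msg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
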