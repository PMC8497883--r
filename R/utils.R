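`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
# stream. Every stochastic operation in the package goes through this.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Set package logging verbosity
#'
#' Controls how chatty the fitting routines are. At level 0 (default) nothing
#' is printed; at level 1 each stage reports iteration counts, objective values
#' and active-feature summaries; level 2 adds per-sweep objective traces.
#'
#' @param verbose Integer verbosity level (0, 1 or 2).
#' @return The previous verbosity level, invisibly.
#' @export
configure_logging <- function(verbose = 0L) {
  old <- getOption("tskfs.verbose", 0L)
  options(tskfs.verbose = as.integer(verbose))
  invisible(old)
}

tsk_log <- function(..., level = 1L) {
  if (getOption("tskfs.verbose", 0L) >= level) {
    message(sprintf(...))
  }
  invisible(NULL)
}
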