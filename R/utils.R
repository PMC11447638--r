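# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state so that
#' library code never perturbs user-level randomness.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive n reproducible sub-seeds (< 2^31) from one master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Log one structured line for a pipeline stage
#'
#' One line per stage: stage name, input shape, key parameters, seed.
#' Suppress with `options(neurodyn.verbose = FALSE)`.
#'
#' @param stage Stage name.
#' @param ... Named values appended as `key=value`.
#' @return Invisibly, the formatted line.
#' @keywords internal
nd_log <- function(stage, ...) {
  if (!isTRUE(getOption("neurodyn.verbose", FALSE))) {
    return(invisible(NULL))
  }
  kv <- list(...)
  msg <- paste0(
    "[neurodyn] stage=", stage,
    if (length(kv)) paste0(" ", paste(names(kv), unname(vapply(kv, function(v)
      paste(format(v, digits = 6), collapse = ","), "")), sep = "=", collapse = " "))
  )
  message(msg)
  invisible(msg)
}

# Standardise a numeric vector to mean 0, sd 1.
zstd <- function(v) {
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) stop("cannot standardise a constant column")
  (v - mean(v)) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
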