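#' hertools: heartbeat-evoked response analysis
#'
#' Single-trial and group-level analysis of heartbeat-evoked responses
#' (HERs) with cluster-based permutation inference, a surrogate-
#' heartbeat control and a ground-truth synthetic-session simulator.
#' See the package vignette for the underlying model and conventions.
#'
#' @keywords internal
"_PACKAGE"

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic entry points funnel through this so that a single integer
# seed makes any analysis bit-reproducible.
with_seed <- function(seed, code) {
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
    }, add = TRUE)
    set.seed(as.integer(seed), kind = "Mersenne-Twister")
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot z-score a constant signal")
  (x - mean(x)) / s
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    stopf("'%s' must be a finite number in [%s, %s]", name, lo, hi)
  }
  invisible(x)
}
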