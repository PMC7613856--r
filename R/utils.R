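# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the global RNG seeded at `seed`, then restores the
#' caller's RNG state, so seeded package functions have no side effects on
#' user code. A `NULL` seed evaluates `expr` on the current stream.
#'
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L) # materialize a RNG state so it can be restored
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Unbiased per-column sample variances without forming a copy per column.
col_vars <- function(x) {
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 rows to compute column variances")
  mu <- colMeans(x)
  (colSums(x^2) - n * mu^2) / (n - 1)
}

# scalar checks ---------------------------------------------------------

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop(sprintf("`%s` = %g is outside its allowed range", name, x),
         call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != as.integer(x) || x < min) {
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}
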