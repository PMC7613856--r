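# Stage-2 one-biomarker-at-a-time interaction tests under the linear model
#   E(Y | X_j, T) = b0j + bXj X_j + bT T + bXjxT X_j T,
# with homoscedastic errors. The interaction null bXjxT = 0 is tested with
# a two-sided t statistic on n - 4 degrees of freedom (exact under the
# Gaussian linear model; asymptotically the Wald test).

#' Interaction Wald test for a single biomarker
#'
#' Fits the four-parameter linear model (intercept, biomarker, treatment,
#' biomarker-by-treatment product) by least squares and returns the
#' two-sided t-based p-value for the interaction coefficient with `n - 4`
#' degrees of freedom. The treatment indicator enters raw in `{0, 1}`
#' (centering does not change the interaction p-value here).
#'
#' @param data A [trial_data()] with at least 5 patients.
#' @param j Biomarker column index (or marker name).
#' @return A one-row `data.frame`: `biomarker`, `estimate`, `se`,
#'   `statistic`, `p_value`, `df`.
#' @export
interaction_test <- function(data, j) {
  stopifnot(inherits(data, "trial_data"))
  n <- length(data$y)
  if (n < 5L) stop("interaction test needs n >= 5", call. = FALSE)
  if (is.character(j)) j <- match(j, data$markers)
  j <- assert_count(j, "j")
  if (j > ncol(data$X)) stop("biomarker index out of range", call. = FALSE)
  x <- data$X[, j]
  d <- cbind(`(Intercept)` = 1, x = x, trt = data$trt, `x:trt` = x * data$trt)
  qrd <- qr(d)
  if (qrd$rank < 4L) {
    bad <- colnames(d)[qrd$pivot[seq(qrd$rank + 1L, 4L)]]
    stop(sprintf(
      "rank-deficient interaction design for biomarker %s (collinear: %s)",
      data$markers[j], paste(bad, collapse = ", ")), call. = FALSE)
  }
  beta <- qr.coef(qrd, data$y)
  resid <- data$y - drop(d %*% beta)
  sigma2 <- sum(resid^2) / (n - 4)
  xtx_inv <- chol2inv(qr.R(qrd))[order(qrd$pivot), order(qrd$pivot)]
  se <- sqrt(sigma2 * diag(xtx_inv))
  est <- beta[["x:trt"]]
  se_int <- se[4L]
  stat <- if (se_int == 0) sign(est) * Inf else est / se_int
  data.frame(biomarker = data$markers[j], estimate = est, se = se_int,
             statistic = stat,
             p_value = 2 * stats::pt(-abs(stat), df = n - 4),
             df = n - 4, stringsAsFactors = FALSE, row.names = NULL)
}

#' Interaction Wald tests for a set of biomarkers
#'
#' Applies the one-at-a-time interaction test to each requested biomarker.
#' The computation is vectorized through the per-arm decomposition of the
#' saturated model (separate intercept and slope per arm: the interaction
#' estimate is the slope difference, with the usual pooled homoscedastic
#' variance), which is algebraically identical to [interaction_test()]'s
#' least-squares fit.
#'
#' @param data A [trial_data()].
#' @param subset Integer (or marker-name) vector of biomarker indices;
#'   `NULL` tests all. An empty subset returns an empty table.
#' @return A `data.frame` with one row per requested biomarker, in input
#'   order: `biomarker`, `estimate`, `se`, `statistic`, `p_value`, `df`.
#' @export
interaction_test_all <- function(data, subset = NULL) {
  stopifnot(inherits(data, "trial_data"))
  n <- length(data$y)
  m <- ncol(data$X)
  if (is.null(subset)) subset <- seq_len(m)
  if (is.character(subset)) {
    subset <- match(subset, data$markers)
    if (anyNA(subset)) stop("unknown marker name in `subset`", call. = FALSE)
  }
  subset <- as.integer(subset)
  if (length(subset) == 0L) {
    return(data.frame(biomarker = character(), estimate = numeric(),
                      se = numeric(), statistic = numeric(),
                      p_value = numeric(), df = numeric(),
                      stringsAsFactors = FALSE))
  }
  if (any(subset < 1L | subset > m)) {
    stop("`subset` indices must lie in 1..m", call. = FALSE)
  }
  if (n < 5L) stop("interaction test needs n >= 5", call. = FALSE)
  arm1 <- data$trt == 1L
  n1 <- sum(arm1); n0 <- n - n1
  if (n0 == 0L || n1 == 0L) {
    stop("single-arm data: treatment indicator is constant", call. = FALSE)
  }
  x <- data$X[, subset, drop = FALSE]
  y <- data$y
  stats_arm <- function(idx) {
    xa <- x[idx, , drop = FALSE]
    ya <- y[idx]
    na <- length(ya)
    xm <- colMeans(xa)
    ym <- mean(ya)
    sxx <- colSums(xa^2) - na * xm^2
    sxy <- drop(crossprod(xa, ya)) - na * xm * ym
    syy <- sum(ya^2) - na * ym^2
    list(n = na, sxx = sxx, sxy = sxy, syy = syy)
  }
  s0 <- stats_arm(which(!arm1))
  s1 <- stats_arm(which(arm1))
  if (any(s0$sxx <= 0) || any(s1$sxx <= 0)) {
    bad <- data$markers[subset][s0$sxx <= 0 | s1$sxx <= 0]
    stop(sprintf("biomarker constant within a treatment arm: %s",
                 paste(utils::head(bad, 5L), collapse = ", ")),
         call. = FALSE)
  }
  slope0 <- s0$sxy / s0$sxx
  slope1 <- s1$sxy / s1$sxx
  rss <- (s0$syy - s0$sxy^2 / s0$sxx) + (s1$syy - s1$sxy^2 / s1$sxx)
  sigma2 <- pmax(rss, 0) / (n - 4)
  est <- slope1 - slope0
  se <- sqrt(sigma2 * (1 / s0$sxx + 1 / s1$sxx))
  stat <- ifelse(se == 0, sign(est) * Inf, est / se)
  data.frame(biomarker = data$markers[subset], estimate = est, se = se,
             statistic = stat,
             p_value = 2 * stats::pt(-abs(stat), df = n - 4),
             df = n - 4, stringsAsFactors = FALSE, row.names = NULL)
}

#' Write an interaction-test table to TSV
#'
#' @param results Output of [interaction_test_all()].
#' @param path Output path.
#' @export
write_interactions <- function(results, path) {
  data.table::fwrite(results, path, sep = "\t")
  invisible(path)
}
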