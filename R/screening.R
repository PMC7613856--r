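# Stage-1 marginal screening.
#
# Two screens are provided:
#  * univariate_screen(): one-biomarker-at-a-time simple linear regression
#    of outcome on biomarker, ranked by ascending p-value;
#  * ridge_screen(): multivariate ridge regression of outcome on the
#    treatment main effect plus all biomarkers jointly, ranked by
#    descending absolute (standardized) coefficient.
#
# Both produce a `screening_result`; the ranking feeds the stage-2
# significance allocation schemes in multiplicity.R.

new_screening_result <- function(method, score, ranking, markers, ...) {
  structure(c(list(method = method, score = score, ranking = ranking,
                   markers = markers), list(...)),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("Stage-1 %s screening of %d biomarkers\n", x$method,
              length(x$score)))
  if (x$method == "ridge") {
    cat(sprintf("  penalty lambda = %.6g (%d-fold CV over %d values)\n",
                x$lambda, x$n_folds %||% NA_integer_,
                length(x$lambda_grid %||% x$lambda)))
  }
  top <- utils::head(x$ranking, 5L)
  cat("  top ranked:", paste(x$markers[top], collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.screening_result <- function(x, ...) {
  rank_of <- integer(length(x$score))
  rank_of[x$ranking] <- seq_along(x$ranking)
  data.frame(biomarker = x$markers, score = unname(x$score),
             rank = rank_of, method = x$method,
             lambda = if (x$method == "ridge") x$lambda else NA_real_,
             stringsAsFactors = FALSE)
}

#' Write a screening result to TSV
#'
#' Columns: `biomarker`, `score`, `rank`, `method`, `lambda`.
#'
#' @param x A `screening_result`.
#' @param path Output path.
#' @export
write_screening <- function(x, path) {
  stopifnot(inherits(x, "screening_result"))
  data.table::fwrite(as.data.frame(x), path, sep = "\t")
  invisible(path)
}

#' Univariate marginal association screening
#'
#' For each biomarker `j` fits the simple linear regression
#' `E(Y | X_j) = d0j + dXj X_j` (intercept included, treatment ignored) and
#' tests `dXj = 0` with a two-sided homoscedastic t-test on `n - 2` degrees
#' of freedom. Biomarkers are ranked by ascending p-value, ties broken by
#' column index. A constant biomarker column is assigned p-value 1 with a
#' warning and therefore ranks last.
#'
#' @param data A [trial_data()] with at least 3 patients.
#' @return A `screening_result` with `method = "univariate"`; `score`
#'   holds the per-biomarker p-values, `estimate` the slope estimates and
#'   `statistic` the t statistics.
#' @export
univariate_screen <- function(data) {
  stopifnot(inherits(data, "trial_data"))
  n <- length(data$y)
  if (n < 3L) stop("univariate screening needs n >= 3", call. = FALSE)
  x <- data$X
  y <- data$y
  m <- ncol(x)
  xm <- colMeans(x)
  sxx <- colSums(x^2) - n * xm^2
  sxy <- drop(crossprod(x, y)) - n * xm * mean(y)
  syy <- sum((y - mean(y))^2)
  const <- sxx <= 0
  if (any(const)) {
    warning(sprintf("%d constant biomarker column(s) assigned p = 1: %s",
                    sum(const),
                    paste(utils::head(data$markers[const], 5L),
                          collapse = ", ")))
    sxx[const] <- NA_real_
  }
  slope <- sxy / sxx
  rss <- syy - sxy^2 / sxx
  # guard tiny negative rss from cancellation in exact fits
  se <- sqrt(pmax(rss, 0) / (n - 2) / sxx)
  tstat <- slope / se
  tstat[se == 0] <- sign(slope[se == 0]) * Inf
  pval <- 2 * stats::pt(-abs(tstat), df = n - 2)
  pval[const] <- 1
  slope[const] <- NA_real_
  tstat[const] <- NA_real_
  ranking <- order(pval, seq_len(m))
  new_screening_result("univariate",
                       score = stats::setNames(pval, data$markers),
                       ranking = ranking, markers = data$markers,
                       estimate = slope, statistic = tstat, df = n - 2)
}

# -- ridge ---------------------------------------------------------------

# Penalty convention: on centered/standardized data the objective is
#   || y - Z delta ||_2^2 + lambda ||delta||_2^2
# (sum of squares, raw lambda), i.e. normal equations
#   (Z'Z + lambda I) delta = Z'y.
# For mutually orthogonal standardized columns (Z'Z = (n-1) I) each
# coefficient is the OLS coefficient shrunk by (n-1) / (n-1 + lambda).

make_lambda_grid <- function(lambda_max, nlambda, lambda_min_ratio) {
  if (lambda_max <= 0) lambda_max <- 1
  exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
          length.out = nlambda))
}

# Stratified (by treatment arm) fold assignment, seeded.
assign_folds <- function(trt, n_folds, cv_seed) {
  n <- length(trt)
  foldid <- integer(n)
  with_seed(cv_seed, {
    for (arm in c(0L, 1L)) {
      idx <- which(trt == arm)
      if (length(idx)) {
        foldid[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
      }
    }
  })
  foldid
}

# Center/standardize a Gram matrix of cbind(Z, y) computed on raw data.
# Returns the standardized Z'Z block, the Z'y block, plus the centering
# and scaling vectors used (scale 1 for the treatment column and y).
standardize_gram <- function(craw, ssum, nobs, p) {
  mu <- ssum / nobs
  cc <- craw - nobs * tcrossprod(mu)
  varx <- diag(cc)[2:p] / (nobs - 1)
  if (any(varx <= 0)) {
    stop("constant biomarker column; ridge screening requires non-constant biomarkers",
         call. = FALSE)
  }
  d <- c(1, sqrt(varx), 1) # treatment centered only; y centered only
  di <- 1 / d
  cs <- cc * tcrossprod(di)
  list(gram = cs[1:p, 1:p, drop = FALSE], zy = cs[1:p, p + 1L],
       mu = mu, scale = d)
}

#' Multivariate ridge marginal screening
#'
#' Fits the multivariate screening model
#' `E(Y | T, X) = d0 + dT T + sum_j dXj X_j` by ridge regression with one
#' shared penalty on the treatment coefficient and all biomarker
#' coefficients (`||delta||^2 = dT^2 + sum_j dXj^2`). The outcome and the
#' treatment indicator are centered (so the treatment main effect is in the
#' model and `E(T) = 0` after centering, the condition under which stage-1
#' and stage-2 statistics are asymptotically independent), each biomarker
#' is centered and standardized to unit variance, and the intercept is
#' never penalized (it is absorbed by centering). The penalty is chosen to
#' minimize the mean squared cross-validation error over `lambda_grid`
#' with `n_folds` folds stratified by treatment arm; centering and scaling
#' are recomputed on each training fold. Biomarkers are ranked by
#' descending absolute standardized coefficient (the treatment coefficient
#' never enters the ranking), ties broken by column index.
#'
#' The solver is exact: each training-fold Gram matrix is
#' eigendecomposed once and the whole penalty path is obtained by
#' diagonal shifts, so coefficients agree with the closed-form ridge
#' solution to machine precision (see the penalty convention note below).
#'
#' Penalty convention: on the centered/standardized data the objective is
#' `||y - Z delta||^2 + lambda ||delta||^2` (sums of squares, raw
#' `lambda`), i.e. `(Z'Z + lambda I) delta = Z'y`.
#'
#' @param data A [trial_data()].
#' @param n_folds Number of CV folds (default 5).
#' @param lambda_grid Optional penalty grid. Default: 100 log-spaced values
#'   from `lambda_max = max |Z'y|` (standardized scale) down to
#'   `lambda_max * 1e-4`. A length-one grid skips cross-validation and
#'   fits at that penalty.
#' @param nlambda,lambda_min_ratio Default grid size and span.
#' @param cv_seed Integer seed for the fold assignment.
#' @return A `screening_result` with `method = "ridge"`: `score` holds the
#'   standardized biomarker coefficients at the selected penalty,
#'   `trt_coef` the (centered-scale) treatment coefficient, `lambda` the
#'   selected penalty, `lambda_grid` and `cvm` the CV curve.
#' @export
ridge_screen <- function(data, n_folds = 5L, lambda_grid = NULL,
                         nlambda = 100L, lambda_min_ratio = 1e-4,
                         cv_seed = 1L) {
  stopifnot(inherits(data, "trial_data"))
  n <- length(data$y)
  m <- ncol(data$X)
  p <- m + 1L # treatment + biomarkers
  if (!is.null(lambda_grid)) {
    if (length(lambda_grid) == 0L) {
      stop("empty lambda grid", call. = FALSE)
    }
    if (any(lambda_grid < 0)) stop("lambda must be >= 0", call. = FALSE)
    lambda_grid <- sort(as.numeric(lambda_grid), decreasing = TRUE)
  }
  do_cv <- is.null(lambda_grid) || length(lambda_grid) > 1L
  if (do_cv) {
    n_folds <- assert_count(n_folds, "n_folds", min = 2L)
    if (n < n_folds) stop("need n >= n_folds", call. = FALSE)
  }

  a <- cbind(data$trt, data$X, data$y)
  caug <- crossprod(a)
  ssum <- colSums(a)

  full <- standardize_gram(caug, ssum, n, p)
  if (is.null(lambda_grid)) {
    lambda_grid <- make_lambda_grid(max(abs(full$zy)), nlambda,
                                    lambda_min_ratio)
  }
  nl <- length(lambda_grid)

  cvm <- NULL
  foldid <- NULL
  if (do_cv) {
    foldid <- assign_folds(data$trt, n_folds, cv_seed)
    sse <- numeric(nl)
    for (f in seq_len(n_folds)) {
      val <- which(foldid == f)
      if (n - length(val) < 2L) {
        stop("degenerate CV fold (training set has fewer than 2 rows)",
             call. = FALSE)
      }
      av <- a[val, , drop = FALSE]
      trn <- standardize_gram(caug - crossprod(av), ssum - colSums(av),
                              n - length(val), p)
      eig <- eigen(trn$gram, symmetric = TRUE)
      dvals <- pmax(eig$values, 0)
      u <- drop(crossprod(eig$vectors, trn$zy))
      # validation design standardized with the training parameters
      zvs <- sweep(av[, 1:p, drop = FALSE], 2L, trn$mu[1:p], "-")
      zvs <- sweep(zvs, 2L, trn$scale[1:p], "/")
      pv <- zvs %*% eig$vectors
      yv <- av[, p + 1L] - trn$mu[p + 1L]
      coef_rot <- u / outer(dvals, lambda_grid, "+")
      resid <- yv - pv %*% coef_rot
      sse <- sse + colSums(resid^2)
    }
    cvm <- sse / n
    lambda <- lambda_grid[which.min(cvm)]
  } else {
    lambda <- lambda_grid
  }

  delta <- ridge_solve(full$gram, full$zy, lambda)
  score <- stats::setNames(delta[-1L], data$markers)
  ranking <- order(-abs(score), seq_len(m))
  new_screening_result("ridge", score = score, ranking = ranking,
                       markers = data$markers, trt_coef = delta[1L],
                       lambda = lambda, lambda_grid = lambda_grid,
                       cvm = cvm, n_folds = if (do_cv) n_folds,
                       cv_seed = cv_seed, foldid = foldid)
}

# Exact solve of (G + lambda I) delta = b. Cholesky when positive
# definite, spectral pseudo-solve otherwise (covers lambda = 0 on
# rank-deficient designs with a clear error for truly singular systems).
ridge_solve <- function(gram, b, lambda) {
  p <- length(b)
  g <- gram
  if (lambda > 0) diag(g) <- diag(g) + lambda
  r <- tryCatch(chol(g), error = function(e) NULL)
  if (!is.null(r)) {
    return(drop(backsolve(r, backsolve(r, b, transpose = TRUE))))
  }
  if (lambda > 0) stop("ridge system is numerically singular", call. = FALSE)
  eig <- eigen(gram, symmetric = TRUE)
  tol <- max(eig$values) * p * .Machine$double.eps
  if (all(eig$values <= tol)) {
    stop("design matrix has no usable variation", call. = FALSE)
  }
  keep <- eig$values > tol
  drop(eig$vectors[, keep, drop = FALSE] %*%
         (crossprod(eig$vectors[, keep, drop = FALSE], b) /
            eig$values[keep]))
}
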