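# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately naive (direct normal-equations / enumeration)
# and never share code with the implementation paths they check.

# Independent least-squares oracle: solve the normal equations of an
# arbitrary design matrix directly.
ols_oracle <- function(design, y) {
  xtx <- crossprod(design)
  beta <- solve(xtx, crossprod(design, y))
  resid <- y - design %*% beta
  df <- nrow(design) - ncol(design)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(sigma2 * diag(solve(xtx)))
  list(beta = drop(beta), se = se, df = df)
}

# Small complete trial dataset with both arms guaranteed non-empty.
toy_trial <- function(n = 40, m = 5, seed = 1, sigma = 1,
                      beta_int = numeric(m), beta_main = numeric(m),
                      beta_trt = 0) {
  set.seed(seed)
  trt <- rep(c(0L, 1L), length.out = n)
  X <- matrix(rnorm(n * m), n, m)
  y <- beta_trt * trt + drop(X %*% beta_main) +
    drop(X %*% beta_int) * trt + rnorm(n, 0, sigma)
  trial_data(y = y, trt = trt, X = X)
}

# Design with exactly orthogonal standardized columns: X columns are
# mutually orthogonal, mean zero, unit sample variance, and orthogonal to
# both the intercept and the (centered) treatment column, so the
# standardized Gram matrix is diagonal and the ridge solution has a
# per-coordinate closed form.
orthonormal_trial <- function(n = 40, m = 6, seed = 42) {
  set.seed(seed)
  trt <- rep(c(0L, 1L), n / 2)
  q <- qr.Q(qr(cbind(1, trt, matrix(rnorm(n * m), n, m))))
  X <- q[, 3:(m + 2), drop = FALSE] * sqrt(n - 1)
  trial_data(y = rnorm(n), trt = trt, X = X)
}

# Write a small data.frame as csv and return the path.
write_tmp_csv <- function(df, name = "toy.csv") {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()),
                    name)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  path
}
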