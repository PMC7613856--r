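# Trial simulator: correlation structure, outcome model, variance
# bookkeeping, reproducibility.

test_that("constructors validate their inputs", {
  expect_error(block_structure(100, 20, rho = 1), "rho")
  expect_error(block_structure(100, 20, rho = -0.1), "rho")
  expect_error(block_structure(100, 30, rho = 0.5), "divide")
  expect_error(effect_spec(sigma = 0), "sigma")
  expect_error(effect_spec(main = c(0.5)), "named")
  expect_error(effect_spec(main = c("0" = 0.5)), "positive integer")
  eff <- effect_spec(main = c("150" = 1), sigma = 1)
  expect_error(sim_config(10, eff, block_structure(100, 20, 0)),
               "exceeds")
})

test_that("identical seeds give bit-identical datasets", {
  cfg <- trial_scenario("correlated", n = 50, m = 100, seed = 99)
  d1 <- generate_trial(cfg)
  d2 <- generate_trial(cfg)
  expect_identical(d1$y, d2$y)
  expect_identical(d1$X, d2$X)
  expect_identical(d1$trt, d2$trt)
  cfg2 <- cfg
  cfg2$seed <- 100L
  expect_false(identical(generate_trial(cfg2)$y, d1$y))
})

test_that("rho = 0 gives independent standard-normal columns", {
  x <- generate_biomarkers(20000, block_structure(6, 2, 0), seed = 4)
  expect_equal(unname(colMeans(x)), rep(0, 6), tolerance = 0.05)
  expect_equal(unname(apply(x, 2, var)), rep(1, 6), tolerance = 0.05)
  cr <- cor(x)
  expect_lt(max(abs(cr[upper.tri(cr)])), 0.03)
})

test_that("block covariance matches the stated exchangeable blocks", {
  # DERIVED oracle: the sample covariance of each 2-member cluster must
  # reproduce [[1, .6], [.6, 1]] directly.
  x <- generate_biomarkers(5e5, block_structure(4, 2, 0.6), seed = 11)
  s <- cov(x)
  expected <- matrix(c(1, 0.6, 0.6, 1), 2)
  expect_equal(unname(s[1:2, 1:2]), expected, tolerance = 0.01)
  expect_equal(unname(s[3:4, 3:4]), expected, tolerance = 0.01)
  expect_lt(max(abs(s[1:2, 3:4])), 0.01)
})

test_that("within/between-cluster sample correlations hit rho on average", {
  str <- block_structure(200, 20, 0.6)
  x <- generate_biomarkers(20000, str, seed = 21)
  cr <- cor(x)
  within <- outer(str$clusters, str$clusters, "==") & upper.tri(cr)
  between <- !outer(str$clusters, str$clusters, "==") & upper.tri(cr)
  expect_equal(mean(cr[within]), 0.6, tolerance = 0.01)
  expect_equal(mean(cr[between]), 0, tolerance = 0.01)
})

test_that("outcome follows the linear model exactly when noise-free", {
  eff <- effect_spec(intercept = 3, sigma = 1e-12)
  cfg <- sim_config(25, eff, block_structure(10, 5, 0.2), seed = 2)
  expect_equal(generate_trial(cfg)$y, rep(3, 25), tolerance = 1e-9)

  eff2 <- effect_spec(trt_main = 2, main = c("3" = 1.5),
                      interaction = c("1" = -1), sigma = 1e-12)
  cfg2 <- sim_config(40, eff2, block_structure(10, 5, 0), seed = 5)
  d <- generate_trial(cfg2)
  expect_equal(d$y, 2 * d$trt + 1.5 * d$X[, 3] - d$X[, 1] * d$trt,
               tolerance = 1e-9)
})

test_that("treatment is independent of biomarkers by design", {
  cfg <- trial_scenario("correlated", n = 4000, m = 200, seed = 8)
  d <- generate_trial(cfg)
  r <- abs(cor(d$trt, d$X))
  expect_lt(mean(r), 4 / sqrt(4000))
})

test_that("outcome moments match the analytic variance decomposition", {
  # DERIVED: under the default scenario Var(Y) = 0.0625 + 1.25 + 9 + 25
  # = 35.3125 and E(Y) = 0.5 * 0.5 = 0.25; checked against a 1e6-draw
  # marginalized simulation of the signal coordinates.
  cfg <- trial_scenario("correlated", n = 1500)
  eff <- cfg$effects
  set.seed(31)
  n <- 1e6
  trt <- rbinom(n, 1, 0.5)
  xa <- matrix(rnorm(n * 5), n, 5) # active biomarkers sit in 5 clusters
  s <- 0.5 * trt + 0.5 * xa[, 1] + xa[, 1] * trt +
    1.5 * (xa[, 2] + xa[, 3] + xa[, 4] + xa[, 5])
  y <- s + rnorm(n, 0, 5)
  expect_lt(abs(var(y) - 35.3125), 0.3)
  expect_lt(abs(mean(y) - 0.25), 0.02)
  v <- analytic_pve(eff, cfg$structure)
  expect_lt(abs(v - var(s) / var(y)), 0.005)
})

test_that("analytic pve: zero effects give zero, default scenario 0.292", {
  str <- block_structure(1000, 20, 0.6)
  expect_identical(analytic_pve(effect_spec(sigma = 5), str), 0)
  cfg <- trial_scenario("correlated")
  expect_equal(round(analytic_pve(cfg$effects, cfg$structure), 3), 0.292)
  # invariant to rho here because the active biomarkers sit in distinct
  # clusters
  cfg0 <- trial_scenario("independent")
  expect_equal(round(analytic_pve(cfg0$effects, cfg0$structure), 3), 0.292)
})

test_that("analytic pve agrees with Monte-Carlo R^2 over random specs", {
  set.seed(77)
  for (k in 1:4) {
    m <- 60
    idx_main <- sample(m, 3)
    idx_int <- sample(m, 2)
    eff <- effect_spec(
      intercept = rnorm(1), trt_main = rnorm(1),
      main = setNames(rnorm(3), idx_main),
      interaction = setNames(rnorm(2), idx_int),
      sigma = runif(1, 0.5, 4))
    str <- block_structure(m, sample(c(5L, 10L, 20L), 1),
                           runif(1, 0, 0.8))
    ana <- analytic_pve(eff, str, p_treat = 0.5)
    emp <- empirical_pve(eff, str, p_treat = 0.5, n = 4e5, seed = 1000 + k)
    expect_lt(abs(ana - emp), 0.005)
  }
})

test_that("csv round trip preserves the dataset and the truth sidecar", {
  cfg <- trial_scenario("correlated", n = 30, m = 100, seed = 6)
  d <- generate_trial(cfg)
  path <- file.path(withr::local_tempdir(), "trial.csv")
  write_trial(d, path)
  expect_true(file.exists(paste0(path, ".truth.json")))
  tab <- read_trial_table(path)
  d2 <- filter_and_impute(tab)
  expect_equal(d2$y, d$y, tolerance = 1e-12)
  expect_identical(d2$trt, d$trt)
  expect_equal(unname(d2$X), unname(d$X), tolerance = 1e-12)
  truth <- ridgescreen:::read_truth_json(paste0(path, ".truth.json"))
  expect_equal(truth$effects$main, cfg$effects$main)
  expect_equal(truth$structure$rho, 0.6)
})
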