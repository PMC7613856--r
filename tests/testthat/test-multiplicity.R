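# Threshold schedules and decision rules.

test_that("bonferroni schedule spreads alpha evenly", {
  s1 <- bonferroni_schedule(0.05, 1)
  expect_identical(s1$thresholds, 0.05)
  s <- bonferroni_schedule(0.05, 1000)
  expect_equal(unique(s$thresholds), 5e-5)
  expect_equal(sum(s$thresholds), 0.05)
})

test_that("subset schedule implements alpha / m*", {
  mk_screen <- function(pv) {
    d <- toy_trial(n = 30, m = length(pv), seed = 1)
    scr <- univariate_screen(d)
    scr$score[] <- pv
    scr$ranking <- order(pv, seq_along(pv))
    scr
  }
  # m* = 10 of 40 selected at alpha1 = 0.05
  pv <- c(rep(0.01, 10), rep(0.5, 30))
  s <- subset_schedule(0.05, mk_screen(pv), alpha1 = 0.05)
  expect_equal(s$params$m_star, 10)
  expect_equal(s$thresholds[1:10], rep(0.005, 10))
  expect_identical(s$thresholds[11:40], rep(0, 30))
  expect_lte(sum(s$thresholds), 0.05 + 1e-12)
  # nobody selected -> all-zero schedule
  s0 <- subset_schedule(0.05, mk_screen(rep(0.9, 5)), alpha1 = 0.05)
  expect_identical(s0$thresholds, rep(0, 5))
  expect_equal(s0$params$m_star, 0)
  # boundary: selection is strict (p < alpha1)
  sb <- subset_schedule(0.05, mk_screen(c(0.05, 0.049)), alpha1 = 0.05)
  expect_identical(sb$thresholds > 0, c(FALSE, TRUE))
  # alpha1 = 1 selects everything: reduces to Bonferroni over m
  sa <- subset_schedule(0.05, mk_screen(pv), alpha1 = 1)
  expect_equal(sa$thresholds, rep(0.05 / 40, 40))
})

test_that("weighted buckets match the printed thresholds for B = 5", {
  s <- weighted_schedule(0.05, ranking = 1:100, B = 5)
  thr <- s$thresholds # ranking is identity so thresholds are by rank
  expect_equal(thr[1:5], rep(0.005, 5))
  expect_equal(thr[6:15], rep(0.00125, 10))
  expect_equal(thr[16:35], rep(3.125e-4, 20))
  expect_equal(thr[36:75], rep(0.05 / 16 / 40, 40))
  expect_equal(thr[76:100], rep(0.05 / 32 / 80, 25)) # truncated bucket
  expect_true(all(thr > 0))
})

test_that("weighted bucket budget respects the geometric series", {
  for (m in c(1, 5, 17, 160, 1000)) {
    for (B in c(1, 5, 8)) {
      s <- weighted_schedule(0.05, sample(m), B = B)
      expect_lte(sum(s$thresholds), 0.05)
      expect_lte(max(s$thresholds), (0.05 / 2) / B)
    }
  }
  # m = 1, B = 1: single threshold (alpha/2)/1
  expect_equal(weighted_schedule(0.05, 1L, B = 1)$thresholds, 0.025)
  expect_error(weighted_schedule(0.05, c(1L, 3L)), "permutation")
})

test_that("for m <= B the weighted scheme beats Bonferroni iff (a/2)/B > a/m", {
  alpha <- 0.05
  for (B in c(1L, 4L, 7L)) {
    for (m in seq_len(B)) {
      w <- weighted_schedule(alpha, seq_len(m), B = B)$thresholds
      b <- bonferroni_schedule(alpha, m)$thresholds
      expect_identical(unique(w > b), (alpha / 2) / B > alpha / m)
    }
  }
})

test_that("apply_schedule compares p-values strictly against thresholds", {
  res <- data.frame(biomarker = c("X1", "X2"),
                    estimate = c(1, 1), se = c(1, 1), statistic = c(1, 1),
                    p_value = c(1e-6, 0.04), df = 10,
                    stringsAsFactors = FALSE)
  sch <- bonferroni_schedule(1e-4, 2, markers = c("X1", "X2"))
  dec <- apply_schedule(res, sch)
  expect_identical(dec$rejected, "X1")
  # all-zero schedule rejects nothing
  scr <- univariate_screen(toy_trial(n = 20, m = 2, seed = 3))
  scr$score[] <- c(0.9, 0.9)
  zero <- subset_schedule(0.05, scr)
  zero$markers <- c("X1", "X2")
  expect_length(apply_schedule(res, zero)$rejected, 0)
  # mismatched biomarker sets error
  bad <- bonferroni_schedule(0.05, 3, markers = c("X1", "X2", "X9"))
  expect_error(apply_schedule(res[1, ], bad), "missing")
})

test_that("rejection is monotone in the p-values under a fixed schedule", {
  set.seed(10)
  m <- 50
  sch <- weighted_schedule(0.05, sample(m), B = 5,
                           markers = paste0("X", 1:m))
  pv <- runif(m)
  mk <- function(p) data.frame(biomarker = paste0("X", 1:m), estimate = 0,
                               se = 1, statistic = 0, p_value = p, df = 10,
                               stringsAsFactors = FALSE)
  base <- apply_schedule(mk(pv), sch)$table$rejected
  lower <- apply_schedule(mk(pv * 0.5), sch)$table$rejected
  expect_true(all(base <= lower))
})

test_that("a biomarker's decision can flip with its rank alone", {
  m <- 100
  # p-value between the top-bucket threshold (0.005) and a deep-bucket one
  pv <- rep(1, m); pv[42] <- 0.003
  mk <- data.frame(biomarker = paste0("X", 1:m), estimate = 0, se = 1,
                   statistic = 0, p_value = pv, df = 10,
                   stringsAsFactors = FALSE)
  top <- weighted_schedule(0.05, c(42L, setdiff(1:m, 42L)), B = 5,
                           markers = paste0("X", 1:m))
  deep <- weighted_schedule(0.05, c(setdiff(1:m, 42L), 42L), B = 5,
                            markers = paste0("X", 1:m))
  expect_identical(apply_schedule(mk, top)$rejected, "X42")
  expect_length(apply_schedule(mk, deep)$rejected, 0)
})

test_that("schedules and decisions serialize with a provenance header", {
  dir <- withr::local_tempdir()
  s <- weighted_schedule(0.05, sample(10), B = 2,
                         markers = paste0("X", 1:10))
  p1 <- file.path(dir, "schedule.tsv")
  write_schedule(s, p1)
  lines <- readLines(p1)
  expect_match(lines[1], "^# \\{")
  expect_match(lines[1], "\"scheme\":\"weighted\"")
  tab <- utils::read.delim(p1, comment.char = "#")
  expect_equal(tab$threshold, s$thresholds)
})
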