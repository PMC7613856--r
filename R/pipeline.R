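# End-to-end procedures and their Monte-Carlo operating characteristics.
#
# Four procedures are compared throughout:
#   no_screening         - single-step interaction tests, Bonferroni over m;
#   univariate_threshold - univariate screen at alpha1, subset Bonferroni;
#   univariate_rank      - weighted buckets on the univariate p-value rank;
#   ridge_rank           - weighted buckets on the ridge |coefficient| rank.

PROCEDURES <- c("no_screening", "univariate_threshold", "univariate_rank",
                "ridge_rank")

#' Run one two-stage (or single-step) testing procedure
#'
#' @param data A [trial_data()].
#' @param procedure One of `"no_screening"`, `"univariate_threshold"`,
#'   `"univariate_rank"`, `"ridge_rank"`.
#' @param alpha Target overall familywise error rate (default 0.05).
#' @param alpha1 Stage-1 selection level for the threshold procedure
#'   (default 0.05).
#' @param B Top bucket size for the weighted procedures (default 5).
#' @param cv_seed Seed for the ridge CV fold assignment.
#' @param ridge_args Extra arguments passed to [ridge_screen()].
#' @return A `decision_set` (see [apply_schedule()]) with additional
#'   fields `procedure`, `screening` (the stage-1 result, `NULL` for
#'   `no_screening`) and `stage2` (the interaction table).
#' @export
run_procedure <- function(data, procedure = PROCEDURES, alpha = 0.05,
                          alpha1 = 0.05, B = 5L, cv_seed = 1L,
                          ridge_args = list()) {
  procedure <- match.arg(procedure)
  m <- ncol(data$X)
  screening <- NULL
  if (procedure == "no_screening") {
    schedule <- bonferroni_schedule(alpha, m, data$markers)
    stage2 <- interaction_test_all(data)
  } else if (procedure == "univariate_threshold") {
    screening <- univariate_screen(data)
    schedule <- subset_schedule(alpha, screening, alpha1)
    stage2 <- interaction_test_all(data, which(schedule$thresholds > 0))
  } else if (procedure == "univariate_rank") {
    screening <- univariate_screen(data)
    schedule <- weighted_schedule(alpha, screening$ranking, B, data$markers)
    stage2 <- interaction_test_all(data)
  } else { # ridge_rank
    screening <- do.call(ridge_screen,
                         c(list(data = data, cv_seed = cv_seed), ridge_args))
    schedule <- weighted_schedule(alpha, screening$ranking, B, data$markers)
    stage2 <- interaction_test_all(data)
  }
  out <- apply_schedule(stage2, schedule)
  out$procedure <- procedure
  out$screening <- screening
  out$stage2 <- stage2
  out
}

# Decide rejections for each requested procedure on one dataset, sharing
# the stage-2 table and stage-1 screens across procedures (common random
# numbers: the procedures are compared on identical data and identical
# stage-2 statistics).
decide_all <- function(data, procedures, alpha, alpha1, B, cv_seed,
                       ridge_args = list()) {
  m <- ncol(data$X)
  stage2 <- interaction_test_all(data)
  uni <- if (any(procedures %in% c("univariate_threshold", "univariate_rank")))
    univariate_screen(data)
  rdg <- if ("ridge_rank" %in% procedures)
    do.call(ridge_screen, c(list(data = data, cv_seed = cv_seed), ridge_args))
  out <- matrix(FALSE, m, length(procedures),
                dimnames = list(data$markers, procedures))
  for (pr in procedures) {
    schedule <- switch(pr,
      no_screening = bonferroni_schedule(alpha, m, data$markers),
      univariate_threshold = subset_schedule(alpha, uni, alpha1),
      univariate_rank = weighted_schedule(alpha, uni$ranking, B,
                                          data$markers),
      ridge_rank = weighted_schedule(alpha, rdg$ranking, B, data$markers))
    out[, pr] <- stage2$p_value < schedule$thresholds & schedule$thresholds > 0
  }
  out
}

#' Monte-Carlo operating characteristics of the testing procedures
#'
#' Repeatedly simulates trials from `config`, runs the requested
#' procedures on each replicate (common random numbers: every procedure
#' sees the same datasets and the same stage-2 statistics), and estimates
#'
#' * cluster-discovery power: the probability of rejecting at least one
#'   biomarker in a cluster that contains a truly interacting biomarker
#'   (averaged over signal clusters when there are several), and
#' * familywise error rate: by default the probability of rejecting any
#'   biomarker in a cluster containing no truly interacting member
#'   (`fwer_level = "cluster"`; within-signal-cluster rejections count as
#'   discoveries, not errors). `fwer_level = "biomarker"` uses the
#'   stricter event "any rejection of a biomarker whose own interaction
#'   effect is zero". Under a global null the two coincide with the
#'   standard familywise error rate.
#'
#' Replicate `r` uses seed `seed + r`, so procedure comparisons are paired
#' and fully reproducible.
#'
#' @param config A [sim_config()]; its own seed is ignored in favour of
#'   `seed + r`.
#' @param procedures Character vector of procedures to evaluate.
#' @param alpha,alpha1,B See [run_procedure()].
#' @param R Number of replicate datasets.
#' @param seed Master seed.
#' @param metrics Which metrics to estimate; default: both when the
#'   configuration contains a true interaction, `"fwer"` alone otherwise.
#'   Explicitly requesting `"power"` on a configuration with no signal
#'   cluster is an error.
#' @param fwer_level `"cluster"` (default) or `"biomarker"`.
#' @param ridge_args Extra arguments passed to [ridge_screen()].
#' @return An `operating_characteristics` object: a data.frame with one
#'   row per procedure (`power`, `power_se`, `fwer`, `fwer_se`, `R`), with
#'   the per-replicate rejection indicators in attribute `"replicates"`
#'   (for paired comparisons).
#' @export
estimate_operating_characteristics <- function(config,
                                               procedures = PROCEDURES,
                                               alpha = 0.05, alpha1 = 0.05,
                                               B = 5L, R = 100L, seed = 1L,
                                               metrics = NULL,
                                               fwer_level = c("cluster",
                                                              "biomarker"),
                                               ridge_args = list()) {
  stopifnot(inherits(config, "sim_config"))
  procedures <- match.arg(procedures, PROCEDURES, several.ok = TRUE)
  fwer_level <- match.arg(fwer_level)
  R <- assert_count(R, "R")
  seed <- assert_count(seed, "seed", min = -.Machine$integer.max)
  str <- config$structure
  clusters <- str$clusters
  int_idx <- as.integer(names(config$effects$interaction[
    config$effects$interaction != 0]))
  signal_clusters <- unique(clusters[int_idx])
  null_marker <- !(seq_len(str$m) %in% int_idx)
  null_cluster_marker <- !(clusters %in% signal_clusters)
  have_signal <- length(signal_clusters) > 0L
  metrics <- metrics %||% if (have_signal) c("power", "fwer") else "fwer"
  metrics <- match.arg(metrics, c("power", "fwer"), several.ok = TRUE)
  if ("power" %in% metrics && !have_signal) {
    stop("no signal cluster defined: cluster-discovery power is undefined",
         call. = FALSE)
  }
  have_signal <- "power" %in% metrics

  power_ind <- matrix(NA_real_, R, length(procedures),
                      dimnames = list(NULL, procedures))
  fwer_ind <- matrix(NA_real_, R, length(procedures),
                     dimnames = list(NULL, procedures))
  for (r in seq_len(R)) {
    cfg <- config
    cfg$seed <- seed + r
    dat <- generate_trial(cfg)
    rej <- decide_all(dat, procedures, alpha, alpha1, B,
                      cv_seed = seed + r, ridge_args = ridge_args)
    for (pr in procedures) {
      rj <- rej[, pr]
      if (have_signal) {
        hits <- vapply(signal_clusters,
                       function(cl) any(rj[clusters == cl]), logical(1))
        power_ind[r, pr] <- mean(hits)
      }
      fwer_ind[r, pr] <- if (fwer_level == "cluster")
        any(rj[null_cluster_marker]) else any(rj[null_marker])
    }
  }
  est <- data.frame(
    procedure = procedures,
    power = if (have_signal) colMeans(power_ind) else NA_real_,
    power_se = if (have_signal)
      sqrt(colMeans(power_ind) * (1 - colMeans(power_ind)) / R)
    else NA_real_,
    fwer = colMeans(fwer_ind),
    fwer_se = sqrt(colMeans(fwer_ind) * (1 - colMeans(fwer_ind)) / R),
    R = R, row.names = NULL, stringsAsFactors = FALSE)
  structure(est, replicates = list(power = power_ind, fwer = fwer_ind),
            fwer_level = fwer_level, seed = seed,
            class = c("operating_characteristics", "data.frame"))
}

#' Between-stage independence diagnostic
#'
#' Pearson correlation between paired stage-1 and stage-2 statistics
#' (e.g. ridge screening coefficients and interaction estimates, paired
#' over biomarkers within a dataset, or over replicates for a fixed
#' biomarker), with the two-sided test and the Fisher-z 95% confidence
#' interval. Near-zero correlation with an interval covering zero is what
#' the two-stage procedure's familywise-error guarantee relies on.
#'
#' @param stage1 Numeric vector of stage-1 statistics.
#' @param stage2 Numeric vector of stage-2 statistics, same length (>= 3).
#' @return An `independence_diagnostic`: list with `estimate`, `p_value`,
#'   `conf_int` (95%), `n`.
#' @export
between_stage_diagnostic <- function(stage1, stage2) {
  stage1 <- as.numeric(stage1)
  stage2 <- as.numeric(stage2)
  if (length(stage1) != length(stage2) || length(stage1) < 3L) {
    stop("need >= 3 complete pairs", call. = FALSE)
  }
  if (anyNA(stage1) || anyNA(stage2)) {
    stop("missing values in the paired statistics", call. = FALSE)
  }
  if (stats::sd(stage1) == 0 || stats::sd(stage2) == 0) {
    stop("constant input vector: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(stage1, stage2, method = "pearson",
                        conf.level = 0.95)
  structure(list(estimate = unname(ct$estimate), p_value = ct$p.value,
                 conf_int = as.numeric(ct$conf.int), n = length(stage1)),
            class = "independence_diagnostic")
}

#' @export
print.independence_diagnostic <- function(x, ...) {
  cat(sprintf(
    "Between-stage Pearson correlation: %.4f (95%% CI %.4f to %.4f, p = %.3g, n = %d)\n",
    x$estimate, x$conf_int[1], x$conf_int[2], x$p_value, x$n))
  invisible(x)
}

#' Tidy export of operating characteristics
#'
#' Long-format table (procedure x metric) suitable for re-plotting
#' power/familywise-error curves across scenarios.
#'
#' @param x An `operating_characteristics` object.
#' @param scenario Optional scenario label column.
#' @return A data.frame with columns `scenario`, `procedure`, `metric`,
#'   `estimate`, `mc_se`, `R`.
#' @export
tidy_operating_characteristics <- function(x, scenario = NA_character_) {
  stopifnot(inherits(x, "operating_characteristics"))
  rbind(
    data.frame(scenario = scenario, procedure = x$procedure,
               metric = "power", estimate = x$power, mc_se = x$power_se,
               R = x$R, stringsAsFactors = FALSE),
    data.frame(scenario = scenario, procedure = x$procedure,
               metric = "fwer", estimate = x$fwer, mc_se = x$fwer_se,
               R = x$R, stringsAsFactors = FALSE))
}
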