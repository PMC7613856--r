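# Significance allocation for the stage-2 interaction tests: plain
# Bonferroni, subset Bonferroni after threshold screening, and the
# rank-weighted bucket scheme. A schedule assigns every biomarker a
# per-test threshold; threshold 0 means "not tested at stage 2".

new_threshold_schedule <- function(alpha, thresholds, scheme, params,
                                   markers = NULL) {
  structure(list(alpha = alpha, thresholds = thresholds, scheme = scheme,
                 params = params,
                 markers = markers %||% paste0("X", seq_along(thresholds))),
            class = "threshold_schedule")
}

#' @export
print.threshold_schedule <- function(x, ...) {
  tested <- sum(x$thresholds > 0)
  cat(sprintf(
    "%s threshold schedule: overall level %g, %d of %d biomarkers tested\n",
    x$scheme, x$alpha, tested, length(x$thresholds)))
  cat(sprintf("  alpha budget used: %g\n",
              sum(x$thresholds[x$thresholds > 0])))
  invisible(x)
}

#' Bonferroni schedule
#'
#' Every one of the `m` biomarkers is tested at the adjusted level
#' `alpha / m`, so the thresholds sum to exactly `alpha`.
#'
#' @param alpha Target overall familywise error rate.
#' @param m Number of biomarkers.
#' @param markers Optional biomarker names.
#' @return A `threshold_schedule` with scheme `"bonferroni"`.
#' @export
bonferroni_schedule <- function(alpha, m, markers = NULL) {
  assert_scalar_number(alpha, "alpha", lower = 0, upper = 1,
                       strict_lower = TRUE, strict_upper = TRUE)
  m <- assert_count(m, "m")
  new_threshold_schedule(alpha, rep(alpha / m, m), "bonferroni",
                         list(m = m), markers)
}

#' Subset-Bonferroni schedule after threshold screening
#'
#' Stage-1 univariate screening selects the `m*` biomarkers with p-value
#' strictly below `alpha1` (unadjusted); only those are tested at stage 2,
#' each at the Bonferroni-adjusted level `alpha / m*`. With stage-1 and
#' stage-2 statistics independent this preserves the overall familywise
#' error rate at `alpha`. If nothing is selected the schedule is all-zero
#' (no stage-2 tests).
#'
#' @param alpha Target overall familywise error rate.
#' @param screening A `screening_result` from [univariate_screen()].
#' @param alpha1 Stage-1 selection level (default 0.05, unadjusted).
#' @return A `threshold_schedule` with scheme `"subset"`; untested
#'   biomarkers have threshold 0.
#' @export
subset_schedule <- function(alpha, screening, alpha1 = 0.05) {
  assert_scalar_number(alpha, "alpha", lower = 0, upper = 1,
                       strict_lower = TRUE, strict_upper = TRUE)
  assert_scalar_number(alpha1, "alpha1", lower = 0, upper = 1,
                       strict_lower = TRUE)
  if (!inherits(screening, "screening_result") ||
      screening$method != "univariate") {
    stop("`screening` must be a univariate screening_result (stage-1 p-values)",
         call. = FALSE)
  }
  pv <- screening$score
  if (anyNA(pv)) stop("missing stage-1 p-values", call. = FALSE)
  sel <- pv < alpha1
  m_star <- sum(sel)
  thr <- numeric(length(pv))
  if (m_star > 0) thr[sel] <- alpha / m_star
  new_threshold_schedule(alpha, thr, "subset",
                         list(alpha1 = alpha1, m_star = m_star),
                         screening$markers)
}

# per-rank thresholds of the weighted bucket scheme: rank r falls in
# bucket k (k = 0, 1, ...) of size 2^k B covering ranks
# (B(2^k - 1), B(2^(k+1) - 1)], tested at (alpha / 2^(k+1)) / (2^k B).
weighted_bucket_thresholds <- function(m, alpha, B) {
  r <- seq_len(m)
  k <- ceiling(log2(r / B + 1)) - 1
  # guard against floating error at exact bucket boundaries
  k <- ifelse(r > B * (2^(k + 1) - 1), k + 1, k)
  k <- ifelse(r <= B * (2^k - 1), k - 1, k)
  (alpha / 2^(k + 1)) / (2^k * B)
}

#' Rank-weighted bucket schedule
#'
#' All `m` biomarkers are tested at stage 2, at significance levels
#' allocated by stage-1 rank: the `B` top-ranked biomarkers are tested at
#' `(alpha/2)/B`, the next `2B` at `(alpha/4)/(2B)`, ..., the next
#' `2^k B` at `(alpha/2^(k+1))/(2^k B)`, and so on. The bucket budgets
#' `alpha/2^(k+1)` form a geometric series, so the total allocated alpha
#' never exceeds `alpha`. The final (possibly partial) bucket keeps its
#' full per-test threshold; unused alpha mass is not redistributed, which
#' is conservative.
#'
#' @param alpha Target overall familywise error rate.
#' @param ranking Permutation of `1..m`, best-ranked biomarker first (as
#'   produced by a `screening_result`).
#' @param B Top bucket size (default 5).
#' @param markers Optional biomarker names.
#' @return A `threshold_schedule` with scheme `"weighted"`; every
#'   biomarker receives a positive threshold.
#' @export
weighted_schedule <- function(alpha, ranking, B = 5L, markers = NULL) {
  assert_scalar_number(alpha, "alpha", lower = 0, upper = 1,
                       strict_lower = TRUE, strict_upper = TRUE)
  B <- assert_count(B, "B")
  m <- length(ranking)
  if (m < 1L || !setequal(ranking, seq_len(m))) {
    stop("`ranking` must be a permutation of 1..m", call. = FALSE)
  }
  thr_by_rank <- weighted_bucket_thresholds(m, alpha, B)
  thr <- numeric(m)
  thr[ranking] <- thr_by_rank
  new_threshold_schedule(alpha, thr, "weighted",
                         list(B = B, ranking = ranking), markers)
}

#' Apply a threshold schedule to stage-2 results
#'
#' Biomarker `j` is rejected iff its stage-2 interaction p-value is
#' strictly below its scheduled threshold and the threshold is positive.
#'
#' @param results Interaction table from [interaction_test_all()]; its rows
#'   must cover exactly the biomarkers with positive thresholds (testing
#'   all `m` is always acceptable).
#' @param schedule A `threshold_schedule` over the same biomarkers.
#' @return A `decision_set`: list with `rejected` (character vector of
#'   rejected biomarker names), `table` (per-biomarker decision table) and
#'   the originating `schedule`.
#' @export
apply_schedule <- function(results, schedule) {
  stopifnot(inherits(schedule, "threshold_schedule"))
  need <- schedule$markers[schedule$thresholds > 0]
  missing_rows <- setdiff(need, results$biomarker)
  if (length(missing_rows)) {
    stop("stage-2 results missing for scheduled biomarkers: ",
         paste(utils::head(missing_rows, 5L), collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(results$biomarker, schedule$markers)
  if (length(extra)) {
    stop("stage-2 results contain biomarkers absent from the schedule: ",
         paste(utils::head(extra, 5L), collapse = ", "), call. = FALSE)
  }
  thr <- schedule$thresholds[match(results$biomarker, schedule$markers)]
  rejected <- !is.na(results$p_value) & thr > 0 & results$p_value < thr
  tab <- data.frame(biomarker = results$biomarker,
                    p_value = results$p_value, threshold = thr,
                    rejected = rejected, stringsAsFactors = FALSE)
  structure(list(rejected = results$biomarker[rejected], table = tab,
                 schedule = schedule),
            class = "decision_set")
}

#' @export
print.decision_set <- function(x, ...) {
  cat(sprintf("Decisions under %s schedule (overall level %g): %d rejection(s)\n",
              x$schedule$scheme, x$schedule$alpha, length(x$rejected)))
  if (length(x$rejected)) {
    cat("  rejected:", paste(utils::head(x$rejected, 10L), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Write a schedule (or decision set) to TSV
#'
#' The TSV carries the per-biomarker thresholds (and decisions, for a
#' `decision_set`); scheme parameters are echoed as a JSON comment header
#' for provenance.
#'
#' @param x A `threshold_schedule` or `decision_set`.
#' @param path Output path.
#' @export
write_schedule <- function(x, path) {
  if (inherits(x, "decision_set")) {
    header <- jsonlite::toJSON(
      c(list(scheme = x$schedule$scheme, alpha = x$schedule$alpha),
        x$schedule$params[setdiff(names(x$schedule$params), "ranking")]),
      auto_unbox = TRUE)
    tab <- x$table
  } else {
    stopifnot(inherits(x, "threshold_schedule"))
    header <- jsonlite::toJSON(
      c(list(scheme = x$scheme, alpha = x$alpha),
        x$params[setdiff(names(x$params), "ranking")]),
      auto_unbox = TRUE)
    tab <- data.frame(biomarker = x$markers, threshold = x$thresholds,
                      stringsAsFactors = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
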