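# Reading and preprocessing of real trial tables: column-role validation,
# missingness filtering, mean imputation, top-variance probe selection.

#' Read a delimited trial table
#'
#' Reads a CSV or TSV file (delimiter chosen by extension: `.tsv`/`.txt`
#' are tab-separated, everything else comma-separated), checks the column
#' roles, and records per-column missingness fractions in attribute
#' `"missingness"`. The result is a plain `data.frame` ready for
#' [filter_and_impute()].
#'
#' @param path Input file with a header row.
#' @param outcome Name of the outcome column.
#' @param treatment Name of the treatment column (values must be 0/1,
#'   possibly with missing entries which are handled downstream).
#' @param markers Optional character vector naming the biomarker columns;
#'   default: every column other than outcome and treatment.
#' @return A `data.frame` with attributes `roles` (list with `outcome`,
#'   `treatment`, `markers`) and `missingness` (named fractions).
#' @export
read_trial_table <- function(path, outcome = "outcome",
                             treatment = "treatment", markers = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- as.data.frame(data.table::fread(path, sep = sep, header = TRUE,
                                        check.names = FALSE))
  if (anyDuplicated(names(df))) {
    stop("duplicate column names in input: ",
         paste(unique(names(df)[duplicated(names(df))]), collapse = ", "),
         call. = FALSE)
  }
  for (role in c(outcome, treatment)) {
    if (!role %in% names(df)) {
      stop(sprintf("required column '%s' not found in %s", role, path),
           call. = FALSE)
    }
  }
  markers <- markers %||% setdiff(names(df), c(outcome, treatment))
  missing_cols <- setdiff(markers, names(df))
  if (length(missing_cols)) {
    stop("biomarker columns not found: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (length(markers) == 0L) stop("no biomarker columns", call. = FALSE)
  tv <- df[[treatment]]
  bad <- unique(tv[!is.na(tv) & !(tv %in% c(0, 1))])
  if (length(bad)) {
    stop("treatment column must be 0/1; offending values: ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  attr(df, "roles") <- list(outcome = outcome, treatment = treatment,
                            markers = markers)
  attr(df, "missingness") <- vapply(df, function(z) mean(is.na(z)),
                                    numeric(1))
  df
}

#' Missingness filtering and mean imputation
#'
#' Applies the preprocessing rule used for real trial tables: rows with a
#' missing outcome or treatment are dropped (with a message), biomarker
#' columns with more than `max_missing` missing data (strictly greater;
#' exactly 10\% is retained) are excluded, and remaining missing biomarker
#' values are replaced by the mean of the observed values in that column.
#'
#' @param table A `data.frame` from [read_trial_table()] (or any data.frame
#'   with attribute `roles`).
#' @param max_missing Maximum tolerated missing fraction per biomarker
#'   column (default 0.10).
#' @return A complete [trial_data()]; attributes `dropped_markers` and
#'   `imputed_markers` list the removed and mean-imputed columns.
#' @export
filter_and_impute <- function(table, max_missing = 0.10) {
  roles <- attr(table, "roles")
  if (is.null(roles)) {
    stop("`table` must carry column roles (use read_trial_table())",
         call. = FALSE)
  }
  assert_scalar_number(max_missing, "max_missing", lower = 0, upper = 1)
  y <- table[[roles$outcome]]
  trt <- table[[roles$treatment]]
  keep_row <- !is.na(y) & !is.na(trt)
  if (any(!keep_row)) {
    message(sprintf("dropping %d row(s) with missing outcome or treatment",
                    sum(!keep_row)))
  }
  x <- as.matrix(table[keep_row, roles$markers, drop = FALSE])
  storage.mode(x) <- "double"
  frac <- colMeans(is.na(x))
  drop_cols <- roles$markers[frac > max_missing]
  keep_cols <- setdiff(roles$markers, drop_cols)
  if (length(keep_cols) == 0L) {
    stop("all biomarker columns exceed the missingness cutoff", call. = FALSE)
  }
  x <- x[, keep_cols, drop = FALSE]
  imputed <- character()
  na_any <- colSums(is.na(x)) > 0L
  if (any(na_any)) {
    for (j in which(na_any)) {
      mu <- mean(x[, j], na.rm = TRUE)
      x[is.na(x[, j]), j] <- mu
    }
    imputed <- keep_cols[na_any]
  }
  out <- trial_data(y = y[keep_row], trt = trt[keep_row], X = x,
                    markers = keep_cols)
  attr(out, "dropped_markers") <- drop_cols
  attr(out, "imputed_markers") <- imputed
  out
}

#' Keep the k most variable biomarkers
#'
#' Retains the `k` biomarker columns with the largest unbiased sample
#' variance (computed on the imputed data); ties are broken by original
#' column order for determinism.
#'
#' @param data A [trial_data()].
#' @param k Number of biomarkers to keep, `1 <= k <= m`.
#' @return A [trial_data()] restricted to the selected columns (original
#'   column order preserved).
#' @export
top_variance_filter <- function(data, k) {
  stopifnot(inherits(data, "trial_data"))
  m <- ncol(data$X)
  k <- assert_count(k, "k")
  if (k > m) stop(sprintf("k = %d exceeds the %d biomarkers", k, m),
                  call. = FALSE)
  if (k == m) return(data)
  v <- col_vars(data$X)
  sel <- sort(order(-v, seq_len(m))[seq_len(k)])
  trial_data(y = data$y, trt = data$trt, X = data$X[, sel, drop = FALSE],
             markers = data$markers[sel],
             clusters = if (!is.null(data$clusters)) data$clusters[sel])
}
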