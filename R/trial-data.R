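# The core data container: outcome, treatment indicator, biomarker matrix.

#' Trial dataset container
#'
#' Bundles the outcome vector, binary treatment indicator, and biomarker
#' matrix of one randomized trial, plus optional per-biomarker cluster
#' labels. All components must be complete (no missing values); use
#' [filter_and_impute()] to preprocess raw tables first.
#'
#' @param y Numeric outcome vector of length `n`.
#' @param trt Treatment indicator of length `n`, values in `{0, 1}`.
#' @param X Numeric `n x m` biomarker matrix.
#' @param markers Optional character vector of biomarker names (defaults to
#'   `colnames(X)` or `X1..Xm`).
#' @param clusters Optional integer vector of length `m` assigning each
#'   biomarker to a cluster.
#' @return An object of class `trial_data` with fields `y`, `trt`, `X`,
#'   `markers`, `clusters`.
#' @export
trial_data <- function(y, trt, X, markers = NULL, clusters = NULL) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- length(y)
  if (!is.numeric(trt) && !is.logical(trt)) {
    stop("`trt` must be numeric 0/1", call. = FALSE)
  }
  trt <- as.integer(trt)
  if (length(trt) != n || nrow(X) != n) {
    stop("`y`, `trt` and `X` must agree on the number of patients",
         call. = FALSE)
  }
  bad <- setdiff(unique(trt), c(0L, 1L))
  if (length(bad) || anyNA(trt)) {
    stop(sprintf("treatment indicator must be 0/1; found: %s",
                 paste(c(bad, if (anyNA(trt)) NA), collapse = ", ")),
         call. = FALSE)
  }
  if (anyNA(y) || anyNA(X)) {
    stop("trial_data must be complete; preprocess with filter_and_impute()",
         call. = FALSE)
  }
  m <- ncol(X)
  markers <- markers %||% colnames(X) %||% paste0("X", seq_len(m))
  if (length(markers) != m || anyDuplicated(markers)) {
    stop("`markers` must be m unique names", call. = FALSE)
  }
  colnames(X) <- markers
  if (!is.null(clusters)) {
    clusters <- as.integer(clusters)
    if (length(clusters) != m || anyNA(clusters)) {
      stop("`clusters` must be m integer labels", call. = FALSE)
    }
  }
  structure(list(y = y, trt = trt, X = X, markers = markers,
                 clusters = clusters),
            class = "trial_data")
}

#' @export
print.trial_data <- function(x, ...) {
  cat(sprintf("Trial dataset: %d patients (%d treated), %d biomarkers%s\n",
              length(x$y), sum(x$trt), ncol(x$X),
              if (is.null(x$clusters)) "" else
                sprintf(", %d clusters", length(unique(x$clusters)))))
  invisible(x)
}

#' @export
dim.trial_data <- function(x) c(length(x$y), ncol(x$X))

#' Write a trial dataset to a delimited file
#'
#' Columns are `outcome`, `treatment`, then one column per biomarker. When
#' the dataset carries a generating [sim_config()] (attribute `"truth"`,
#' set by [generate_trial()]), the true effect specification is written to
#' a JSON sidecar `<path>.truth.json` for downstream evaluation.
#'
#' @param data A [trial_data()] object.
#' @param path Output file; `.tsv` extension writes tab-separated,
#'   anything else comma-separated.
#' @param truth_sidecar Write the sidecar when truth is available
#'   (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_trial <- function(data, path, truth_sidecar = TRUE) {
  stopifnot(inherits(data, "trial_data"))
  df <- data.frame(outcome = data$y, treatment = data$trt, check.names = FALSE)
  df <- cbind(df, as.data.frame(data$X, check.names = FALSE))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  data.table::fwrite(df, path, sep = sep)
  truth <- attr(data, "truth")
  if (truth_sidecar && !is.null(truth)) {
    write_truth_json(truth, paste0(path, ".truth.json"))
  }
  invisible(path)
}

write_truth_json <- function(config, path) {
  eff <- config$effects
  str <- config$structure
  jsonlite::write_json(
    list(n = config$n, p_treat = config$p_treat, seed = config$seed,
         effects = list(intercept = eff$intercept, trt_main = eff$trt_main,
                        main = as.list(eff$main),
                        interaction = as.list(eff$interaction),
                        sigma = eff$sigma),
         structure = list(m = str$m, cluster_size = str$cluster_size,
                          rho = str$rho),
         analytic_pve = analytic_pve(eff, str, config$p_treat)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  eff <- effect_spec(
    intercept = x$effects$intercept, trt_main = x$effects$trt_main,
    main = unlist(x$effects$main) %||% numeric(),
    interaction = unlist(x$effects$interaction) %||% numeric(),
    sigma = x$effects$sigma)
  sim_config(n = x$n, effects = eff,
             structure = block_structure(x$structure$m,
                                         x$structure$cluster_size,
                                         x$structure$rho),
             p_treat = x$p_treat, seed = x$seed)
}
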