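# Synthetic randomized-trial data with block-correlated Gaussian biomarkers.
#
# The generative model for patient i is the linear outcome model
#   Y_i = b0 + bT * T_i + sum_j ( bX_j * X_ij + gX_j * X_ij * T_i ) + eps_i,
# with T_i ~ Bernoulli(p) independent of the biomarkers, X_i ~ N(0, Sigma)
# where Sigma is block diagonal with exchangeable blocks (1-rho) I + rho 11',
# and eps_i ~ N(0, sigma^2).

#' Effect specification for the trial simulator
#'
#' Sparse description of the true linear outcome model: intercept, treatment
#' main effect, per-biomarker main effects, per-biomarker interaction
#' effects, and the noise standard deviation. Biomarker effects are given as
#' named numeric vectors whose names are 1-based biomarker indices
#' (matching marker names `"X1"`, `"X2"`, ...).
#'
#' @param intercept Intercept `b0`.
#' @param trt_main Treatment main effect `bT`.
#' @param main Named numeric vector of biomarker main effects; names are
#'   biomarker indices, e.g. `c("1" = 0.5, "21" = 1.5)`.
#' @param interaction Named numeric vector of biomarker-by-treatment
#'   interaction effects, same naming convention.
#' @param sigma Noise standard deviation (must be > 0).
#' @return An object of class `effect_spec`.
#' @examples
#' effect_spec(trt_main = 0.5, main = c("1" = 0.5), interaction = c("1" = 1),
#'             sigma = 5)
#' @export
effect_spec <- function(intercept = 0, trt_main = 0, main = numeric(),
                        interaction = numeric(), sigma = 1) {
  assert_scalar_number(intercept, "intercept")
  assert_scalar_number(trt_main, "trt_main")
  assert_scalar_number(sigma, "sigma", lower = 0, strict_lower = TRUE)
  main <- parse_sparse_effects(main, "main")
  interaction <- parse_sparse_effects(interaction, "interaction")
  structure(list(intercept = intercept, trt_main = trt_main,
                 main = main, interaction = interaction, sigma = sigma),
            class = "effect_spec")
}

parse_sparse_effects <- function(x, name) {
  if (length(x) == 0L) return(stats::setNames(numeric(), character()))
  if (!is.numeric(x) || is.null(names(x)) || any(names(x) == "")) {
    stop(sprintf("`%s` must be a named numeric vector (names = indices)",
                 name), call. = FALSE)
  }
  idx <- suppressWarnings(as.integer(names(x)))
  if (anyNA(idx) || any(idx < 1L)) {
    stop(sprintf("`%s` names must be positive integer biomarker indices",
                 name), call. = FALSE)
  }
  if (anyDuplicated(idx)) {
    stop(sprintf("duplicate biomarker index in `%s`", name), call. = FALSE)
  }
  stats::setNames(as.numeric(x), as.character(idx))
}

#' @export
print.effect_spec <- function(x, ...) {
  cat("Effect specification\n")
  cat("  intercept:", x$intercept, "  treatment main effect:", x$trt_main,
      "  sigma:", x$sigma, "\n")
  cat("  main effects:",
      if (length(x$main)) paste0("X", names(x$main), "=", x$main,
                                 collapse = ", ") else "none", "\n")
  cat("  interactions:",
      if (length(x$interaction)) paste0("X", names(x$interaction), ":T=",
                                        x$interaction, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' Block-exchangeable correlation structure for the biomarker panel
#'
#' The `m` biomarkers are partitioned into contiguous clusters of
#' `cluster_size` members. Within a cluster the correlation between any two
#' biomarkers is `rho`; biomarkers in different clusters are independent.
#' Each biomarker is marginally standard normal.
#'
#' @param m Number of biomarkers.
#' @param cluster_size Cluster size `c`; must divide `m`. Default 20.
#' @param rho Within-cluster correlation, in `[0, 1)`.
#' @return An object of class `block_structure` with the implied cluster
#'   labels (`rep(1:(m/c), each = c)`).
#' @export
block_structure <- function(m, cluster_size = 20L, rho = 0) {
  m <- assert_count(m, "m")
  cluster_size <- assert_count(cluster_size, "cluster_size")
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) ||
      rho < 0 || rho >= 1) {
    stop("`rho` must lie in [0, 1)", call. = FALSE)
  }
  if (m %% cluster_size != 0L) {
    stop(sprintf("cluster_size (%d) must divide m (%d)", cluster_size, m),
         call. = FALSE)
  }
  structure(list(m = m, cluster_size = cluster_size, rho = as.numeric(rho),
                 clusters = rep(seq_len(m %/% cluster_size),
                                each = cluster_size)),
            class = "block_structure")
}

#' @export
print.block_structure <- function(x, ...) {
  cat(sprintf(
    "Block correlation structure: %d biomarkers, %d clusters of %d, rho = %g\n",
    x$m, x$m %/% x$cluster_size, x$cluster_size, x$rho))
  invisible(x)
}

#' Simulation configuration for one randomized trial
#'
#' @param n Sample size.
#' @param effects An [effect_spec()].
#' @param structure A [block_structure()].
#' @param p_treat Treatment allocation probability (default 0.5, i.e.
#'   `T ~ Bernoulli(0.5)`).
#' @param seed Integer seed; the generated dataset is bit-identical for
#'   identical seeds.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n, effects, structure, p_treat = 0.5, seed = 1L) {
  n <- assert_count(n, "n")
  stopifnot(inherits(effects, "effect_spec"),
            inherits(structure, "block_structure"))
  assert_scalar_number(p_treat, "p_treat", lower = 0, upper = 1,
                       strict_lower = TRUE, strict_upper = TRUE)
  seed <- assert_count(seed, "seed", min = -.Machine$integer.max)
  idx <- as.integer(c(names(effects$main), names(effects$interaction)))
  if (length(idx) && max(idx) > structure$m) {
    stop(sprintf("effect index %d exceeds number of biomarkers m = %d",
                 max(idx), structure$m), call. = FALSE)
  }
  structure(list(n = n, effects = effects, structure = structure,
                 p_treat = p_treat, seed = seed),
            class = "sim_config")
}

# Draw an n x m matrix with the block covariance via the shared-factor
# representation X_ij = sqrt(rho) U_{c(j)} + sqrt(1-rho) Z_ij, which has
# exactly the exchangeable-block covariance and costs O(nm) (no Cholesky).
draw_block_normals <- function(n, structure) {
  m <- structure$m
  k <- m %/% structure$cluster_size
  rho <- structure$rho
  if (rho == 0) {
    x <- matrix(stats::rnorm(n * m), n, m)
  } else {
    u <- matrix(stats::rnorm(n * k), n, k)
    z <- matrix(stats::rnorm(n * m), n, m)
    x <- sqrt(rho) * u[, structure$clusters, drop = FALSE] +
      sqrt(1 - rho) * z
  }
  colnames(x) <- paste0("X", seq_len(m))
  x
}

#' Generate block-correlated standard-normal biomarkers
#'
#' Rows are i.i.d. multivariate normal with mean zero and the
#' block-exchangeable covariance of `structure`; every column is marginally
#' `N(0, 1)`.
#'
#' @param n Number of rows (patients).
#' @param structure A [block_structure()].
#' @param seed Integer seed (the caller's RNG state is left untouched).
#' @return An `n x m` numeric matrix with columns `X1..Xm`.
#' @export
generate_biomarkers <- function(n, structure, seed = 1L) {
  n <- assert_count(n, "n")
  stopifnot(inherits(structure, "block_structure"))
  with_seed(seed, draw_block_normals(n, structure))
}

#' Simulate one randomized trial dataset
#'
#' Draws `T ~ Bernoulli(p_treat)` i.i.d. and independent of the biomarkers,
#' the biomarker matrix from the block-correlated normal model, and the
#' outcome from the linear model
#' `Y = b0 + bT T + sum_j (bX_j X_j + gX_j X_j T) + eps`,
#' `eps ~ N(0, sigma^2)`. The treatment indicator is returned raw in
#' `{0, 1}`; any centering required by downstream screening is applied
#' there, so the dataset mirrors a real trial table.
#'
#' @param config A [sim_config()].
#' @return A [trial_data()] object carrying the generating `sim_config` in
#'   attribute `"truth"`.
#' @export
generate_trial <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n
  eff <- config$effects
  str <- config$structure
  out <- with_seed(config$seed, {
    trt <- stats::rbinom(n, 1L, config$p_treat)
    x <- draw_block_normals(n, str)
    eps <- stats::rnorm(n, 0, eff$sigma)
    list(trt = trt, x = x, eps = eps)
  })
  signal <- true_signal(out$x, out$trt, eff)
  y <- signal + out$eps
  dat <- trial_data(y = y, trt = out$trt, X = out$x,
                    clusters = str$clusters)
  attr(dat, "truth") <- config
  dat
}

# Noiseless conditional mean E[Y | X, T] under an effect_spec.
true_signal <- function(x, trt, effects) {
  s <- rep(effects$intercept, length(trt)) + effects$trt_main * trt
  if (length(effects$main)) {
    j <- as.integer(names(effects$main))
    s <- s + drop(x[, j, drop = FALSE] %*% effects$main)
  }
  if (length(effects$interaction)) {
    j <- as.integer(names(effects$interaction))
    s <- s + drop(x[, j, drop = FALSE] %*% effects$interaction) * trt
  }
  s
}

# Covariance submatrix of the active biomarkers under a block structure.
active_sigma <- function(idx, structure) {
  cl <- structure$clusters[idx]
  s <- structure$rho * outer(cl, cl, "==")
  diag(s) <- 1
  s
}

#' Closed-form proportion of variance explained by the true model
#'
#' Computes `Var(E[Y | X, T]) / Var(Y)` exactly under the generative
#' distribution: biomarkers standard normal with block-exchangeable
#' correlation, treatment Bernoulli(`p_treat`) independent of biomarkers.
#' Writing `a(T) = bX + gX * T` for the active-coordinate coefficient
#' vector, the signal variance decomposes as
#' `bT^2 p (1-p) + (1-p) a(0)' S a(0) + p a(1)' S a(1)` with `S` the active
#' submatrix of the biomarker covariance, which accounts for
#' main-effect/interaction covariance terms and within-cluster correlation
#' between effect-bearing biomarkers.
#'
#' @param effects An [effect_spec()].
#' @param structure A [block_structure()].
#' @param p_treat Treatment allocation probability.
#' @return The proportion of variance explained, in `[0, 1)`.
#' @seealso [empirical_pve()] for the Monte-Carlo counterpart.
#' @export
analytic_pve <- function(effects, structure, p_treat = 0.5) {
  stopifnot(inherits(effects, "effect_spec"),
            inherits(structure, "block_structure"))
  assert_scalar_number(p_treat, "p_treat", lower = 0, upper = 1,
                       strict_lower = TRUE, strict_upper = TRUE)
  idx <- sort(unique(as.integer(c(names(effects$main),
                                  names(effects$interaction)))))
  if (length(idx) && max(idx) > structure$m) {
    stop("effect index exceeds number of biomarkers", call. = FALSE)
  }
  v_sig <- effects$trt_main^2 * p_treat * (1 - p_treat)
  if (length(idx)) {
    a0 <- stats::setNames(numeric(length(idx)), as.character(idx))
    a0[names(effects$main)] <- effects$main
    a1 <- a0
    a1[names(effects$interaction)] <-
      a1[names(effects$interaction)] + effects$interaction
    s <- active_sigma(idx, structure)
    quad <- function(a) drop(a %*% s %*% a)
    v_sig <- v_sig + (1 - p_treat) * quad(a0) + p_treat * quad(a1)
  }
  v_sig / (v_sig + effects$sigma^2)
}

#' Monte-Carlo R-squared of the true mean function
#'
#' Simulates outcomes from the generative model and returns the sample
#' R-squared of the (known) conditional mean, `1 - RSS/TSS`. Only the
#' effect-bearing biomarker coordinates are drawn: the joint law of the
#' conditional mean depends on those coordinates alone, and their implied
#' covariance submatrix is reproduced exactly, so this is an exact
#' marginalization of the full `m`-biomarker simulation (and makes the
#' 10^6-sample check cheap). Serves as the simulation oracle for
#' [analytic_pve()].
#'
#' @inheritParams analytic_pve
#' @param n Monte-Carlo sample size.
#' @param seed Integer seed.
#' @return Sample R-squared of the true mean function.
#' @export
empirical_pve <- function(effects, structure, p_treat = 0.5, n = 1e6,
                          seed = 1L) {
  stopifnot(inherits(effects, "effect_spec"),
            inherits(structure, "block_structure"))
  n <- assert_count(n, "n", min = 2L)
  idx <- sort(unique(as.integer(c(names(effects$main),
                                  names(effects$interaction)))))
  with_seed(seed, {
    trt <- stats::rbinom(n, 1L, p_treat)
    s <- rep(effects$intercept, n) + effects$trt_main * trt
    if (length(idx)) {
      cl <- structure$clusters[idx]
      rho <- structure$rho
      xa <- matrix(stats::rnorm(n * length(idx)), n)
      if (rho > 0) {
        ucl <- unique(cl)
        u <- matrix(stats::rnorm(n * length(ucl)), n)
        xa <- sqrt(rho) * u[, match(cl, ucl), drop = FALSE] +
          sqrt(1 - rho) * xa
      }
      a0 <- stats::setNames(numeric(length(idx)), as.character(idx))
      a0[names(effects$main)] <- effects$main
      g <- stats::setNames(numeric(length(idx)), as.character(idx))
      g[names(effects$interaction)] <- effects$interaction
      s <- s + drop(xa %*% a0) + drop(xa %*% g) * trt
    }
    y <- s + stats::rnorm(n, 0, effects$sigma)
    1 - sum((y - s)^2) / sum((y - mean(y))^2)
  })
}

#' Preset simulation scenarios
#'
#' Ready-made [sim_config()]s for the scenarios used throughout the power
#' and familywise-error studies: 1000 biomarkers in 50 clusters of 20, one
#' biomarker (`X1`, the first member of cluster 1) carrying both a main
#' effect (0.5) and a treatment interaction (1), four biomarkers (`X21`,
#' `X41`, `X61`, `X81`, first members of clusters 2-5) carrying main
#' effects only (1.5 each), treatment main effect 0.5, noise standard
#' deviation 5, treatment Bernoulli(0.5). Under this configuration the
#' proportion of variance explained by the true model is 0.292.
#'
#' @param preset One of `"correlated"` (within-cluster correlation 0.6),
#'   `"independent"` (`rho = 0`), `"global_null"` (as `"correlated"` but
#'   with every interaction effect set to zero), or
#'   `"cancellation"` (independent biomarkers with the main effect of the
#'   interacting biomarker set so its marginal association cancels:
#'   `bX1 = -gX1 * p_treat`).
#' @param n Sample size (default 1500).
#' @param m Number of biomarkers (default 1000).
#' @param rho Override the preset's within-cluster correlation.
#' @param main_effect_size Main effect of the four main-effect-only
#'   biomarkers (default 1.5).
#' @param interaction_effect Interaction effect of `X1` (default 1).
#' @param seed Integer seed.
#' @return A [sim_config()].
#' @export
trial_scenario <- function(preset = c("correlated", "independent",
                                      "global_null", "cancellation"),
                           n = 1500L, m = 1000L, rho = NULL,
                           main_effect_size = 1.5,
                           interaction_effect = 1, seed = 1L) {
  preset <- match.arg(preset)
  m <- assert_count(m, "m")
  if (m %% 20L != 0L || m < 100L) {
    stop("presets need m to be a multiple of 20 and at least 100 (five clusters)",
         call. = FALSE)
  }
  cs <- 20L
  k <- m %/% cs
  # first members of clusters 2-5 carry main effects only
  main_idx <- as.character(cs * (1:4) + 1L)
  rho <- rho %||% switch(preset,
                         correlated = 0.6, global_null = 0.6,
                         independent = 0, cancellation = 0)
  gx1 <- if (preset == "global_null") numeric() else
    stats::setNames(interaction_effect, "1")
  bx1 <- if (preset == "cancellation") -interaction_effect * 0.5 else 0.5
  eff <- effect_spec(
    intercept = 0, trt_main = 0.5,
    main = c(stats::setNames(bx1, "1"),
             stats::setNames(rep(main_effect_size, 4L), main_idx)),
    interaction = gx1,
    sigma = 5)
  sim_config(n = n, effects = eff,
             structure = block_structure(m, cs, rho),
             p_treat = 0.5, seed = seed)
}
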