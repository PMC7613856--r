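---
title: "Two-stage screening for biomarker-treatment interactions"
author: "ridgescreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage screening for biomarker-treatment interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ridgescreen)
```

## The problem

Randomized clinical trials increasingly measure high-dimensional biomarker
panels (expression arrays, metabolomics, genotypes) alongside the primary
outcome. A *predictive* biomarker is one whose value modifies the effect of
treatment — a biomarker-treatment interaction. Testing every biomarker for
an interaction at a familywise error rate (FWER) of $\bar\alpha$ forces a
Bonferroni-type correction over $m$ tests, and with $m$ in the thousands the
per-test threshold $\bar\alpha/m$ destroys power.

Two-stage testing recovers much of that power. A *screening* statistic,
computed in stage 1, either selects a subset of biomarkers to test or ranks
all of them so that stage-2 significance thresholds can be front-loaded onto
the most promising candidates. The FWER guarantee survives **only if** the
stage-1 statistic is (asymptotically) independent of the stage-2 interaction
statistic. In a randomized trial the treatment indicator $T$ is independent
of every biomarker by design, and that independence is exactly what makes
marginal-association screening legitimate here.

## Models

Stage 2 tests one biomarker at a time with the linear model

$$E(Y_i \mid X_{ij}, T_i) = \beta_{0j} + \beta_{X_j} X_{ij} + \beta_T T_i +
  \beta_{X_j \times T}\, X_{ij} T_i,$$

rejecting $H_{0j}\colon \beta_{X_j\times T}=0$ with a two-sided $t$
statistic on $n-4$ degrees of freedom (homoscedastic errors; exact under
the Gaussian linear model and asymptotically the Wald test). `ridgescreen`
computes all $m$ tests in one vectorized pass through the per-arm
decomposition of the saturated model (the interaction estimate is the
between-arm slope difference with the pooled residual variance), which is
algebraically identical to the per-biomarker least-squares fit; the test
suite asserts agreement with an independent normal-equations solve.

Stage 1 offers two screens:

* **Univariate** — for each $j$, fit
  $E(Y_i \mid X_{ij}) = \delta_{0j} + \delta_{X_j} X_{ij}$ and keep the
  two-sided p-value for $\delta_{X_j}=0$. The regression deliberately does
  *not* adjust for $T$ (the screening model is taken literally); because
  $T \perp X$ and the trial arms are balanced in expectation, adjusting
  would change little.
* **Ridge** — fit the joint model
  $E(Y_i \mid T_i, X_{i1..m}) = \delta_0 + \delta_T T_i + \sum_j
  \delta_{X_j} X_{ij}$ with an $L_2$ penalty
  $\lambda_n(\delta_T^2 + \sum_j \delta_{X_j}^2)$. Including the treatment
  main effect, and centering $T$ (and $Y$) so that $E(T)=0$ after
  centering, is what makes the stage-1 coefficient asymptotically
  independent of the stage-2 interaction estimator under the interaction
  null in a randomized trial. Biomarkers are ranked by descending
  $|\hat\delta_{X_j}|$ on the standardized scale; the treatment coefficient
  never enters the ranking.

The point of the multivariate screen is correlation. When biomarkers form
correlated clusters, the univariate screen hands every cluster-mate of a
true signal an exaggerated marginal association, flooding the top ranks
with proxies. The ridge fit adjusts each biomarker for all others, demotes
the proxies, and — as the property tests verify on scaled-down
simulations — that translates into a substantially better stage-2 ranking
when correlation is strong.

## Significance allocation at stage 2

Three schedules convert stage-1 output into per-biomarker thresholds:

| scheme | thresholds |
|---|---|
| `bonferroni_schedule` | every biomarker at $\bar\alpha/m$ |
| `subset_schedule` | the $m^*$ biomarkers with stage-1 $p < \alpha_1$ at $\bar\alpha/m^*$; the rest untested |
| `weighted_schedule` | ranked buckets of sizes $B, 2B, 4B, \dots$ at per-test levels $(\bar\alpha/2)/B, (\bar\alpha/4)/(2B), \dots, (\bar\alpha/2^{k+1})/(2^k B)$ |

The bucket budgets $\bar\alpha/2^{k+1}$ form a geometric series, so the
weighted scheme never allocates more than $\bar\alpha$ in total.

Conventions, fixed once and used everywhere:

* Rejection (and stage-1 selection) uses the **strict** inequality
  $p < \text{threshold}$; ties have probability zero under continuous
  models and strictness is conservative.
* The final, possibly partial, bucket keeps its full per-test threshold;
  leftover alpha mass is *not* redistributed. This follows the bucket
  formula literally and remains conservative.
* An $m^*=0$ selection yields an all-zero schedule: nothing is tested and
  nothing can be rejected.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| $\bar\alpha$ (`alpha`) | 0.05 | target overall FWER |
| $\alpha_1$ (`alpha1`) | 0.05 | stage-1 selection level of the threshold procedure (unadjusted) |
| $B$ | 5 | top bucket size of the weighted scheme |
| `n_folds` | 5 | CV folds for the ridge penalty, stratified by arm |
| `nlambda`, `lambda_min_ratio` | 100, $10^{-4}$ | log-spaced penalty grid from $\lambda_{\max}=\max_j |Z^\top y|$ (standardized scale) downward |

## Numerical choices

The ridge solver is exact, not iterative. On centered/standardized data
the objective is $\|y - Z\delta\|^2 + \lambda\|\delta\|^2$ (sums of
squares, raw $\lambda$), so the solution solves
$(Z^\top Z + \lambda I)\,\delta = Z^\top y$. For cross-validation each
training fold's Gram matrix — obtained by downdating the full-data
crossproduct and re-centering/re-scaling with that fold's own training
means and variances — is eigendecomposed once, after which the entire
penalty path costs a diagonal shift per $\lambda$. Consequences worth
knowing:

* coefficients agree with closed forms to machine precision (the test
  suite checks the orthonormal-design shrinkage factor
  $(n-1)/(n-1+\lambda)$ at $10^{-8}$ tolerance);
* $\lambda = 0$ on a full-rank design reproduces OLS exactly; on a
  rank-deficient design the solver falls back to the spectral
  pseudo-inverse rather than failing silently;
* ties in $|\hat\delta_{X_j}|$ (and in univariate p-values) are broken by
  original column index, so rankings are deterministic;
* a constant biomarker column is an error for the ridge screen and a
  warned, rank-last $p=1$ for the univariate screen;
* the stage-2 test keeps $T$ raw in $\{0,1\}$ — centering there would not
  change the interaction p-value;
* CV error is the mean squared validation residual aggregated over all
  points; the selected $\lambda$ is the grid minimizer (first index, i.e.
  the more regularized end, on exact ties).

## What the simulator states — and what it does not

`trial_scenario()` encodes the reference simulation world: $m = 1000$
biomarkers in 50 clusters of 20 with within-cluster exchangeable
correlation $\rho$ (0.6 in the correlated presets, 0 in the independent
one), each biomarker marginally $N(0,1)$, treatment Bernoulli(0.5)
independent of biomarkers, and the linear outcome with $\beta_T = 0.5$,
$\beta_{X_1} = 0.5$, $\beta_{X_1\times T} = 1$,
$\beta_{X_{21}} = \beta_{X_{41}} = \beta_{X_{61}} = \beta_{X_{81}} = 1.5$,
$\sigma_\varepsilon = 5$. The interacting biomarker is the first member of
cluster 1; the four main-effect-only biomarkers are the first members of
clusters 2–5 (their cluster placement is followed literally; nothing in
the power conclusions is believed to depend on it). Under this
configuration the proportion of variance explained by the true model is
$10.3125 / 35.3125 = 0.292$, which `analytic_pve()` reproduces in closed
form and `empirical_pve()` verifies by simulation. The block-correlated
draws use the shared-factor representation
$X_{ij} = \sqrt\rho\, U_{c(j)} + \sqrt{1-\rho}\, Z_{ij}$ — mathematically
identical to the stated covariance at $O(nm)$ cost.

The `cancellation` preset sets $\beta_{X_1} = -\beta_{X_1\times T}\,P(T=1)$
so the marginal association of the interacting biomarker vanishes exactly
(the cancellation point is computed from the generative model, since the
marginal slope is $\beta_{X_1} + \beta_{X_1\times T} E[T]$). In that world
stage-1 screening is uninformative about $X_1$ and the two-stage
procedures fall behind the single-step test — the known failure mode of
marginal screening, and a property test in the suite.

What the simulator does **not** emulate: non-Gaussian biomarker
distributions (genotype dosages, counts), heteroscedastic or non-linear
outcome models, realistic correlation decay (real linkage disequilibrium
or co-expression is not exchangeable within rigid blocks), missing data,
batch effects, or covariate-adaptive randomization. A green Monte-Carlo
test therefore establishes the operating characteristics *of the stated
Gaussian world*, not of any particular omics platform; the preprocessing
helpers (`filter_and_impute()`, `top_variance_filter()`) exist precisely
because real tables violate these assumptions before analysis begins.

## Error definitions and Monte-Carlo scaling

Power is the probability of a *cluster discovery*: rejecting at least one
biomarker in a cluster that contains a truly interacting member. The
default familywise error event is correspondingly cluster-level — any
rejection in a cluster containing **no** truly interacting member — so a
within-signal-cluster rejection counts as a discovery, not an error;
under a global null this reduces to the standard FWER. The stricter
biomarker-level event ("any rejection of a biomarker whose own
interaction effect is zero") is available via `fwer_level = "biomarker"`.

Replicate $r$ of `estimate_operating_characteristics()` uses seed
`seed + r` and every procedure is evaluated on the same dataset with the
same stage-2 statistics (common random numbers), so procedure comparisons
are paired and their differences carry much smaller Monte-Carlo error than
the marginal estimates. The reference studies used 1000 replicates; the
package default is configurable, and the test suite runs the heavy
criteria at 150 replicates per scenario (the acceptance script at 250)
with tolerance bands computed from the binomial Monte-Carlo standard error
at the replicate count actually used — reducing $R$ widens the bands, it
never narrows them.

## Known limitations

* The FWER guarantee is asymptotic and requires treatment-biomarker
  independence; it is proven for linear regression only. A logistic stage
  2 can be biased under model misspecification and is deliberately not
  provided.
* Ridge averages effects across strongly correlated biomarkers, which can
  still promote a few proxies; lasso screening would avoid the averaging
  but lacks the smoothness needed for the between-stage independence
  argument, and is out of scope.
* The univariate screen follows its screening model literally and does not
  adjust for treatment.
* The between-stage independence diagnostic is a finite-sample Pearson
  correlation; a confidence interval covering zero is consistent with, not
  proof of, independence.
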