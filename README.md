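# ridgescreen

Two-stage detection of biomarker-treatment interactions in randomized
clinical trials, with a multivariate ridge-regression screening stage that
accounts for correlation among high-dimensional biomarkers.

## The problem

Trials increasingly measure thousands of biomarkers per patient. A
*predictive* biomarker modifies the treatment effect, i.e. it carries a
biomarker-treatment interaction in the outcome model

> E(Y | X_j, T) = β0j + β_Xj X_j + β_T T + β_{Xj×T} X_j T,

and the one-at-a-time Wald test of H0: β_{Xj×T} = 0 must survive a
multiplicity correction over m tests. At a familywise error rate (FWER)
ᾱ, plain Bonferroni tests each biomarker at ᾱ/m and pays dearly in power.

Two-stage testing first screens biomarkers with a statistic that is
asymptotically independent of the interaction test — in a randomized
trial, marginal association with the outcome qualifies, because treatment
is independent of the biomarkers by design — and then spends the alpha
budget unevenly:

* **univariate threshold**: keep biomarkers with stage-1 p < α1, test each
  at ᾱ/m*;
* **univariate rank** / **ridge rank**: test everything, but allocate
  per-test levels (ᾱ/2)/B, (ᾱ/4)/(2B), (ᾱ/8)/(4B), ... down ranked
  buckets of sizes B, 2B, 4B, ...

The package's centerpiece is the **ridge screen**: stage 1 fits
E(Y | T, X) = δ0 + δ_T T + Σ_j δ_Xj X_j by ridge regression (one shared
penalty on δ_T and all δ_Xj, five-fold cross-validated, treatment and
outcome centered, biomarkers standardized) and ranks biomarkers by
|δ̂_Xj|. Unlike the univariate screen it adjusts every biomarker for all
others, so correlated "proxies" of a true signal are demoted and true
signals land in the generous buckets — substantially higher power when
biomarkers are strongly correlated, at the same FWER.

## Worked example

```r
library(ridgescreen)

cfg <- trial_scenario("correlated", n = 1500, m = 1000, seed = 42)
round(analytic_pve(cfg$effects, cfg$structure), 3)
#> [1] 0.292

trial <- generate_trial(cfg)
trial
#> Trial dataset: 1500 patients (717 treated), 1000 biomarkers, 50 clusters

dec <- run_procedure(trial, "ridge_rank", alpha = 0.05, B = 5, cv_seed = 42)
dec
#> Decisions under weighted schedule (overall level 0.05): 1 rejection(s)
#>   rejected: X1

dec$screening
#> Stage-1 ridge screening of 1000 biomarkers
#>   penalty lambda = 2485.29 (5-fold CV over 100 values)
#>   top ranked: X41, X81, X21, X61, X1

subset(dec$table, rejected)
#>   biomarker      p_value threshold rejected
#> 1        X1 5.218565e-05     0.005     TRUE
```

What happened: the simulated trial hides one true interaction (X1, the
first member of biomarker cluster 1; the scenario's true model explains
29.2% of outcome variance). The ridge screen ranks X1 fifth — behind the
four strong main-effect biomarkers, but inside the top bucket — so its
stage-2 interaction p-value of 5.2e-5 is compared against the top-bucket
threshold (0.05/2)/5 = 0.005 instead of the Bonferroni 5e-5. The decision
table reports every tested biomarker with its p-value, its allocated
threshold, and the rejection flag.

`estimate_operating_characteristics()` repeats this over replicate trials
(procedures share datasets, so comparisons are paired) and returns
cluster-discovery power and FWER with Monte-Carlo standard errors;
`between_stage_diagnostic()` checks the near-zero correlation between
stage-1 and stage-2 statistics that the FWER guarantee relies on.

## Command line

```sh
Rscript exec/ridgescreen simulate --preset correlated --n 1500 --m 1000 --seed 7 --out trial.csv
Rscript exec/ridgescreen run --input trial.csv --procedure ridge_rank --alpha 0.05 --outdir results/
Rscript exec/ridgescreen evaluate --scenarios scenarios.json --out oc.tsv
Rscript exec/ridgescreen diagnose --input trial.csv --out diag.json
```

`run` accepts real trial tables (CSV/TSV; `--outcome`, `--treatment` name
the columns) and applies the standard preprocessing first: drop biomarkers
with more than 10% missing values, mean-impute the rest, optionally keep
the `--top-k` most variable biomarkers.

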