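---
title: "Validating genetic evaluations with partial and whole data: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating genetic evaluations with partial and whole data: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrcv)
```

## The problem

Breeders rank animals on estimated breeding values (EBV) computed by BLUP
from the mixed-model equations. Whether those EBV can be trusted — are they
biased, over-dispersed, and how well do they rank animals — is usually asked
of a *population*: the correlation between true breeding values (TBV) and
EBV across a cohort of selection candidates. TBV are never observed, so
`lrcv` implements the cross-validation strategy of comparing two evaluations
of the same animals: one from **partial** data (records up to a cutoff, or a
random subset) and one from **whole** data (everything). If the model is
right, the new records move EBV in a statistically predictable way, and the
movement itself estimates the quantities of interest.

## Model

The animal model is `y = X b + Z u + e`, with `Var(u) = K σ²_u` for a
relationship matrix `K` (pedigree NRM from the tabular method, or VanRaden
method-1 GRM) and `Var(e) = I σ²_e`. Solving Henderson's equations for the
partial and the whole data gives EBV vectors `û_p`, `û_w`, and the inverse
of the coefficient matrix gives the prediction-error variance and covariance
(PEV/PEC) blocks `C_p`, `C_w` and the fixed-effect error covariance `C^ββ`.

Writing `S` for the centering matrix and `vf = tr(S K_focal)/n`
(equivalently `1 + F̄ − 2f̄`, the relationship-adjusted genetic-variance
factor), the key quantity for a focal set is

```
acc² = [ vf σ²_u,∞ − (mean PEV − mean PEC) ] / ( vf σ²_u,∞ )
```

the squared *population accuracy*. Under selection the equilibrium genetic
variance `σ²_u,∞ = (1 − k) σ²_u` replaces the base variance; `k` is a user
input (estimated elsewhere or derived from the selection scheme), never
estimated internally, because the mixed model itself provides no estimator
for it.

The comparison statistics and their expectations, all computed by
`lr_stats()` / `lr_expectations()`:

| statistic | definition | expectation |
|---|---|---|
| `mu_wp` | `mean(û_p) − mean(û_w)` | 0 if unbiased |
| `b_wp` | `cov(û_w, û_p)/var(û_p)` | 1; `θ_w/θ_p` under uniform scaling |
| `b_pw` | `cov(û_p, û_w)/var(û_w)` | `acc_p²/acc_w²` |
| `rho_wp` | `cor(û_p, û_w)` | `acc_p/acc_w` |
| `rho2_cov` | `cov(û_p, û_w)/(vf σ²_u,∞)` | `acc_p²` |
| `predictivity` | `cor(y*, û_p)` | `acc_p · h_∞` (precise fixed effects) |

These rest on `Cov(û_w, û_p) = Var(û_p)`: new data refine, and do not
contradict, old predictions when the model is correct and no information is
discarded. `young_bull_counterexample()` quantifies the canonical failure —
a later evaluation that *drops* the dam record used by the earlier one — in
closed form, using the progeny-test variance ratio `λ = (4 − h²)/h²`.

Two practical corrections around predictivity are included.
`precorrection_inflation(n, m)` gives the upward bias
`(m − 1)/(n − (m − 1))` in apparent accuracy caused by treating estimated
fixed effects (m balanced contemporary groups estimated from n records) as
known when precorrecting phenotypes. `selected_to_unselected_acc(acc, k)`
converts an accuracy measured on the selection-reduced variance scale to the
unselected scale via `sqrt(k + (1 − k) acc²)`: prediction-error variance is
unchanged while the genetic variance is restored, which is also how the
package validates the formula by simulation in its test suite.

## Tunable parameters

* `variance_components(sigma2_u, sigma2_e, sigma2_u_inf | k)` — trait
  variance units. Defaults nothing; heritability and the variance ratio
  `λ = σ²_e/σ²_u` follow. `sigma2_u_inf` defaults to `sigma2_u` (no
  selection).
* `solve_mme(fixed = ~ ...)` — any formula of factors and covariates; the
  first level of each factor is dropped (treatment constraint). Precorrected
  data `y* = y − Xβ̂` are invariant to that choice (tested).
* `make_partition(fraction, scheme)` — random masking uses the floor rule;
  the cutoff scheme masks whole generations. The validation set is the set
  of individuals with at least one masked record.
* `grm(freqs, ridge)` — observed allele frequencies by default,
  base-population frequencies optionally; `ridge ≈ 1e-6` makes a GRM
  invertible for GBLUP. Loci pass `maf_filter()` (strict `>` threshold,
  default 0.01).
* `em_reml(tol = 1e-6, max_iter = 500)` — convergence is measured relative
  to the total variance (a per-component criterion stalls when the genetic
  component collapses); `σ²_u < 1e-6` of the total is reported as a boundary
  fit, flagged rather than an error.

## What the simulator emulates — and what it does not

`simulate_population()` generates discrete non-overlapping generations:
founder sires and dams, each dam mated to one random sire, balanced sex
ratio, infinitesimal TBV (`u = parent average + Mendelian sampling` with
variance `σ²_u (1 − ¼(1+F_s) − ¼(1+F_d))`), Gaussian contemporary-group
effects, and optional truncation selection of parents on phenotype, TBV or
EBV between generations. Unlinked biallelic markers are gene-dropped for
the GBLUP path. The defaults — 25 sires, 250 dams, two offspring per dam
(500 phenotyped animals in one final cohort), `h² = 0.4`, 25 contemporary
groups with effect SD 1 — emulate a single-cohort beef-cattle design with a
random 50% of records masked; the group-effect SD is set comparable to the
phenotypic SD, a realistic magnitude for herd-year-season effects, since no
canonical value exists.

Deliberately absent: linkage and LD (markers are exchangeable, so GRM→NRM
convergence holds but marker-based fine structure does not), overlapping
generations, maternal/permanent-environment effects, genotyping error and
imputation, multi-trait selection. Passing tests therefore demonstrate the
statistical machinery under the stated generative model, not robustness to
the many ways real data depart from it.

## Numerical choices

* Dense linear algebra throughout (Cholesky factorizations, `chol2inv`),
  exact PEV/PEC from the full coefficient-matrix inverse; intended scale is
  a few thousand animals.
* The variance factor uses the trace form `tr(S K)/n` — the grand mean
  includes the diagonal. This differs from the verbal `1 + F̄ − 2f̄` by
  self-coancestry terms of order `1/n`, but it is the exact quantity in
  every quadratic-form expectation, so it is the one implemented.
* Ratio statistics use `1/n` (co)variances (the normalization cancels);
  the reported variance of EBV change `vd_wp` uses the sample convention
  `1/(n−1)`.
* Accuracy estimates (`rho2_cov`, `acc_from_predictivity`) are **not**
  clipped to `[0, 1]`; out-of-range values are flagged so that users see
  sampling noise. The PEV-based accuracy clips a negative numerator at zero
  with a warning.
* Replicated experiments with a fixed design (`lr_sim_experiment()`) reuse
  the Cholesky factor of the coefficient matrix across replicates and only
  redraw `(u, e)`; with `resample_mask = TRUE` the partial system is
  refactorized per replicate.
* In subsets, statistics are centred with subset means (each statistic is
  computed "within" its subset); empty or single-animal subsets yield `NA`
  rather than an error in replicate tables.
* Unknown parents are coded `"0"` in files; unknown-parent groups are not
  fitted (they are a known source of bias, and out of scope).

## Design choices that were genuinely open

* **Which variance components drive the LR statistics** when partial-data
  REML estimates differ from whole-data values: the package defaults to the
  fixed (whole-data/true) components for all LR statistics and reports the
  per-replicate partial-data REML `h²` alongside (`lr_crossval(reml =
  TRUE)`), since the statistics' expectations are derived under a single
  variance structure. Setting `use_reml_components = TRUE` instead solves
  the partial model with its own REML estimates, emulating pipelines that
  re-estimate components per dataset — the setting under which the
  characteristic correlations between the `h²` estimate and the
  reference/validation predictivities emerge.
* **Precorrection** uses the whole-data fixed-effect solutions, matching
  how predictivity is defined; a partial-data precorrection is available by
  fitting the partial model and calling `precorrect()` with it.
* **Validation-set definition** masks *records* and collects the
  individuals affected; with one record per animal (the emulated design)
  this coincides with masking animals, and it generalizes to repeated
  records.
* **The unselected-accuracy conversion** is implemented as the
  reliability-shift form `sqrt(k + (1 − k) acc²)`; it reproduces both the
  worked example (0.67 → 0.82 at k = 0.4) and a direct simulation of
  equilibrium variance reduction (see the test suite).

## Problem sizes

The replicated checks in the test suite and the acceptance script use an
unselected two-generation population of 775 animals (500 phenotyped), 500
replicates for expectation checks (fixed mask, factorization reuse), 600
replicates for the single-family bias check, and 200 REML-replicated
cross-validations of a 233-animal population for the correlation-pattern
check; Monte-Carlo oracles for closed forms use 4·10⁵–10⁶ draws. These
sizes give Monte-Carlo standard errors a comfortable order of magnitude
below the effects being tested.

## Known limitations

* Standard errors of the LR statistics are not provided; the replicate
  spread in `lr_crossval()` is the intended empirical substitute.
* `E(b_wp)` is exactly 1 only in the large, diverse focal-set limit; for
  small related validation sets the true expectation is below 1 (the
  package demonstrates this, it does not correct for it). Use large mixed
  cohorts for validation.
* Single trait, one genetic effect, homogeneous residual variance.
* Dense solvers only; no sparse inverses or iterative solvers.

## A minimal session

```{r example, eval = FALSE}
library(lrcv)
cfg <- sim_config(n_sires = 10, n_dams = 60, n_groups = 5)
pop <- simulate_population(cfg, seed = 1)
K <- nrm(pop$pedigree)
vc <- variance_components(0.4, 0.6)

cv <- lr_crossval(pop$phenotypes, K, vc, fixed = ~cg,
                  fraction = 0.5, n_rep = 100, seed = 1)
summarize_replicates(cv)$summary
autoplot(cv)

ex <- lr_sim_experiment(cfg, n_rep = 300, fraction = 0.5, seed = 1)
glance(ex)          # replicate means vs PEV/PEC expectations
autoplot(ex)
```
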