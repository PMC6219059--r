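# lrcv — LR validation of genetic evaluations

Breeding programs rank animals on estimated breeding values (EBV) from BLUP
mixed models, but whether a given evaluation is biased, over-dispersed, or
accurate for a cohort of candidates is an empirical question — and true
breeding values are never observed. `lrcv` implements the *LR* (linear
regression) validation method: run the same evaluation twice, on **partial**
(truncated or masked) and on **whole** data, and read bias, dispersion and
population accuracy off the comparison of the two EBV vectors. The package
is aimed at quantitative geneticists and breeders validating pedigree-based
(PBLUP) or genomic (GBLUP) evaluations.

## The statistics

For focal individuals with partial-data EBV `û_p` and whole-data EBV `û_w`
(empirical moments across individuals):

| statistic | definition | expectation under a correct model |
|---|---|---|
| `mu_wp`      | `mean(û_p) − mean(û_w)`   | 0 (unbiasedness) |
| `b_wp`       | `cov(û_w,û_p)/var(û_p)`   | 1; `θ_w/θ_p` under uniform over/under-dispersion |
| `b_pw`       | `cov(û_p,û_w)/var(û_w)`   | `acc_p²/acc_w²` |
| `rho_wp`     | `cor(û_p,û_w)`            | `acc_p/acc_w` |
| `rho2_cov`   | `cov(û_p,û_w)/((1+F̄−2f̄)σ²_u,∞)` | `acc_p²` |

where `acc` is the population accuracy (correlation of true and estimated
breeding values across the cohort),

```
acc² = 1 − (mean PEV − mean PEC) / ((1 + F̄ − 2f̄) σ²_u,∞)
```

computed from the prediction-error (co)variances of the mixed-model
coefficient-matrix inverse, `1 + F̄ − 2f̄` the relationship-adjusted
genetic-variance factor of the cohort, and `σ²_u,∞ = (1−k)σ²_u` the
equilibrium genetic variance under selection. The package provides both
sides: the empirical statistics from EBV vectors, and their theoretical
expectations from PEV/PEC — so every estimator can be checked against the
theory on simulated data, and the theory used to interpret real data.

Companion tools cover the predictivity route (`cor(y*, û_p)` with
precorrected phenotypes, its `acc/h∞` conversion, and the
`(m−1)/(n−(m−1))` inflation from imperfect precorrection), the conversion
of selected-scale accuracies to the unselected scale, and the closed-form
counterexample of a later evaluation that discards earlier data.

## Worked example

Simulate an unselected two-generation population, replicate the
partial/whole evaluation with the design held fixed, and compare replicate
means of the statistics with their PEV/PEC expectations:

```r
library(lrcv)

cfg <- sim_config(n_sires = 10, n_dams = 60, n_groups = 5)  # h2 = 0.4
ex  <- lr_sim_experiment(cfg, n_rep = 300, fraction = 0.5, seed = 1)
glance(ex)
#>    statistic     mean   mc_se expected
#>        mu_wp -0.00058 0.00222    0.000
#>         b_wp  1.03301 0.02359    1.000
#>         b_pw  0.24373 0.00639    0.256
#>       rho_wp  0.48921 0.00994    0.506
#>     rho2_cov  0.11351 0.00398    0.115
#> predictivity  0.21507 0.00856    0.215
#>    acc_p_emp  0.32286 0.00960    0.340
#>    acc_w_emp  0.66263 0.00528    0.671
```

Masking a random half of the records costs this design about half its
squared accuracy (`rho2_cov ≈ 0.11` vs `acc_w² ≈ 0.45`); the regression of
whole on partial EBV sits at 1 (no over-dispersion) and the partial/whole
correlation `rho_wp ≈ 0.49` estimates `acc_p/acc_w`. Every replicate mean
is within Monte-Carlo error of its expectation.

The same loop on one dataset with re-masking per replicate (the
cross-validation a practitioner runs on real data):

```r
pop <- simulate_population(cfg, seed = 1)
K   <- nrm(pop$pedigree)
vc  <- variance_components(0.4, 0.6)
cv  <- lr_crossval(pop$phenotypes, K, vc, fixed = ~cg,
                   fraction = 0.5, n_rep = 50, seed = 1)
summarize_replicates(cv)$summary
#>   statistic  mean     sd   min   max
#>      b_wp   0.916 0.0923 0.701 1.111
#>      b_wp_r 0.957 0.0468 0.846 1.041
#>      b_wp_v 0.776 0.2906 0.178 1.511
#>      b_pw   0.558 0.1025 0.291 0.754
#>      ...
autoplot(cv)                  # replicate means ± SD
plot_lr_correlations(cv)      # correlation heatmap among statistics
```

Scalar helpers reproduce the classic worked example directly: with an
observed predictivity `r = 0.30`, base heritability `0.30` and equilibrium
heritability `0.20`, `acc_from_predictivity()` gives 0.55 (biased, base
`h`) and 0.67 (correct, `h∞`), and `selected_to_unselected_acc(0.67, 0.4)`
gives 0.82 on the unselected scale.

See `vignette("lr-method")` for the model, assumptions, parameter choices
and limitations, and `inst/cli/lrcv.R` for a command-line wrapper
(`simulate`, `evaluate`, `lr`, `crossval` subcommands).

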