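# fshthreshold

Threshold (two-piece-wise linear) regression of oocyte yield on Day-7 serum
FSH, estimated by generalized estimating equations — with the full analysis
pipeline that surrounds such a model in reproductive-medicine cohort studies.

## The problem

In controlled ovarian stimulation under a GnRH antagonist protocol, the
serum FSH level measured on stimulation Day 7 (mIU/mL) reflects both the
exogenous dose and the ovarian response. Its relationship with the number of
oocytes retrieved is not monotone: yield rises with FSH up to an inflection
point and falls slowly beyond it. `fshthreshold` estimates that inflection
point and the slopes on either side of it from cycle-level cohort data in
which patients may contribute repeated, correlated cycles.

## The model

For cycle-level outcome $Y$ (oocytes retrieved), exposure $\mathrm{FSH}$ and
covariates $Z_i$, the mean is continuity-constrained and two-piece-wise
linear in the exposure:

$$
E[Y] = \beta_0 + \beta_1(\mathrm{FSH}-K)\,\mathbf{1}[\mathrm{FSH}<K]
              + \beta_2(\mathrm{FSH}-K)\,\mathbf{1}[\mathrm{FSH}\ge K]
              + \textstyle\sum_i \gamma_i Z_i .
$$

Both segments equal $\beta_0 + \sum_i\gamma_i Z_i$ at $\mathrm{FSH}=K$, so
the fitted mean is continuous at the breakpoint $K$. Coefficients are
estimated by Gaussian-family GEE with an exchangeable working correlation
across a patient's cycles and robust (sandwich) standard errors. The
breakpoint is found by a recursive quasi-likelihood search: a global screen
of the 5th–95th exposure percentiles at 5-point steps, then a ±4-point
refinement at 1-point steps around the stage-1 winner. Inference on $K$ uses
a cluster (patient-level) nonparametric bootstrap percentile CI; the
threshold effect itself is tested by a quasi-likelihood ratio comparison of
the segmented model against the nested single-slope linear model, and
validated by patient-grouped 10-fold cross-validation.

Around the core model the package provides the standard cohort machinery:
schema-validated CSV I/O, eligibility exclusions with a flow-chart report,
exposure tertiles with descriptive group tests (ANOVA / Kruskal–Wallis /
chi-square), univariate and multivariable-adjusted linear screening with a
tertile trend test, a penalized-spline (GAM) nonlinearity screen,
subgroup/interaction analyses, and the two common sensitivity designs
(first-cycle-only; gonadotropin-type subset). A synthetic-cohort simulator
with known piece-wise ground truth, realistic covariate marginals and a
configurable within-patient ICC makes every stage testable end to end.

## Worked example

```r
library(fshthreshold)

cfg    <- default_study_config(n_patients = 2000, seed = 42)
cohort <- assign_tertiles(simulate_cohort(cfg))
covs   <- default_covariates()

res     <- recursive_threshold_search(cohort, covs)
res$ci  <- bootstrap_breakpoint_ci(cohort, covs, B = 200, seed = 43)
res$qlr <- qlr_threshold_test(cohort, res$fit, covs)
res
#> Recursive threshold search: K_opt = 9.363 (19 + 9 candidates)
#>   bootstrap 95% CI: [8.865, 11.84]
#>   QLR threshold test p = 9.84e-20
#> Two-piece-wise GEE fit (breakpoint K = 9.363)
#>   slope below K :   0.9621
#>   slope >= K    :  -0.0604
#>   n = 2502 cycles, 2000 patients; working alpha = 0.291, phi = 15.704
#>   quasi-likelihood = -1241.500

fit_smooth(cohort, covariates = covs)
#> Adjusted smooth fit: edf = 5.99, nonlinearity p = 4.17e-17 (n = 2502)

cross_validate_threshold(cohort, covs, folds = 10, seed = 44)
#> 10-fold grouped CV: pooled MSE segmented = 15.864, linear = 16.384
```

The simulator's generating truth here is a breakpoint at 9.13 mIU/mL with
slopes 1.18 below and −0.07 at/above it. At 2,000 patients the search lands
at 9.36 with the bootstrap CI comfortably covering the truth; the segment
slopes carry the expected signs and magnitudes; the smooth screen flags the
nonlinearity; and the segmented model out-predicts the linear one on
held-out patients. `run_full_analysis(run_config(...))` chains all stages —
exclusions, descriptives, screening, GAM, threshold, subgroups,
sensitivity — into a reproducible report bundle written as CSV/JSON.

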