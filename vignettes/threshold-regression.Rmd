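---
title: "Threshold regression of Day-7 FSH on oocyte yield: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold regression of Day-7 FSH on oocyte yield: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fshthreshold)
```

## The scientific question

During controlled ovarian stimulation for IVF under a GnRH antagonist
protocol, serum FSH measured on stimulation Day 7 integrates the exogenous
gonadotropin dose with the ovary's uptake and clearance of it. Clinically
one wants to know whether there is an FSH level beyond which further
elevation no longer improves — or begins to harm — the oocyte yield at
retrieval. Statistically that is a *threshold effect*: a dose–response curve
that is piece-wise linear with a single breakpoint, continuous at the
breakpoint, estimated from cycle-level data in which the same patient may
contribute more than one (correlated) cycle.

## Model and estimation

### Mean structure

For outcome $Y$ (oocytes retrieved), exposure $F$ (Day-7 FSH, mIU/mL),
breakpoint $K$ and covariates $Z_i$:

* when $F < K$:   $E[Y] = \beta_0 + \beta_1 (F - K) + \sum_i \gamma_i Z_i$
* when $F \ge K$: $E[Y] = \beta_0 + \beta_2 (F - K) + \sum_i \gamma_i Z_i$

The shared intercept $\beta_0$ at $F = K$ is the continuity constraint. The
implementation encodes it with the hinge basis
$h_1 = (F-K)\,\mathbf 1[F<K]$, $h_2 = (F-K)\,\mathbf 1[F\ge K]$
(`hinge_design()`): both columns vanish at $F=K$ and sum to $F-K$, so any
linear fit on them is automatically continuous. An algebraically equivalent
parameterization — $F$ plus a single hinge $\max(F-K, 0)$ — returns
$\beta_1$ and the slope change $\beta_2 - \beta_1$; the test suite checks
the two agree to $10^{-8}$.

The outcome is a count, but it is large enough (population mean near 9) that
the analysis models it with an identity-link Gaussian-family marginal model,
which keeps the slopes interpretable as oocytes per mIU/mL.

### GEE with exchangeable working correlation

Repeated cycles of one patient are correlated. Coefficients solve the
Gaussian-family GEE with working correlation
$R = (1-\alpha)I + \alpha J$ within each patient. The algebra of the
exchangeable inverse,
$R^{-1} = \tfrac{1}{1-\alpha}\big(I - \tfrac{\alpha}{1+(m-1)\alpha} J\big)$,
reduces every crossproduct to per-cluster column sums, so each iteration is
$O(np^2)$ without any per-cluster inversion; the solver is compiled
(RcppArmadillo). $\alpha$ and the dispersion $\varphi$ are moment estimates
from standardized residuals, alternated with the coefficient solve to a
$10^{-8}$ tolerance (cap 100 iterations). Standard errors are always the
robust sandwich $A^{-1} M A^{-1}$, valid under working-correlation
misspecification. Two exact identities anchor the implementation: with
singleton clusters and independence correlation the GEE equals ordinary
least squares and the sandwich equals the HC0 heteroskedasticity-robust
covariance, both verified to $10^{-8}$ against `lm()` and
`sandwich::vcovHC()`.

### Quasi-likelihood and the breakpoint search

The profile objective over candidate breakpoints is the Gaussian log
quasi-likelihood $QL = -\mathrm{RSS}/(2\hat\varphi)$, with $\hat\varphi$
**held fixed at the linear-model estimate for all candidates of one
search**, so that candidate comparison is monotone in RSS and not distorted
by candidate-specific dispersion estimates. The working $\alpha$ is likewise
held at its linear-model value while profiling, which turns each candidate
into a single weighted least-squares solve; the full GEE (with $\alpha$
re-estimated) is refit at the selected optimum. These are package design
choices — threshold-analysis tooling common in this literature does not
document its quasi-likelihood — and they are deliberately simple: any fixed
positive $\varphi$ induces the same ranking of candidates.

The recursive search has two stages:

1. **Global screen** — candidates at the 5th–95th exposure percentiles in
   5-point steps (type-7 sample quantiles).
2. **Refinement** — a window of ±4 percentile *points* around the stage-1
   winner, searched at 1-point steps, clamped to [5, 95]. The step size of
   the refinement is one reading of a "±4 percentile" window; it is
   recorded as a design choice.

`K_opt` maximizes $QL$ over **every** candidate evaluated in either stage;
ties break deterministically toward the smallest $K$. Candidates leaving
fewer than `min_segment` observations on one side (default
$\max(20,\,2p)$ where $p$ is the parameter count) are skipped and logged.
The suite verifies the search against an exhaustive re-evaluation of the
same candidate set by an independent least-squares oracle, and that a
noiseless cohort whose true breakpoint sits exactly on the refinement grid
is recovered without error.

### Bootstrap CI for the breakpoint

The 95% CI for $K$ is the 2.5th/97.5th percentile of breakpoint estimates
across nonparametric bootstrap replicates. Resampling is of **patients
(clusters), with replacement, to the original cluster count** — resampling
cycles would break the within-patient correlation the GEE is there to
handle. The reporting default is 1000 replicates; simulation experiments in
the test suite use 200 to keep runtimes reasonable, and at study scale the
resulting CI covers the generating breakpoint in 88–99% of replications.

### Threshold test

The segmented and the nested linear model are compared on identical
complete-case rows by $2(QL_{\text{seg}} - QL_{\text{lin}})$, referred to
$\chi^2_1$ for the one added slope parameter. Because $K$ is itself chosen
to maximize the objective, this reference is **anti-conservative**; the
returned p-value carries that note in its attributes. Under a fully
adjusted no-kink simulation at 2,000 patients the empirical size at the
0.05 level is about 0.16 — inflated, as expected, and bounded well below
the documented 0.25 ceiling. Davies-type corrections for an estimated
changepoint are out of scope and noted as such. Power is not the concern:
at the default kink magnitude (1.18 vs −0.07) the test rejects at
$p<0.001$ in essentially every study-scale simulation.

### Cross-validation

Ten folds partition **patients**, never cycles, so no patient straddles the
train/test boundary. Per fold the entire search plus both fits run on the
training clusters and mean squared prediction error is evaluated on the
held-out cycles. Under the default kink the segmented model out-predicts
the linear one; under a linear truth the two differ only by noise.

## Screening machinery

* **Tertiles** use type-7 (linearly interpolated) sample quantiles at 1/3
  and 2/3, with records exactly at a cut assigned to the **lower** group
  (closed lower intervals). Published tertile boundaries in clinical
  reports are frequently ambiguous about which side owns a cut; one
  convention is fixed here and documented. Labels are invariant to record order and to strictly monotone
  transformation of the exposure.
* **Group tests**: one-way ANOVA for continuous variables, switched to
  Kruskal–Wallis when |skewness| > 1 (the dichotomy "normal vs skewed" needs
  an operational rule; sample skewness is ours), chi-square without
  continuity correction for categorical variables.
* **Linear screening**: per-exposure simple regressions, and a
  multivariable-adjusted model, with t-based 95% CIs (residual df); the
  trend test enters the tertile as an ordinal 1/2/3 score in the adjusted
  model. Categorical exposures expand against the most frequent level by
  default (overridable), mirroring the usual "tubal disease = reference"
  presentation.
* **Missing data**: every model is complete-case on exactly the variables it
  uses, with the dropped-row count recorded (`n_used`). This mirrors the
  unexplained cohort-size reductions between descriptive and adjusted
  tables in studies of this design, where complete-case deletion is the
  parsimonious explanation.

## The GAM nonlinearity screen

A cubic regression spline (`mgcv`, basis dimension 10, smoothing parameter
by GCV; REML available) with linear covariate adjustment estimates the
partial dose–response curve, evaluated with a pointwise 95% band on 200
points spanning the 1st–99th exposure percentiles (the tails beyond are
unstable). The nonlinearity p-value is an F-type comparison of the spline
against the nested linear fit with the smooth's effective df as numerator
df — documented as approximate, since penalized-fit df are themselves
estimates; its role is gating (a screen before threshold modeling), not
confirmatory inference. With the penalty driven to infinity the smooth
collapses onto the straight line, which the suite checks to $10^{-6}$.

## Subgroups and sensitivity designs

Stratified exposure effects remove the stratifying variable from its own
stratum's adjustment list. The interaction p-value comes from a pooled
adjusted model with exposure-by-stratum product terms tested jointly
(F test against the model without them) — the standard product-term
Wald/F approach, since this literature rarely names its interaction test.
Default cuts: age 35 years; AMH 1.2 and 5 ng/mL; BMI 18.5 kg/m²; the POR
and PCOS flags. The two sensitivity designs rerun the entire threshold
pipeline (a) on one cycle per patient — clustering becomes trivial — and
(b) restricted to a gonadotropin type. Gonadotropin type is deliberately a
*configurable filter* rather than a fixed exclusion: clinical analyses of
this design variously exclude urinary-gonadotropin cycles or analyze them
as their own sensitivity set, so the package takes no position.

## The synthetic cohort generator

The generator exists so that every stage of the pipeline can be validated
against known truth; its defaults are the study conditions used throughout
the tests.

* **Exposure**: equal-weight three-component log-normal mixture with
  component means/SDs 8.1/1.5, 13.0/1.4 and 19.2/3.3 mIU/mL — tertile moments of
  Day-7 FSH reported for GnRH antagonist cohorts. The parametric form is
  our choice; only group moments are reported in this literature.
* **Covariates**: marginals matched to reported cohort moments (age
  32.74 ± 4.81 y, BMI 22.34 ± 3.21 kg/m², AMH 3.51 ± 3.81 ng/mL, AFC
  7.99 ± 5.04, Day-1 FSH 6.10 ± 1.98 mIU/mL, doses, 12.3% PCOS, 19.9% POR),
  tied to the exposure through a one-factor Gaussian copula whose loadings
  reproduce the qualitative tertile trends (ovarian-reserve markers fall
  with Day-7 FSH; age, Day-1 FSH and doses rise). Patient-constant
  covariates are held fixed across a patient's cycles.
* **Outcome**: `true_mean()` plus a patient random intercept (variance
  `icc * sigma^2`) and cycle noise (variance `(1-icc) * sigma^2`), so the
  within-patient residual correlation equals `icc` exactly. Defaults
  `sigma = 4`, `icc = 0.3` are explicit placeholders — residual SDs and
  ICCs are rarely reported for repeated IVF cycles. Optional rounding/clipping produces
  integer non-negative counts; it is **off** in oracle tests (exact
  recovery needs the Gaussian model class the fit assumes) and **on** in
  realism tests.
* **Calibration**: the default breakpoint/slopes are 9.13, 1.18 and −0.07;
  `beta0 = 10.3` and the covariate effect sizes (signs and rough magnitudes
  typical of univariate screens in such cohorts) were chosen once, from the
  configured mean structure, so the marginal outcome lands near the
  reported 9.40 ± 6.10; simulated cohorts give ≈ 9.4 ± 6.1.

What the generator does **not** emulate: the true joint covariate
distribution (only marginals plus one-factor dependence), informative dose
titration (confounding by indication), assay error in FSH, and
count-specific outcome features (zero inflation from cancelled retrievals,
overdispersion). Passing tests therefore demonstrate that the *machinery*
is correct under the model class it assumes, not that the model class is
right for any particular clinic's data.

## Problem sizes used in validation

The acceptance-level simulations run at the study's scale — 3,000 patients
with 25% second cycles (≈ 3,750 cycles) — with 100 replications for
parameter recovery and bootstrap coverage, 400 null replications at 2,000
patients for test calibration, and 200 bootstrap replicates inside each
coverage replication. Unit tests use smaller cohorts (hundreds of
patients). `scripts/acceptance.R` reports one full pipeline run at
3,000 patients with the full 1000-replicate bootstrap.

## Known limitations

* One breakpoint only; no multi-changepoint extension.
* Gaussian quasi-likelihood only; count-family GEEs are out of scope.
* The QLR reference distribution ignores the estimated breakpoint
  (anti-conservative; bounded, documented, uncorrected).
* Percentile-grid resolution limits breakpoint precision to the local
  1-percentile spacing of the exposure distribution.
* The bootstrap treats the candidate grid as part of the estimator: each
  replicate re-derives its own percentile grid, so grid discreteness
  contributes to CI width.
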