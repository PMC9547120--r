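---
title: "Latent change score models with lcsmr: models, estimation, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent change score models with lcsmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcsmr)
```

## The model family

A latent change score model (LCSM) separates an observed repeated measure
into a latent true score and an occasion-specific unique score,
`x[t] = lx[t] + u[t]`, and models the latent difference between adjacent
occasions explicitly: a change score `dx[t]` is defined structurally by
fixing `lx[t] = lx[t-1] + dx[t]` (both paths at 1, no residual variance on
`dx`). What makes the family flexible is the equation driving the change
scores:

* **Constant change factor** (`alpha_constant`). A latent factor `g2` with
  fixed unit loadings on every change score, an estimated mean `alpha_g2`,
  variance `sigma2_g2`, and covariance `sigma_g2lx1` with the initial true
  score. Its mean acts like a linear slope; its variance captures individual
  differences in that slope. The per-individual slope score is a latent
  variable, never a free parameter.
* **Proportional change** (`beta`). Each change score is regressed on the
  previous occasion's true score with a single coefficient `beta_x`
  (occasions 2..T). Negative values produce exponential-type decay toward an
  equilibrium.
* **Autoregression of change scores** (`phi`). Each change score is
  regressed on the previous change score, `phi_x`, from occasion 3 onward
  (two successive change scores are needed, hence T >= 3).
* **Piecewise change** (`alpha_piecewise` with change point `k`): `g2` loads
  on change scores 2..k, a second factor `g3` on k+1..T, with the full
  covariance block (`alpha_g3`, `sigma2_g3`, `sigma_g3lx1`, `sigma_g2g3`).
  The two loading sets partition the change scores; no change score loads on
  both factors.
* **Linear change factor** (`alpha_linear`): one factor with fixed loadings
  `t - 1` on `dx[t]` (1, 2, ..., T-1), so the change *increments* grow
  linearly and observed trajectories are quadratic. The loading scheme is a
  package choice: a factor whose influence on the change score is
  proportional to elapsed time is the natural "linear" analogue of the
  constant factor, and it nests the constant factor's interpretation at
  T = 2.

A bivariate LCSM joins two such constructs. Beyond the always-free
covariances (same-occasion unique-score covariance `sigma_su`, initial
true-score covariance `sigma_ly1lx1`, and the covariances among whichever
change factors exist), eight coupling regressions are available:
`delta_{con,lag}_{xy,yx}` regress a change score on the *true* score of the
other construct (same occasion / previous occasion), and
`xi_{con,lag}_{xy,yx}` regress it on the other construct's *change* score.
Concurrent couplings run from occasion 2, lagged couplings from occasion 3.
All coupling coefficients are constrained equal over time unless
`coupling_piecewise` splits them at a change point into `_p1` (up to and
including the change point) and `_p2` (after) phases. When both a piecewise
change factor and piecewise coupling are requested, each carries its own
change point; the two are never implicitly shared.

Equality of the unique variance over time (one `sigma2_ux` per construct) is
built in: it identifies the true-score/unique-score decomposition without
requiring multiple indicators per occasion, and it is what keeps the free
parameter count independent of the number of occasions. Unique scores are
mutually uncorrelated except for the same-occasion cross-construct
`sigma_su`.

## From options to matrices and syntax

`compile_lcsm()` translates a specification into RAM-style matrices: a
directed-path matrix `A` (unit loadings, true-score autoregressions,
change-score definitions, change-factor loadings, and the labelled
regressions), a symmetric matrix `S` (free variances and covariances), and a
mean vector `m` (`gamma_lx1` on the initial true score, `alpha_g2`/`alpha_g3`
on the change factors, observed intercepts fixed at 0). Cells sharing a
label are constrained equal; the label-to-cells map is exposed as
`model$label_map`. Implied moments follow the reduced form

    mu = F (I - A)^{-1} m,    Sigma = F (I - A)^{-1} S (I - A)^{-T} F',

with `F` the observed-variable filter. `render_syntax()` prints the same
model as sectioned, commented lavaan-dialect text — useful for reporting, for
manual adaptation (e.g. freeing a coefficient at one occasion), or for
cross-checking against other SEM software; `syntax_labels()` parses the
labels back out, and the set always equals the parameter table.

## Estimation

**FIML.** The log-likelihood sums, over individuals, the multivariate-normal
log-density of each individual's observed subset of variables; rows with no
observed values contribute nothing and are excluded from the effective `n`.
Internally the sample is grouped by missingness pattern and reduced to
per-pattern sufficient statistics (count, mean, scatter), so one likelihood
evaluation costs `O(#patterns * p^3)` regardless of sample size; the result
is numerically identical to case-by-case evaluation (tested to 1e-10).

**Optimisation.** Parameters stay on their natural scale; any parameter
vector whose implied covariance is not positive definite on some observed
subset (or is numerically untrustworthy — non-finite, or with a Cholesky
condition beyond 1e10) evaluates to a large finite penalty. Start values are
data-driven: the first occasion's mean for `gamma_lx1`, half its variance
for `sigma2_lx1` and `sigma2_ux`, the mean successive difference for
change-factor means, half the variance of successive differences for
change-factor variances, and zero for regressions and covariances. A short
Nelder-Mead pre-stage precedes BFGS because a quasi-Newton line search from a
zero-regression start can overshoot into degenerate territory when the start
misfit is large; BFGS (with parameter scaling) then iterates to machine-level
relative tolerance (1e-9), and damped Newton steps on the numerically
differentiated Hessian finish until the gradient max-norm falls below
1e-6 relative to max(1, |loglik|). The convergence flag reports exactly this
criterion; non-convergence returns a diagnosable object, not an error.
Standard errors come from the inverse of the observed information (the final
Hessian of the negative log-likelihood); Wald z tests and two-sided p-values
follow.

**Fit statistics.** The saturated reference (unstructured mean and
covariance) has no closed form under missingness, so it is estimated by EM,
with the closed-form solution used when the data are complete. The
independence baseline (free means and variances, zero covariances)
factorises per variable and is closed-form even under missingness. Then

* `chisq = 2 (ll_sat - ll_model)` with `df = p(p+3)/2 - npar`,
* `aic = -2 ll + 2 npar`, `bic = -2 ll + npar log(n)` with `n` the number of
  rows with at least one observed value (so `bic - aic = npar (log n - 2)`),
* `cfi = 1 - max(chisq - df, 0) / max(chisq_b - df_b, chisq - df, 0)`,
* `rmsea = sqrt(max(chisq - df, 0) / (df n))`,
* `srmr` is the classic covariance-only version: residuals between the
  saturated and model-implied covariances standardised by saturated
  variances, root-mean-squared over the unique elements. Mean residuals are
  not included; with the model's saturated-at-the-first-occasion mean
  structure they are typically negligible, and the covariance-only form is
  the most widely reported definition.

## The simulator

`sim_uni_lcsm()`/`sim_bi_lcsm()` draw the exogenous latents (initial true
scores, change factors, occasion-specific uniques) from the multivariate
normal defined by the supplied means and (co)variances, then run the
structural recursion to build change scores, true scores and observed
scores. This is distributionally identical to sampling the implied normal
directly, but also yields the latent scores (`return_latent = TRUE`) for
inspecting how interdependent parameters shape trajectories. Parameters
omitted from the generating list default to zero with a message, mirroring
the partial-list idiom. Missingness is cellwise MCAR per construct
(`na_x_pct`, `na_y_pct`), applied after generation, never to the `id`
column; MAR/MNAR mechanisms and non-normal residuals are out of scope. Given
a seed the output is reproducible exactly — within this implementation; no
cross-software bit-reproduction of a particular seed is possible.

What the simulator deliberately does *not* emulate about real longitudinal
data: non-normal and heteroscedastic residuals, MAR/MNAR dropout,
measurement non-invariance over time, and floor/ceiling effects. Tests that
pass on simulated data therefore validate the estimator against its own
assumptions, not robustness to their violation.

## Verification design and problem sizes

The test suite checks the engine against independent oracles: closed-form
mean trajectories (a constant-only change factor gives exactly linear means;
proportional-only change gives geometric means), covariance algebra
propagated by hand at T = 3, case-wise brute-force likelihood on small
matrices with random missingness, and sample moments of large simulations
(10^6 draws, componentwise within four Monte-Carlo standard errors).
Recovery is validated by round trips — simulate at n = 5000 without
missingness, refit, compare medians over 20 replicates to the generating
values (within 5% for means and regressions, 10% for variances and
covariances) — for each univariate option and each of the eight coupling
options. Two design points matter there:

* **Identifiability of the round-trip configuration.** With a constant-only
  change factor every change score equals the factor (`dx[t] = g2`), so a
  change-to-change coupling is perfectly confounded with the change-factor
  covariances, and `phi` alone leaves all change scores deterministically
  zero. Coupling options are therefore tested on top of the full change
  equation (constant + proportional + autoregressive) in both constructs,
  and `phi` on top of a constant change factor.
* **Measurable effect sizes.** A 5% relative band around a truth of 0.3 is
  0.015, which is the same order as the Monte-Carlo noise of a median of 20
  estimates when the parameter's standard error is ~0.055 (as for a
  change-factor mean in the full model at n = 5000). Generating magnitudes
  for the recovery checks are chosen so each band is at least ~3 median
  standard errors (e.g. change-factor means of 1, autoregressions of 0.2,
  cross-construct covariances of 0.15); otherwise the check would measure
  noise, not recovery.

The worked example used throughout (T = 5, n = 500, 15%/10% missingness,
coupling `xi_lag_yx = 0.5`) runs in about a second for the univariate fit
and under a minute for the 22-parameter bivariate fit on one CPU; the full
round-trip battery takes a few minutes.

## Numerical choices and edge cases

* Variances are estimated on the natural scale (no log transform); the
  positive-definiteness guard keeps the optimizer in the admissible region
  and valid solutions are interior.
* Timepoints are 1-based; change scores exist for t = 2..T; `phi` and all
  lagged couplings start at t = 3 and require T >= 3.
* Ambiguous specifications (two change-factor types at once, a piecewise
  change point outside 2..T-1, lagged couplings at T = 2) are rejected with
  errors naming the conflicting options.
* `(I - A)` singular — possible only with self-reinforcing concurrent
  coupling loops at unit gain — raises a structural-cycle error rather than
  returning nonsense.
* Fit statistics depend on the EM saturated model; if that estimation fails,
  chi-square-based indices are reported as missing while AIC/BIC (which need
  only the candidate's likelihood) are still returned.
* The p-value formatter mirrors the conventional compact style: values below
  .001 print as `< .001`, otherwise three decimals without the leading zero.

## Known limitations

Single-indicator constructs with time-invariant unique variance (by design);
no robust/weighted estimators, bootstrap standard errors, ordinal
indicators, multi-group or mixture extensions; coupling coefficients beyond
the piecewise split cannot vary freely per occasion (the rendered syntax is
the escape hatch); the path-diagram layout optimises topology, not the
aesthetics of a publication figure.
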