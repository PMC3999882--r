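---
title: "Comparing proportion-difference estimators on (0,1) responses: models, design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing proportion-difference estimators on (0,1) responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(propdiffsim)
```

## The question

Response variables bounded on the open unit interval — proportions,
percentages, rates — are routinely analysed with ordinary linear
regression, even though the Gaussian error model is at best an
approximation there. This package implements a controlled comparison of
four estimators of the two-sample mean difference
$\Delta = E(Y \mid x{=}1) - E(Y \mid x{=}0)$ on such data: linear
regression, beta regression with a single dispersion parameter, beta
regression with a group-specific (log-linked) dispersion sub-model, and
fractional logit regression. Everything needed to rerun the comparison —
data generators, fitters, inference, replication harness — is first-class,
tested code.

## Models

**Linear.** $Y_i = \beta_0 + \beta_1 x_i + \epsilon_i$ with homoskedastic
errors; $\hat\Delta = \hat\beta_1$ is the difference of group sample means
and carries the usual OLS standard error.

**Beta regression.** The beta density is indexed by its mean $\mu$ and a
precision-like dispersion $\phi$ (shapes $p = \mu\phi$, $q = (1-\mu)\phi$),
so that $E(Y) = \mu$ and $\mathrm{Var}(Y) = \mu(1-\mu)/(1+\phi)$. The mean
follows a logit-linear model $\mathrm{logit}(\mu_i) = \beta_0 + \beta_1
x_i$. The constant-dispersion variant estimates a single $\phi$, kept on
the identity scale with a positivity bound. The variable-dispersion
(double-index) variant adds $\log(\phi_i) = \gamma_0 + \gamma_1 x_i$, so
each group may have its own precision. Both are fitted by maximum
likelihood; the coefficient covariance is the inverse observed information.

**Fractional logit.** A quasi-parametric alternative that assumes only a
logistic conditional mean, $E(Y\mid x) = \mathrm{expit}(\beta_0 + \beta_1
x)$, estimated by maximizing the Bernoulli quasi-likelihood
$\sum_i y_i \log \mu_i + (1-y_i)\log(1-\mu_i)$. Because the nominal
Bernoulli variance is generally wrong for fractional data, the covariance
is the robust sandwich $A^{-1} M A^{-1}$, with $A$ the (here exact)
expected Hessian $X^\top \mathrm{diag}(\mu(1-\mu)) X$ and $M$ the sum of
outer products of per-observation scores.

**Effect and test.** For the three logit-mean models
$\hat\Delta = \mathrm{expit}(\hat\beta_0 + \hat\beta_1) -
\mathrm{expit}(\hat\beta_0)$, with variance from the first-order delta
method: the gradient of $\Delta$ in the full coefficient vector is
$(h'(\eta_1) - h'(\eta_0),\, h'(\eta_1),\, 0, \ldots)$ with $h'(\eta) =
\mathrm{expit}(\eta)(1 - \mathrm{expit}(\eta))$; dispersion coordinates get
zero gradient but their covariance with the mean coefficients is retained.
All models reject $\Delta = 0$ when $|\hat\Delta/\widehat{se}| > 1.96$, the
fixed 5% critical value, at every sample size. This is deliberately naive
in small samples — the small-sample behaviour of exactly this rule is part
of what the simulation measures.

## What the generators emulate

`beta_scenario()` draws independent beta responses in each group under the
mean–dispersion parameterization; `multinomial_scenario()` draws discrete
responses on the ten support points $\{0.05, 0.15, \ldots, 0.95\}$ with
group-specific probability vectors. The shipped registries fix the *stated
world* of the experiment:

* **Registry 1 (beta, 24 rows).** Null rows pair means
  $\mu \in \{0.5, 0.25, 0.05\}$ with dispersions $\phi_0 \in \{5, 100\}$
  and either $\phi_1 = \phi_0$ or $\phi_1 = 2\phi_0$; power rows shift the
  group-1 mean by $+0.025$. This sweeps symmetric, skewed and
  near-boundary shapes, at low and high precision, with and without a
  dispersion misspecification.
* **Registry 2 (multinomial, 4 rows).** A symmetric vector (mean 0.5) and
  a right-skewed vector (mean 0.215), each used as a null (same vector in
  both groups) and as a power scenario in which the group-1 vector is
  shifted one support point upward (mean shift $+0.10$). Here *every*
  continuous model is misspecified, which probes robustness to discrete
  responses.

Group sizes default to $n_0 = n_1 \in \{25, 100, 250, 750\}$ and the full
design uses 20\,000 replications per cell, enough for roughly 1000
rejections of a true null at the 5% level. Tests and the acceptance report
run the identical machinery at 1000–2000 replications, which widens the
Monte Carlo error of a rejection rate to about 0.005–0.015; the checks
compare against reference values with a $3\times$MCE band computed at the
replication count actually used.

What the generators do **not** emulate: covariates beyond the single group
indicator, within-sample correlation or clustering, unequal group sizes in
the shipped grids, measurement error, or boundary observations at exactly 0
or 1. A green test therefore establishes correctness of the estimators and
harness under independent sampling from these parametric worlds — not
performance on real clustered or zero-inflated data.

## Seeding and reproducibility

Each experiment has one master seed; replication $r$ draws its dataset from
`substream_seed(seed, r)`, a deterministic 31-bit multiplicative mix of the
master seed and the index. Any single replication is therefore reproducible
in isolation, aggregation order is irrelevant, and replication-level
parallelism could not change results. (The mix is not a cryptographic hash;
collisions across the replication counts used here do not occur for a fixed
master seed, which the test suite checks.)

Beta draws can underflow to exactly 0.0 or 1.0 in double precision when a
shape parameter is extreme (second shape below roughly $10^{-12}$). All
likelihoods here require interior responses, so such draws are clamped to
one machine epsilon inside the interval and counted in the `n_clamped`
attribute of the dataset. Across the shipped grids the event never occurs;
the choice only matters for user-supplied extreme scenarios.

## Numerical choices

* **Starting values.** Mean coefficients from least squares on the
  logit-transformed group means; dispersion from the method-of-moments
  $\tilde\phi = \tilde\mu(1-\tilde\mu)/s^2 - 1$ using the pooled
  within-group variance, floored at 0.1 (and logged for the
  variable-dispersion model).
* **Optimization.** Quasi-Newton (BFGS; L-BFGS-B with bound
  $\phi \ge 10^{-4}$ for the constant-dispersion model) on the analytic
  gradient of the log-likelihood. Up to three restarts from
  deterministically jittered starts on failure; a replication whose fit
  still fails is excluded from the aggregates and counted in `n_excluded`
  (exclusion, not imputation, because failures are rare and concentrated in
  the smallest, most extreme cells).
* **Covariance.** Inverse observed information from a finite-difference
  Hessian of the analytic gradient at the optimum, rather than analytic
  expected-information formulas: asymptotically equivalent, and one code
  path serves both beta models including the mean–dispersion cross blocks.
  A fit is only marked converged if this matrix is positive definite.
* **Fractional logit.** Newton iteration on the quasi-score; for the logit
  link the observed and expected Hessians coincide, so the sandwich `A`
  matrix is model-based. The Pearson-scale variant is intentionally not
  implemented.
* **Ties and degeneracies.** Zero residual variance in the linear model
  yields `se = 0` and a `degenerate` flag; a dispersion estimate at its
  lower bound likewise flags the fit. `alpha = 0.05` uses the literal
  critical value 1.96 (not `qnorm(0.975)`) to match the published decision
  rule; other levels use the exact normal quantile.

## Reading the summaries

`run_experiment()` reports, per model: `bias` = mean($\hat\Delta$) − true
$\Delta$; `variance` = the **empirical** variance of $\hat\Delta$ across
replications (the mean delta-method variance is reported separately as
`mean_model_variance`, a calibration diagnostic); `rejection_rate`; and
Monte Carlo errors $sd/\sqrt{R}$, $s^2\sqrt{2/(R-1)}$ and
$\sqrt{r(1-r)/R}$. The empirical-variance reading of the variance column is
the one consistent with the reference tables' own MCE column (e.g. a
variance of 3.34e−3 at $R = 20000$ implies an MCE of 3.34e−5, matching the
printed magnitude).

## Design decisions that were genuinely open

* The reference description of $\Delta$ for logit-mean models is typeset
  with a stray logarithm; it is implemented as the inverse-logit
  difference, the only reading consistent with the delta-method variance
  and the linear-combination derivation.
* The quasi-likelihood for the fractional logit is typeset with
  $\log h(\mu_i)$ in both terms; it is implemented as the standard
  Bernoulli form with $\log(1 - h(\mu_i))$ in the second term.
* Original per-experiment seeds are not published; the substream scheme
  above is this package's own, so individual replication draws differ from
  the original runs while every aggregate is comparable within Monte Carlo
  error.
* Convergence failures are not discussed in the reference results; the
  exclusion-with-count policy here makes them visible instead of silent.

## Known limitations

Single binary covariate only; logit mean link only (no probit/cloglog);
no bias-corrected or bias-reduced beta estimation; no likelihood-ratio or
score tests; no coverage summaries (only bias, variance, rejection rate);
no adaptive replication counts. The harness is serial; determinism is
guaranteed by construction rather than by a parallel backend.
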