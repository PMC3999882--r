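# propdiffsim

Monte Carlo machinery for comparing regression estimators of the **average
proportion difference** in a two-sample design when the response is bounded
on the open unit interval (0,1) — proportions, percentages, fractions,
rates. Intended for biostatisticians and epidemiologists deciding whether to
analyse such outcomes with plain linear regression or with one of the
bounded-response models, and for methodologists who want a reproducible,
seeded simulation harness for that comparison.

## The problem and the estimators

Let the response satisfy `Y ∈ (0,1)` and let `x ∈ {0,1}` indicate the two
groups. The target of inference is the mean difference

    Δ = E(Y | x = 1) − E(Y | x = 0)

Four estimators of Δ are implemented from their (quasi-)likelihoods:

| model | mean model | dispersion | covariance |
|---|---|---|---|
| `linear` | `E(Y) = β₀ + β₁x` | `σ²` (homoskedastic) | OLS |
| `beta_const` | `logit(μ) = β₀ + β₁x` | single `φ`, identity scale | inverse observed information |
| `beta_vardisp` | `logit(μ) = β₀ + β₁x` | `log(φ) = γ₀ + γ₁x` | inverse observed information (full 4×4) |
| `fraclogit` | `logit(μ) = β₀ + β₁x` | none assumed | robust sandwich `A⁻¹MA⁻¹` |

The beta models use the mean–dispersion parameterization of the beta
distribution: shapes `p = μφ`, `q = (1−μ)φ`, so `E(Y) = μ` and
`Var(Y) = μ(1−μ)/(1+φ)`. For the linear model `Δ̂ = β̂₁`; for the
logit-mean models `Δ̂ = expit(β̂₀+β̂₁) − expit(β̂₀)` with a delta-method
standard error, and the null `Δ = 0` is tested by Wald statistic with the
fixed critical value 1.96.

The scientific point of the comparison: when the two groups share a common
dispersion all four estimators are essentially unbiased with near-nominal
type-1 error, but if the dispersion differs between groups and the mean sits
away from 1/2, the constant-dispersion beta regression is **biased** and its
type-1 error escalates with sample size — while the variable-dispersion
model, the fractional logit and plain OLS remain well behaved.

## Worked example

Replicate the misspecification experiment (both groups have mean 0.25, but
dispersions 5 and 10; true Δ = 0) at 25 observations per group, with 2000
replications:

```r
library(propdiffsim)
sc  <- registry_scenario(1, 6, 25)   # mu0 = mu1 = 0.25, phi0 = 5, phi1 = 10
cfg <- experiment_config(sc, reps = 2000, seed = 42)
s   <- run_experiment(cfg)
s[, c("model", "bias", "mce_bias", "variance", "rejection_rate",
      "mce_rejection", "n_excluded")]
```

```
         model     bias mce_bias variance rejection_rate mce_rejection n_excluded
1       linear 0.000149 0.000960  0.00184         0.0505       0.00490          0
2   beta_const 0.023648 0.000906  0.00163         0.0970       0.00664         11
3 beta_vardisp 0.000445 0.000956  0.00183         0.0595       0.00529          0
4    fraclogit 0.000149 0.000960  0.00184         0.0565       0.00516          0
```

Read: under a true null, the constant-dispersion beta regression is biased
by ≈ +0.024 (more than 20 Monte Carlo standard errors from zero) and already
rejects almost twice too often at n = 25, while the other three estimators
sit at their nominal 5% level within Monte Carlo error. `n_excluded` counts
replications whose fit did not converge; they are dropped from the
aggregates. Columns `bias`, `variance` and `rejection_rate` come with their
Monte Carlo errors (`sd/√R`, `s²√(2/(R−1))`, `√(r(1−r)/R)`).

The shipped designs are addressable by `(table, row, n)`: registry 1 holds
24 beta-response scenarios (12 null, 12 with a +0.025 mean shift) and
registry 2 holds 4 discrete multinomial scenarios on the support
`{0.05, 0.15, …, 0.95}` (2 null, 2 with a one-point shift, Δ = 0.10).

## Command line

```sh
Rscript -e 'quit(status = propdiffsim::run_cli())' --args \
  --table 1 --row 1 --n 25 --reps 2000 --seed 7 --out results/
```

writes `results/summary_table1.csv` (one row per scenario × n, per-model
column blocks) and `results/run_log.dcf`. `--all` runs every row × sample
size of a table; `--config file.dcf` reads the same keys from a flat
key–value file, with command-line flags taking precedence.

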