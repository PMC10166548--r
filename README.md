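# mmcal

Bayesian calibration of a mechanistic apoptosis model to quantitative *and*
non-quantitative data through explicit, data-driven **measurement models**.

## The problem

Mechanistic ODE models of cell signaling are usually calibrated against
fluorescence time courses, because those map almost directly onto model
variables.  But most of cell biology's data are not like that: immunoblots
give ordered categories, cell-fate experiments give death/survival labels,
viability assays give population fractions with no stated link to any model
variable.  `mmcal` treats each of these as a first-class likelihood by
pairing the mechanistic model x(t, θ) with a parameterized measurement model
and inferring both parameter sets jointly:

- **Fluorescence** — Gaussian noise on normalized predictions:
  log L = Σ −(ŷ − y)² / 2σ².
- **Ordinal** (immunoblot-like) — a cumulative-link logistic model,
  P(y ≥ c_j | x) = φ(α(x − β_j)) with shared slope α and ordered boundaries
  β_j = Σ θ_j (θ_j > 0), plus a 95%/2.5% adjacent-category
  misclassification matrix marginalized in the likelihood.
- **Nominal** (cell fate) — Bernoulli outcomes with
  P(death | x) = φ(α(β + Σ β_l x_l)) over dynamic features of tBID
  (time at maximum truncation rate, log maximum rate, and an unrelated
  control signal).
- **Fractional cell death** — a zero-mean Gaussian process over
  critical-point features with ARD radial-basis kernel
  κ(x_p, x_q) = σ_f² exp(−½ (x_p−x_q)ᵀ M (x_p−x_q)), M = diag(β)⁻².

The mechanism is an abridged extrinsic apoptosis cascade (TRAIL → DISC →
initiator caspase → tBID → two MOMP steps → effector caspase → cPARP) with
lognormal cell-to-cell heterogeneity (CV 0.20) plus three disconnected
non-apoptotic control species.  Posteriors are sampled with a multi-chain
differential-evolution MCMC that draws difference vectors from an archive
of past states (4 chains, 25 crossover levels, 8 jump-size levels, γ=1
jumps at probability 0.10), stopping when the Gelman–Rubin statistic on the
latter half of every trace is ≤ 1.2.  Model certainty is summarized by the
**credible-region area**: the sum of 95% posterior-predictive band widths
over the 100-point time grid (smaller = more certain).

## Worked example

Generate a synthetic ordinal tBID time course from the built-in ground
truth, jointly calibrate mechanism rates and the ordinal measurement model,
and summarize certainty:

```r
library(mmcal)

truth <- ground_truth()
ord <- generate_ordinal_dataset(truth, observables = "tBID",
                                interval_s = 300, seed = 11)
nrow(ord)
#> [1] 67

problem <- calibration_problem(
  truth$network,
  list(dataset_ordinal(ord, c(tBID = 5L), prior_variant = "exponential")),
  free_rates = c("kc0", "kf1", "kc2", "kc3", "kc6"))

chains <- run_until_converged(problem,
  sampler_config(burn_in = 3000, max_steps = 40000, seed = 99,
                 check_interval = 1000, snooker_prob = 0.1))
max(chains$gelman_rubin)
#> [1] 1.179113

region <- credible_region(chains, predict_observable_fn(problem, "tBID"),
                          n_draws = 200, seed = 1)
credible_area(region)
#> [1] 31.30814
```

The run converges (every Gelman–Rubin statistic ≤ 1.2, here after 14,000
iterations per chain); the credible-region area of ~31 normalized-
concentration·timepoints quantifies how tightly the 67-point ordinal dataset
pins the tBID trajectory — repeating this with denser or sparser sampling
(or adding a nominal cell-fate dataset) moves this single number, which is
how the package measures what a dataset is worth.

A thin CLI wraps the same functions (`inst/cli/mml.R`):

```sh
Rscript inst/cli/mml.R generate --type ordinal --interval 60 --seed 1 --out ord.csv
```

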