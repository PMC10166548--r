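---
title: "Calibrating a mechanistic apoptosis model to non-quantitative data"
author: "mmcal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating a mechanistic apoptosis model to non-quantitative data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmcal)
```

## The problem

Most measurements in cell biology are not quantitative.  Immunoblots report
ordered intensity categories, cell-fate experiments report death or survival,
and viability assays report fractions of a population without any stated link
to the intracellular variables a mechanistic model actually simulates.
`mmcal` calibrates a mass-action ODE model of extrinsic apoptosis to such
data by giving every dataset an explicit, parameterized *measurement model* —
a probabilistic map from latent model variables to observed values — and
inferring mechanism and measurement parameters jointly in one Bayesian
posterior.

## The mechanism model

`aearm_network()` builds a compact extrinsic-apoptosis cascade: TRAIL ligand
and receptor form the death-inducing signaling complex (DISC, rate constant
`kc0`); the DISC binds and activates initiator caspase (the bound complex is
the IC-DISC observable); active initiator caspase truncates Bid; truncated
Bid (tBID) drives two sequential MOMP signal-activation steps; the second
MOMP signal activates effector caspase in a single step; effector caspase
cleaves PARP.  Three additional species (`USM1`–`USM3`) form a
feedback-coupled activation/inactivation loop that shares no reaction with
the cascade; they exist as negative controls for feature-selection analyses.
The exact published reaction and parameter tables of the model family this
network abridges are not reproduced here; the shipped network is a
documented equivalent with its own fixture ground-truth parameter vector,
tuned so that tBID shows the characteristic snap-action sigmoid with a
dose-dependent switch time.

```{r sim}
net <- aearm_network()
traj <- simulate_network(net)
round(traj_values(traj, "tBID", times = c(2000, 5000, 8000, 20000)))
```

Simulation uses `deSolve::lsoda` (automatic stiff/non-stiff switching) with
`atol = 1e-6`, `rtol = 1e-3`, a 2^20 step limit, and a 100-point linear grid
over 0–20160 s; off-grid values are linear interpolations.  Rate parameters
are inferred on the log10 scale because plausible rate constants span orders
of magnitude; the ODE consumes the linear scale.  Integration failures are
*signalled*, not fatal: a classed condition (`mmcal_infeasible`) is mapped
to log-posterior `-Inf` so that a calibration rejects the proposal and
continues.  Doses are stated in ng/mL and converted to ligand copies at 60
molecules per ng/mL (50 ng/mL = 3000 molecules per cell), a documented
package convention.

Cell-to-cell variability is modeled as lognormal initial conditions for the
receptor, the caspase zymogens, Bid and the control-module input `USM1`,
with the mean preserved and coefficient of variation 0.20
(`sample_initial_conditions()`).  Large populations are integrated in one
block-diagonal `lsoda` call with a banded Jacobian
(`simulate_population_batch()`), which is numerically equivalent to per-cell
simulation but an order of magnitude cheaper inside population likelihoods.

## The four measurement-model families

**Fluorescence** (`fluorescence_loglik`): i.i.d. Gaussian noise on
normalized predictions, `sum(-(pred - obs)^2 / (2 sd^2))`.  Trajectories are
normalized to [0, 1] by their own maximum before comparison; a flat
trajectory cannot be normalized and is treated as infeasible.

**Ordinal** (`ordinal_params`, `ordinal_category_probs`, `ordinal_loglik`):
a cumulative-link logistic model.  The probability of reaching category
`c_j` or above is `plogis(alpha * (x - beta_j))` with a shared slope `alpha`
and category boundaries `beta_j` on the normalized measurand scale;
category probabilities are differences of consecutive cumulative terms.
Boundaries are parameterized by positive distances `theta_j`
(`beta_j = cumsum(theta)`), so the ordinal ordering constraint holds by
construction.  Reporting error is an adjacent-category misclassification
matrix: 95% on the diagonal and 2.5% per interior neighbour (terminal
categories give the whole 5% to their single neighbour); the likelihood
marginalizes over the true category.

**Nominal** (`nominal_params`, `nominal_prob`, `nominal_loglik`): a logistic
model of death vs survival over three dynamic features of tBID — the time
at maximum truncation rate, the log of that maximum rate, and the level of
the unrelated control species at that time — each an independent Bernoulli
observation with zero label noise.

**Fractional cell death** (`gp_params`, `gp_log_marginal`,
`predict_fractional_cell_death`): a zero-mean Gaussian process over
critical-point features of tBID dynamics with an ARD radial-basis kernel,
`sigma_f2 * exp(-0.5 * sum(((xp - xq)/beta)^2))`.  Per-feature weights
`beta` set inverse squared length scales, so a large `|beta_l|` marks an
influential feature.  Observation noise enters only the Gram diagonal
(per-point reported sd, floored at 1e-3).  The Cholesky factorization adds
jitter `1e-8 * trace(K)/n`, doubling it up to three times before declaring
numerical failure (`-Inf`).  Two printed-formula ambiguities in the source
material for this family were resolved as design choices: the kernel is
evaluated on the *difference* `x_p - x_q` (a radial-basis kernel must be
translation invariant), and the GP prior mean is zero with the data entering
only through the marginal likelihood (standard GP regression), rather than
re-using the observations as their own prior mean.

A mixed dataset multiplies the component likelihoods
(`composite_loglik()` sums the logs; any `-Inf` component dominates).

## Feature extraction

Derivatives are finite differences on the uniform grid: second-order first
derivatives (central interior, one-sided ends) and fourth-order second
derivatives (5-point central interior, 6-point one-sided near the ends),
with stencil weights generated by Fornberg's algorithm.  The cell-fate
features refine the discrete maximum of the tBID derivative with a parabola
through the argmax and its neighbours: a grid-quantized maximum makes
population likelihoods piecewise constant in the rate parameters (the grid
spacing is 203 s), which stalls MCMC mixing, while the refined time and
height vary smoothly.  Critical points
(relative extrema from sign changes of the first derivative, inflections
from the second) are detected on interior points only, with derivative
magnitudes below 1e-10 normalized units treated as zero so float noise
cannot mint spurious critical points; equal maxima tie-break to the earliest
time.  Because different parameter vectors produce different critical-point
sets, features are column-indexed through an append-only look-up table with
capacity 10 (`feature_registry()`), keeping every GP weight's meaning fixed
across a whole calibration.

## Synthetic data

All datasets are generated from the fixture ground truth; nothing is
downloaded.  The ordinal category count follows the effective-bit-resolution
rule (`effective_resolution()`): `SNR = 20*log10(range/(1.6449 * rms))`,
`EBR = (SNR - 1.76)/6.02`, and `J` at most `0.7 * 2^EBR` — which yields 5
tBID categories and 4 cPARP categories for fluorescence-like noise, with
IC-DISC fixed at 4.  The `rms` term is taken to be the rms of the *noise*
component (the residual sd); this reproduces the standard effective-
resolution derivation of noisy analogue signals.  Sampling times use
interval counting (`k * interval`), which reproduces the documented dataset
sizes (112 points at 180 s, 336 at 60 s); an inclusive convention (adding
t = 0, e.g. 14 points at 1500 s) is also available because published
dataset sizes mix both conventions.

Ordinal data: the ground-truth trajectory is normalized, mapped to category
probabilities by fixture ordinal parameters (slope 50; boundaries every 0.2
of the tBID range, every 0.25 for cPARP/IC-DISC), sampled, then corrupted
by the 5% misclassification model.  Nominal data: two heterogeneous
populations of 200 cells at 10 and 50 ng/mL are simulated, features
extracted and standardized by frozen reference constants, and outcomes drawn
from the fixture logistic model.  The fixture constants are package choices
standing in for unpublished ground-truth tables: features are standardized
to roughly unit scale, and the fixture weights (time at maximum truncation
rate -0.45, log maximum rate 0.3, unrelated signal 0) are of a size the
Laplace(0, 0.1) weight priors plausibly support — a ground truth the stated
priors could not support would make any recovery experiment meaningless.
Half-max-time data: per-cell times at half-maximal tBID by linear
interpolation, rounded to the nearest 180 s.

## Priors and sampling

Mechanism rates: independent normals on log10 rates centred at the
reference vector with scale 1.5.  Ordinal measurement models: exponential
priors (slope scale 100, distance scale 0.25) in the data-driven default;
biased variants encode boundary assumptions as uniform(0,1)/uniform(0,100),
Cauchy(0.2, 0.05)/Cauchy(50, 10), or Cauchy(0.2, 0.005)/Cauchy(50, 1)
priors (Cauchy variants truncated to the positive half-line, which the
distance support requires).  Nominal models: Laplace(0, 1) on the slope (truncated to the positive
half-line — the model is invariant under jointly flipping the signs of
slope, intercept and weights, so the unconstrained posterior has two exact
mirror modes and raw-parameter convergence is undefined; the constraint
removes the redundant copy without changing anything observable) and
Laplace(0, 0.1) on intercept and weights.  Genotype multipliers on `kc0`:
normals on the log10 multiplier (locations 0 and -1, scale 1.5) truncated
above at 0 so a dominant-negative genotype can only diminish DISC
formation.  Extrinsic variance: an inverse-gamma whose hyperparameters are
moment-matched (`invgamma_cv_match()`) so the induced CV has prior mean
0.20 and sd 0.015.  Where the prior scale for lognormal-type priors could
be read as natural-log or log10, log10 was chosen: scale 1.5 then spans
roughly three orders of magnitude, which matches how loosely rate constants
are known.

Sampling uses a multi-chain differential-evolution MCMC with a past-state
archive (`dream_sample()`): 4 chains; proposals are scaled differences of
two archive states restricted to a random parameter subspace (25 crossover
levels); jump sizes take `2.38/sqrt(2 d')` divided by one of 8 discrete
levels, with a unit jump (`gamma = 1`) at probability 0.10 to allow mode
swaps; crossover and jump-level selection probabilities adapt during
burn-in only, freezing afterwards to preserve detailed balance.  Snooker
updates are implemented but off by default — the archive-difference
proposal is the core of the algorithm family, and internals beyond the
documented settings are deliberately not guessed.  Convergence is the
Gelman-Rubin potential scale reduction factor on the latter 50% of each
trace, with the run stopping when every free parameter is at or below 1.2
(`run_until_converged()`); reaching the step cap without convergence is
reported, not thrown.

## Posterior analytics

`credible_region()` sub-samples 1000 posterior parameter sets (type-7
quantiles, documented for bit-stability), simulates each, and takes
pointwise 0.025/0.975 envelopes on the 100-point grid; `credible_area()`
sums the band widths — the certainty metric used throughout (smaller area,
more certain model).  Normalization of predicted tBID uses each draw's own
maximum.  `ordinal_probability_bands()`, `decision_boundary()` (the 50%
survival line in a feature plane), `feature_weight_posterior()` (the
product slope × coefficient, invariant under the joint sign flip) and
`predict_fractional_cell_death()` (GP posterior means clamped to [0, 1])
cover the measurement-model side.  Population feature clouds are summarized
by 0.05-level Gaussian-KDE contours with Scott's-rule bandwidth.

## Reduced problem sizes

The package's tests and the acceptance script run desk-scale versions of
experiments that, at publication scale, take multi-day calibrations: 2–5
free mechanism rates instead of the full vector, ordinal datasets of 4–336
points, nominal datasets of 400 observations with 16 simulated cells per
dose recycled across observations (the outcome-to-cell pairing is arbitrary
because the inference re-simulates its own heterogeneous sample), chains of
at most 40,000 iterations.  These sizes are the package's own defaults for
its reproduction experiments.  Two consequences of shrinking the parameter
vector deserve note.  First, a small model *saturates*: beyond a modest
number of measurements the posterior stops tightening, so the dataset-size
contrast pairs a dense (67-point) with a deliberately under-determined
(4-point) ordinal dataset, preserving the full-scale study's property that
its sparsest datasets carry fewer measurements than the model has free
parameters.  For the same reason the
dataset-synergy experiment pairs the IC-DISC ordinal dataset with a small
(2 by 16 observation) nominal dataset: against a two-rate mechanism the
full 400-observation nominal dataset is saturating rather than weakly
informative, which would invert the full-scale picture it is meant to
reproduce; the 400-observation dataset is used where its information is
needed, in the feature-selection recovery.  Second, conclusions that depend
on dataset size are asserted as orderings (dense beats sparse; combined
beats either alone), not as reproductions of printed area values, which
belong to the full-scale setting.

## What the generators do and do not emulate

The synthetic generators reproduce the statistical structure of the data
types — category counts from effective bit resolution, adjacent-category
misclassification, Bernoulli cell fates driven by trajectory features,
lognormal extrinsic heterogeneity — but not the artefacts of real assays:
no blot saturation or loading variation, no segmentation errors, no
batch effects, and the fluorescence emulator is a noisy sigmoid rather than
any published reporter dataset.  Tests passing on these data show the
inference machinery is correct and internally consistent; they do not
validate the biology of the network against real measurements.

## Known limitations

Single-species observables only (each observable maps to one network
species); binary nominal outcomes; no stochastic (SSA) simulation; no
parallel tempering or gradient-based samplers; the GP measurement model
fixes its weights during joint mechanism inference (free GP-weight blocks
are exercised at the unit level).  The double-well and Gaussian recovery
tests bound sampler bias at desk scale but say nothing about worst-case
multimodal targets.
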