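---
title: "Shrinking treatment effects in network meta-analysis: models, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shrinking treatment effects in network meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A contrast-based network meta-analysis (NMA) takes `S` two-arm studies, each
reporting an observed relative effect `y_i` (on an additive scale such as the
log odds ratio) with standard error `s_i` for a comparison of treatments
`t1_i` and `t2_i`, and estimates the `T - 1` *basic parameters* `d_k` -- the
effects of each treatment versus a reference, with `d_ref = 0`. Every one of
the `T(T-1)/2` pairwise contrasts is a linear combination `d_k - d_j`
(consistency). The standard Bayesian model,

```
y_i ~ N(d[t2_i] - d[t1_i], s_i^2 + tau^2),    d_k ~ N(0, 100^2),
```

treats the basic parameters as a priori independent. That is harmless for a
single prespecified comparison, but NMAs are almost always used to *select*
something afterwards -- the best-ranking treatment, or the contrasts whose
95% credible intervals exclude zero. Selection among many independently
estimated parameters systematically favours estimates that are extreme by
chance: in a null star network of `T` equally effective treatments the
familywise chance of at least one "significant" basic parameter is
`1 - 0.95^(T-1)` (62% at `T = 20`, see `expected_familywise_rate()`), and
the selected best-vs-worst contrast is biased away from zero even without
any significance thresholding.

## The models

`fit_nma()` implements five variants that differ only in the prior on the
effect vector:

* **Model I** (standard): independent `d_k ~ N(0, d_sd^2)`; `d_sd = 100`
  ("flat") or `1` ("informative").
* **Model II** (exchangeable): all non-control basic parameters share
  `d_k ~ N(mu_d, tau_d^2)`. The hierarchy shrinks each effect towards the
  estimated common mean by an amount the data choose through `tau_d`
  (`tau_d = 0` is complete pooling, `tau_d -> Inf` recovers Model I). A
  declared control arm is required; it stays outside the exchangeable set.
* **Model III** (symmetric): all `T` effects are jointly normal with
  pairwise correlation 0.5 and mean fixed at zero (the common level does not
  enter the likelihood, so fixing it loses nothing). No treatment is
  privileged, which suits networks without a natural control. Any contrast
  has implied prior variance `tau_d^2`.
* **Model IV**: Model II with several exchangeable *classes* of non-control
  treatments, each with its own `mu_dx` and `tau_dx` (optionally a shared
  `tau_d` via `common_class_sd`).
* **Model V**: the symmetric analogue of IV -- 0.5-correlated effects within
  each class, independence across classes, class means sampled under their
  vague priors. The class blocks make within-class contrasts shrink like
  Model III while between-class contrasts remain nearly unshrunk.

Defaults for the hyperpriors follow the simulation protocol:
`mu_d ~ N(0, 10)` read as **variance** 10 (the notation is ambiguous; the
flat treatment-effect prior is written with an explicit square as `100^2`,
so the unsquared 10 is taken as a variance; it is configurable via
`prior_spec(mu_d_var=)`), `tau_d ~ U(0, 2)`, and `tau ~ U(0, 5)` for the
heterogeneity SD under random effects. A half-normal `tau_d` prior is
available for applied analyses.

## Sampling

The posterior is explored with a blocked Gibbs sampler (RcppArmadillo):

* `d | rest` is conjugate multivariate normal. The prior covariance is
  `D C D` with `C` a fixed correlation matrix (identity, or 0.5-blocks for
  the symmetric models) and `D` the diagonal of prior SDs, so its inverse is
  available in closed form each sweep.
* class means `mu_d` are conjugate normal (the prior precision of `d` is
  block-diagonal across classes, so each mean only sees its own block);
* `tau_d` and `tau` are updated by slice sampling on the SD scale with
  shrinkage on a fixed bounded interval -- the natural choice under uniform
  priors. The half-normal prior is sampled on `(0, 15 * scale)`; the
  truncated mass is of order `1e-50`.

Study-level random effects are marginalised analytically
(`y_i ~ N(., s_i^2 + tau^2)`) rather than sampled, which is exactly
equivalent for two-arm contrast data and mixes better; the test suite
verifies the equivalence against an explicitly hierarchical fit. Records
sharing a study id (multi-arm trials) receive a joint multivariate normal
likelihood with `tau^2/2` between-contrast random-effects covariance. Their
within-study sampling covariance cannot be recovered from contrast-level
SEs alone: either supply it (`sampling_cov=`) or the package approximates a
shared baseline-arm variance as half the smallest contrast variance in the
study. Chains are seeded as `seed + chain`, so every fit is
bit-reproducible.

For Model I with common effects there are no hyperparameters and the
"sampler" draws i.i.d. from the exact multivariate-normal posterior, whose
mean and covariance match the generalized-least-squares solution
(`fit_fixed_effect_gls()`); the test suite uses this as an analytic oracle.

Default chains follow the simulation protocol (2 chains, 15000 iterations,
5000 burn-in). Convergence is monitored with split-Rhat (flagged above
1.05) and an initial-positive-sequence effective sample size; tied or
degenerate draws are handled conservatively. Credible intervals are
equal-tailed posterior percentiles of the retained draws; point estimates
are posterior medians.

## Ranking

`rank_probabilities()` ranks treatments per draw by their effect on the
common scale (reference included at zero; the symmetric models' common
level cancels, so ranks are invariant to it). Ties -- a measure-zero event
for continuous posteriors -- are broken by treatment order so results are
deterministic. `sucra()` averages the cumulative rank probabilities:
`SUCRA = 1` is certainly best, `0` certainly worst, and values always sum
to `T/2`. The default direction treats larger effects as better, matching
the simulation truths; applied analyses must state the direction.

## The scenario simulator

`make_scenario()` / `simulate_dataset()` generate the study conditions the
simulation harness measures, and they are deliberately rigid: the defaults
*are* the conditions, not dials.

* Standard errors: `s_i = 0.5 + 0.2 * chi2_1` -- bounded below at 0.5, mean
  0.7 -- emulating modest binary-outcome trials on the log-OR scale.
* Heterogeneity (family B only): one `tau^2 ~ LogNormal(-2.56, 1.74^2)` per
  dataset, an empirical distribution for log-OR heterogeneity; all
  comparisons share it.
* Geometries: star (every study versus treatment 1) and fully connected
  (one independent study per unordered pair, 45 for `T = 10`), one or more
  studies per edge depending on the scenario.
* Truths: all-zero (A-D); all actives equal to 1 (E); two five-treatment
  groups 0/1 (F); all-different `psi_t = 0.9 + 0.1 t` (G); control plus two
  classes at 1 and 2 (H).

Only two-arm studies are generated. What the simulator does **not**
emulate: multi-arm trials, unequal per-comparison evidence, sampling-error
dependence between `y_i` and `s_i`, publication bias, or inconsistency.
Passing simulation checks therefore says nothing about those features of
real data; the models' multi-arm path is exercised separately by unit
tests.

## Analysis protocol and one deliberate deviation

`run_study()` fits every requested model to the same datasets (paired
comparisons), evaluates each against the scenario truth and aggregates:
mean absolute error and bias of basic parameters (posterior medians);
best-vs-worst and best-vs-reference contrasts selected by SUCRA per
dataset; the share of datasets with a confident nonzero among truly-equal
contrasts; power pooled over truly-nonzero contrasts; reversal rate (a
confident interval with the wrong sign) over all contrast estimates; and
the per-dataset maximum/minimum SUCRA.

Random-effects analysis is used exactly where the generator has random
effects (family B). Scenario C (two treatments, five studies) is analysed
with the common-effect models: with only five homogeneous studies a
`U(0, 5)` heterogeneity prior dominates its posterior (median near 1),
which would inflate every posterior SD to ~0.7 -- incompatible with the
behaviour this scenario is meant to exhibit (pooled SEs near 0.3 and a ~5%
two-treatment false-positive rate, which the common-effect analysis
reproduces). The "confident nonzero" count uses all pairwise contrasts,
not only basic parameters; power pools truly-nonzero contrasts across
datasets.

Seeding is hierarchical and documented in the run manifest: the scenario
stream is derived from the base seed, each dataset from the scenario
stream, each fit from the dataset index and model position, each chain from
the fit seed (`substream_seed()`; a fixed Lehmer-style integer hash, always
below 2^31).

## Problem sizes and numerical choices

The reduced-replication studies in the test-suite and in
`scripts/acceptance.R` use 200 datasets per scenario (500 for the
reversal-rate scenario, whose target is a ~1% event) with 2 chains of 4000
iterations (1000 burn-in). Monte Carlo tolerances are three standard
errors, binomial for per-dataset rates and cluster-aware (per-dataset
proportions) for pooled rates, since contrasts within a dataset are
correlated. The two-treatment equivalence check compares posterior medians
of two separately seeded fits, so its value is dominated by Monte Carlo
error of the median; it uses 2 chains of 35000 iterations to make that
error small relative to the quantity itself. Degenerate inputs are
rejected early: non-positive SEs, self-comparisons, disconnected networks
(flagged in summaries, fatal at fitting), missing controls or classes.

## Known limitations

* Inconsistency (design-by-treatment interaction) is not modelled; the
  consistency equations hold by construction.
* Arm-level (binomial) likelihoods are out of scope; inputs are
  contrast-level.
* The multi-arm sampling-covariance approximation is a convention; supply
  the true covariance when it is known.
* Class means are independent across classes; exchangeability *across*
  classes and treatment-level meta-regression are not implemented.
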