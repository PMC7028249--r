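---
title: "Estimating family-planning indicators for all women: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating family-planning indicators for all women: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The estimation problem

National surveys measure contraceptive use and unmet need for family
planning irregularly: a country may have a dozen estimates over forty
years or none at all, from sources of varying quality, sometimes for
non-standard target populations. Unmarried women (UWRA) are covered far
more thinly than married or in-union women (MWRA), and their indicator
levels depend strongly on how common sexual activity is among unmarried
women in a given society. This package estimates and projects annual
country trajectories of seven indicators for MWRA, UWRA and all women
(WRA), with full posterior uncertainty, by pooling whatever surveys exist
through a hierarchical time-series model.

## Latent structure

Each country and marital group carries three latent annual series on an
annual mid-year grid:

* **Total prevalence** `P`: logistic growth trend
  `p̃ / (1 + exp(−ω (t − T)))` plus a stationary AR(1) deviation on the
  logit scale. The logistic shape encodes the diffusion character of
  contraceptive adoption — slow uptake, acceleration, saturation below an
  asymptote `p̃ < 1`.
* **Modern share** `R` (modern use / any use): the same logistic form
  with its own parameters.
* **Unmet-share among non-users** `Z*`:
  `logit(Z*) = α + β₁P + β₂P² + AR(1)`, a function of prevalence rather
  than time. Unmet need is `(1 − P)·Z*`, so it vanishes as `P → 1`; a
  very negative country level `α` produces the regime where both
  prevalence and unmet need are essentially zero, as among unmarried
  women in low-sexual-activity settings.

The AR(1) deviations are mean-zero and stationary (marginal sd `σ`,
autocorrelation `φ`, innovation variance `σ²(1 − φ²)`), shared globally
per process. They absorb reversals and country-idiosyncratic swings, and
they define the projection distribution: beyond the fitted grid each
retained trajectory continues by sequential sampling from the AR(1)
conditionals, so projection intervals widen toward the stationary band
around the (time-invariant) systematic trend.

## Hierarchy

Country parameters are exchangeable within a geography tree: transformed
country values are normal around subregion means, which are normal around
region means, which are normal around a world mean, with one half-normal
spread parameter per level and parameter. For UWRA a two-group
sexual-activity classification is spliced between world and region for
the *level/asymptote* parameters (`p̃`, `r̃`, `α`) only; pace and timing
parameters (`ω`, `T`, `ρ`, `t_r`) remain purely geographic. The placement
and the structured-parameter set are configurable
(`fp_model_config(group_structured_params = ...)`); the default reflects
the substantive claim that sexual activity shifts *levels* of use and
need among unmarried women rather than the speed of diffusion.

Group assignment (`assign_sexual_activity_group()`) follows a strict
precedence: a manual override, then the survey-based rule (below 2 %
sexually active in the past 28 days → low-activity group, strict
less-than), then an attitude-based cutoff, then a religiosity cutoff. The
attitude (0.25) and religiosity (0.90) cutoffs are package constants with
no published counterpart; the supported path for replicating any official
country classification is the override column. Countries with no
classification input raise an error rather than receive a silent default.

## Observation model

Survey estimates enter on transformed scales: logit total prevalence,
logit modern share, logit unmet-share among non-users, with sampling
variances obtained by first-order error propagation from the reported
component standard errors. Three numerical conventions matter:

* proportions of exactly 0 or 1 are nudged inward by `0.5/ess`
  (`ess = 1000` by default) before any logit, at the reader;
* a missing standard error for a reported value is imputed as the median
  standard error of the same source type and marital group, and flagged;
* a survey reporting a single combined figure with no traditional-method
  split enters as a *total-prevalence* observation carrying the
  `modern_only_reported` misclassification bias on the total component;
  the modern share is left unidentified for that row.

Bias terms are additive on the transformed scales, shared globally per
flag category, with Normal(0, 0.5²) priors and no imposed direction.
Population-definition flags (non-standard age group, subnational
geography, non-standard union definition) shift all three components;
method-misclassification categories shift the component they distort
(the combined-figure case shifts the total; sterilization-omitted and
folk-as-modern shift the modern share). Total error per component is
sampling variance plus a squared source-type nonsampling term `τ_s`
(half-Normal(0.2) prior), estimated per source type. Components are
treated as independent given the latent state — a simplification;
cross-component sampling correlation from shared denominators is ignored.

Observations at arbitrary fieldwork midpoints are linearly interpolated
between adjacent grid years on the transformed scale. Reference time is
the fieldwork midpoint (`start + (end − start)/2`; a single year maps to
`year + 0.5`).

## Inference

The joint model is expressed in the BUGS language and sampled with JAGS
(Gibbs/slice updates), behind the `run_mcmc()` contract: `iterations`
post-adaptation sweeps per chain, the first `burn_in` discarded,
thinning by `thin`, and bitwise reproducibility from
(model, settings, seed) via per-chain Mersenne-Twister streams.
Convergence is monitored by split R-hat (threshold 1.1) and effective
sample size over all scalar hyperparameters plus a stratified sample of
trajectory nodes; the pipeline's `report` stage refuses to publish while
flags are outstanding unless forced. Priors: Normal world means with sd
10 on logit/log scales (sd 10 around year 2000 for the trend midpoints),
half-Normal(1) level sds on logit/log scales and half-Normal(10) for the
year-scale midpoint parameters, `φ ~ Uniform(0, 0.95)`,
`σ ~ half-Normal(0.5)`, `β₁, β₂ ~ Normal(0, 5²)`.

Countries with no observations are not placed in the sampler; their
trajectories come from `impute_nodata_country()`, which draws country
parameters per retained draw from the fitted hierarchical distribution at
the country's position (falling back one level, with the corresponding
between-level variance added, when its subregion holds no fitted
country), then simulates stationary AR(1) deviations. Imputed bands are
necessarily wider than those of data-rich peers.

## Indicators, counts and aggregation

From `(P, R, Z*)`: modern prevalence `P·R`, traditional `P·(1−R)`, unmet
need `(1−P)·Z*`, unmet need for modern methods = unmet + traditional
(traditional users are counted as having unmet need for modern methods),
total demand = prevalence + unmet, demand satisfied by modern methods =
modern / total demand (undefined when total demand is zero — returned as
missing, never 0). These identities hold per draw by construction and
are asserted in tests to machine precision.

Counts multiply each posterior draw by the population of women 15–49 in
the relevant marital group and year; aggregates (regions, world, and
MWRA + UWRA → WRA) are draw-wise sums on the count scale, so cross-year
and cross-quantity correlation survives into aggregate intervals, and
changes over time are computed within trajectory before summarizing
(PPI = share of draws with a positive change). Summaries are medians with
2.5/97.5 percentiles, type-7 (linear-interpolation) quantiles throughout.
Reported percentages round to one decimal and counts to whole millions.

## The synthetic world

`synthetic_config()` defines the study conditions used throughout the
tests: 3 regions × 2 subregions × 3 countries (18 countries), annual
truth 1970–2030, surveys fielded 1975–2015 with on average 4 per country
and marital group, a DHS-heavy source mix, one third of countries in the
low-sexual-activity group, flag probabilities of 2–6 %, missing
traditional splits (10 %), missing unmet need (20 %) and missing
standard errors (15 %), lognormal effective sample sizes around 3 000,
and hyperparameters (trend levels by marital group, AR persistence 0.8 –
0.85 with logit-scale sds around 0.09, source-type errors 0.04 – 0.12)
chosen as typical of national family-planning compilations. The
generator draws from the same hierarchical and observation-model
assumptions the sampler fits — deliberately, because that is what makes
interval calibration measurable: under these nominal conditions the
fitted 95 % bands should cover the true trajectories at close to nominal
rates, and the test suite checks pooled coverage against the 0.90 – 0.98
band with near-zero mean bias.

What passing these tests does *not* show: robustness to
misspecification. Real compilations contain non-logistic trends,
non-normal and correlated survey errors, biases that drift over time,
and populations whose marital composition interacts with age structure
in ways the generator's smooth logistic unmarried-share trend does not
attempt. The cross-validation tooling (`cross_validate()`, three
leave-out schemes) is the instrument for probing predictive calibration
on real data.

## Problem sizes and settings used by the tests

The shipped fixture world has 18 countries; the recovery fit in the test
suite uses 2 chains × 9 000 iterations (4 000 burn-in, thinning 5) on a
50-year grid (1970.5 – 2019.5), a size chosen so the full suite completes
in a few minutes while leaving enough retained draws (2 000) for stable
interval estimates. Fast unit tests use a 4-country world with shorter
chains. Full-scale applications (about 185 countries, longer chains,
several chains in parallel) use the same code paths with larger
settings; the defaults recorded in `default_pipeline_config()` are
test-scale, not publication-scale.

## Known limitations

* Cross-component independence of observation errors (above).
* The unmet-need curve is quadratic in prevalence on the logit scale;
  other monotone shapes are plausible and would be swapped behind
  `unmet_share_curve()`.
* `φ` and `σ` are global per process, not country-specific.
* The delta-method variances degrade for proportions very near 0 or 1;
  the boundary nudge bounds the damage but very sparse low-prevalence
  countries lean heavily on the hierarchy.
* No age structure below the 15–49 aggregate, and no subnational
  estimation.
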