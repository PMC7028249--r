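# fpest

Bayesian hierarchical estimation and projection of family-planning
indicators — contraceptive prevalence (any/modern/traditional), unmet need
for family planning, unmet need for modern methods, total demand, and the
proportion of demand satisfied by modern methods (SDG indicator 3.7.1) —
for women of reproductive age (15–49), separately for married or in-union
women (MWRA) and unmarried women (UWRA), and combined to all women (WRA)
on the count scale.

The package is aimed at population and reproductive-health analysts who
work with compilations of national survey estimates: sparse, irregular
country series from heterogeneous sources (DHS, MICS, PMA, national and
other surveys), with known definitional quirks and source-dependent
quality.

## The model

For each country `c`, three latent annual series are modelled on
transformed scales:

- total contraceptive prevalence `P_ct`, with a logistic growth trend
  `Λ_c(t) = p̃_c / (1 + exp(−ω_c (t − T_c)))` — social-diffusion-shaped
  adoption with country asymptote `p̃_c`, pace `ω_c`, midpoint `T_c`;
- the modern share of use `R_ct`, with the same logistic form
  (`r̃_c`, `ρ_c`, `t_c`);
- the unmet-need share among non-users `Z*_ct`, driven by prevalence
  rather than time: `logit(Z*) = α_c + β₁ P + β₂ P² + ε`, so that unmet
  need `(1 − P)·Z*` vanishes both at full prevalence and (through a very
  negative `α_c`) in populations where unmarried women are rarely
  sexually active.

Stationary AR(1) deviation processes on the logit scales absorb
departures from the smooth trends, including reversals, and supply the
forecast distribution when trajectories are projected to 2030 (years
≥ 2020 are labelled projections). Country parameters are pooled through
a geographic hierarchy (country ⊂ subregion ⊂ region ⊂ world); for
unmarried women a two-category sexual-activity classification (below 2 %
sexually active in the past 28 days vs the rest) is spliced between world
and region for the level/asymptote parameters, so data-poor countries
borrow strength from the right peers. Observations enter on transformed
scales with delta-method sampling variances, additive bias terms for
non-standard target populations or method categorizations, and
source-type-specific nonsampling error. The joint posterior is sampled
with JAGS; counts are obtained by multiplying posterior draws by
population counts of women 15–49, and all aggregation (regions, world,
MWRA + UWRA → WRA) is draw-wise on the count scale.

A synthetic-data generator (`generate_world()`, `generate_surveys()`)
produces complete worlds — hierarchy, populations, ground-truth
trajectories, surveys with biases and noise — from the same generative
assumptions, so calibration and parameter recovery are measurable.

## Worked example

```r
library(fpest)

# indicator arithmetic from published global 2019 medians (all women):
# modern use 44.3%, unmet need for modern methods 14.2%
ind <- derive_indicators(prev_modern = percent_to_prop(44.3),
                         prev_traditional = 0,
                         unmet_any = percent_to_prop(14.2))
round(prop_to_percent(ind[c("total_demand", "demand_satisfied_modern")]), 1)
#>   total_demand demand_satisfied_modern
#> 1         58.5                    75.7

# a synthetic world: 18 countries in 3 regions, surveys 1975-2015
cfg <- synthetic_config(seed = 20260901)
world <- generate_world(cfg)
surveys <- generate_surveys(world)

# fit the married/in-union model, project to 2030, summarize globally
model <- fp_model(surveys, world$countries, "MWRA")
fit <- run_mcmc(model, chains = 2, iterations = 6000, burn_in = 3000,
                thin = 5, seed = 1)
fit <- extrapolate(fit, horizon_end = 2030.5, seed = 1)
tab <- indicator_table(fit, populations = world$populations,
                       years = c(2000, 2019, 2030), aggregates = "world")
subset(round_results(tab), unit == "World" & scale == "percent" &
         indicator %in% c("prev_modern", "unmet_modern", "total_demand"))
#>      unit marital_group year    indicator   scale median lower95 upper95
#> 706 World          MWRA 2000  prev_modern percent   23.7    22.0    25.7
#> 714 World          MWRA 2000 total_demand percent   67.4    65.9    68.9
#> 712 World          MWRA 2000 unmet_modern percent   43.6    41.6    45.4
#> 719 World          MWRA 2019  prev_modern percent   51.6    48.7    54.9
#> 727 World          MWRA 2019 total_demand percent   80.2    78.4    82.4
#> 725 World          MWRA 2019 unmet_modern percent   28.7    26.2    31.0
#> 732 World          MWRA 2030  prev_modern percent   57.9    53.5    63.5
#> 740 World          MWRA 2030 total_demand percent   83.0    80.2    86.5
#> 738 World          MWRA 2030 unmet_modern percent   25.1    20.7    28.5
```

The medians are the posterior 50th percentiles of the draw-wise world
aggregate (summed counts divided by summed population); `lower95`/`upper95`
are the 2.5th and 97.5th percentiles, and 2030 rows are projections. The
same machinery produces per-country tables, UWRA results, and all-women
results via `wra_indicator_table()`.

An end-to-end orchestration is available as
`run_pipeline("simulate" | "fit" | "indicators" | "aggregate" |
"validate" | "report", ...)`, with a thin command-line wrapper in
`inst/cli/fpest.R`. `report` refuses to publish tables while convergence
flags are outstanding unless forced.

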