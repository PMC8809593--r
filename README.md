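# cropfragility

Conditional extreme value modelling of crop-yield losses under weather
extremes.

## The problem

For food-insecure regions the policy-relevant question about weather and
agriculture is not how average rainfall moves average yields — those mean
effects are small and noisy — but how likely a *severe* harvest failure is
when the weather is *extreme*: drought, flood-level rainfall, unusually hot
nights or days. Both events live in the tails of their distributions, where
empirical co-occurrence counts are hopeless and naive regression says
nothing. `cropfragility` is for analysts working with annual country-level
panels (yields joined to growing-season weather aggregates) who want
defensible estimates of

P( YieldRefl > q₀.₉₀ | Hazard > q_c ),  q_c = 0.91 … 0.9999,

the probability of a yield loss beyond its 90th-percentile severity given a
weather hazard beyond a high quantile. `YieldRefl = -Yield`, so losses are
an upper tail; droughts enter as reflected precipitation (`PrecRefl`).

## The model

The chain, on pooled per-country-standardized regional panels:

1. **Semi-parametric margins.** Each variable gets the empirical
   distribution below its 80th percentile and a maximum-likelihood
   generalized Pareto tail `{1 + ξ(x-u)/β}₊^(-1/ξ)` above it, with
   mean-residual-life diagnostics supporting the threshold.
2. **Laplace margins.** Fitted probabilities map to the standard Laplace
   scale, `y = log(2F)` / `-log(2(1-F))`, whose tails are unit
   exponential.
3. **Conditional extremes (Heffernan–Tawn) dependence.** Above the 90th
   percentile of the conditioning variable,
   `Y_resp | Y_cond = y  =  a·y + y^b·Z`, with `-1 ≤ a ≤ 1`, `b < 1`,
   the joint consistency constraints of Keef–Papastathopoulos–Tawn, a
   Gaussian working likelihood for point estimation, and the empirical
   residual distribution kept for everything downstream. The sign and size
   of `a` are the sign and strength of the extremal dependence.
4. **Monte-Carlo extrapolation.** Conditional exceedances are simulated
   (`y_cond = v + Exp(1)` on the Laplace scale, residuals resampled), 1000
   draws per level of the 91st–99.99th percentile grid; 95% intervals come
   from a 100-replicate full-refit paired bootstrap.
5. **Fragility summaries.** Per (region, crop, hazard): the conditional
   loss probability at the 98th hazard percentile (cells whose interval
   includes zero are flagged); per region, the worst case — the maximum
   upper interval bound over crops and hazards.

A synthetic-data module (`synthetic_spec()`, `gen_pair()`,
`gen_region_fixture()`, `oracle_cond_prob()`) generates panels with known
tail dependence (Gaussian / logistic copulas, independence, perfect
dependence, exact model form) and brute-force oracles, so every stage is
testable against a known truth.

## Worked example

A synthetic two-region panel with known dependence between yield losses and
precipitation extremes, run through the full default analysis:

```r
library(cropfragility)
library(dplyr)

wet <- synthetic_spec("gaussian", dep = 0.6,  n_countries = 12,
                      n_years = 42, missing_rate = 0.05, seed = 101)
dry <- synthetic_spec("gaussian", dep = 0.45, n_countries = 12,
                      n_years = 42, missing_rate = 0.05, seed = 202)
panel <- bind_rows(
  gen_region_fixture(wet, hazard = "prec", low_tail = FALSE, country_prefix = "A"),
  gen_region_fixture(dry, hazard = "prec", low_tail = TRUE,  country_prefix = "B")
)
map <- bind_rows(
  tibble(country = sprintf("A%02d", 1:12), region = "Wetland"),
  tibble(country = sprintf("B%02d", 1:12), region = "Dryland")
)

run <- run_pipeline(run_config(panel, map = map, seed = 42))
run$worst_case
#> # A tibble: 2 × 6
#>   region  crop  variable  orientation point worst_case
#>   <chr>   <chr> <chr>     <chr>       <dbl>      <dbl>
#> 1 Dryland maize prec_refl low         0.236      0.476
#> 2 Wetland maize prec      high        0.631      0.775
```

Read: in the "Wetland" region — generated so that *high* precipitation and
yield losses share a Gaussian-copula tail with ρ = 0.6 — the estimated
probability of a severe maize loss given precipitation beyond its 98th
percentile is 0.63, and the worst-case (upper 95% bootstrap bound over all
crop-hazard cells) is 0.78. In "Dryland" the dependence was planted in the
*low*-precipitation tail (drought, ρ = 0.45), and the analysis finds it
there: point 0.24, worst case 0.48. Under independence both numbers would
sit near 0.10, the unconditional chance of a 90th-percentile loss.
`run$fragility` holds the full cell table (with `shown = FALSE` for cells
whose interval touches zero), `run$curves` the underlying probability
curves, and `run$manifest` the per-combination fit status, seeds and
warning counts.

Individual stages are ordinary pipe-able functions returning tibbles —
`build_region_panel() |> assemble_pair() |> transform_pair() |>
fit_conditional()` — with `tidy()`, `glance()` and `autoplot()` methods on
the fitted objects (`mean_residual_life()` curves, profile likelihood
surfaces, threshold-stability traces, probability curves).

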