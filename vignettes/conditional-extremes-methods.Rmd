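---
title: "Conditional extremes for crop fragility: model, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional extremes for crop fragility: model, assumptions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(cropfragility)
library(dplyr)
```

## The question the package answers

Mean-effect regressions relate average weather to average yields and
typically explain little. The question here is different: *given that a
weather variable is beyond a high (or low) quantile, how likely is a severe
yield loss?* Formally, for a reflected yield series (so losses are the upper
tail) and a weather hazard, the package estimates

$$
P\!\left(\mathrm{YieldRefl} > q_{0.90}^{\mathrm{YieldRefl}} \;\middle|\;
         \mathrm{Hazard} > q_{c}^{\mathrm{Hazard}}\right),
\qquad q_c = 0.91, \dots, 0.9999 .
$$

Both events are rare, so their joint behaviour cannot be read off empirical
counts: a model for the *joint tail* is required, and extrapolation beyond
the data range must be principled.

## Data model and preprocessing

Input panels are annual country-year records of one crop: yield (hg/ha),
growing-season precipitation (mm) and mean daily minimum/maximum
growing-season temperature (deg C), nominally 1961-2002 (up to 42 years per
country). Individual country series are too short for tail estimation, so
countries are pooled into regions (the packaged `region_map()` assigns 83
countries to six regions following the UN Statistics Division composition).
Pooling heterogeneous countries directly would let high-level countries
dominate the pooled tails, so each variable is standardized *within* each
country (mean 0, SD 1, denominator $n-1$) before pooling.

Three processing rules matter and are fixed:

* **Complete cases first.** A country-year is dropped whenever any of the
  four variables is missing; standardization then uses each country's
  retained years only (omission changes the per-country moments, so the
  order matters). Drop counts are kept as provenance.
* **Reflection.** Lower tails of interest (yield losses, droughts) are
  turned into upper tails by negation: `YieldRefl = -Yield`,
  `PrecRefl = -Prec`. All tail machinery is one-sided as a result.
* **One quantile convention.** Empirical quantiles use linear interpolation
  (type 7) everywhere; mixed conventions would move thresholds by up to one
  order statistic and break exact reproducibility.

A `min_years` filter (default 0, i.e. only the standardization minimum of
two years) is exposed rather than hard-coded, since there is no principled
universal cut-off for short post-omission series.

## Marginal model

Each margin is modelled semi-parametrically: the empirical distribution
below a high threshold $u$, a generalized Pareto tail above it,

$$
\hat F(x) =
\begin{cases}
\tilde F(x), & x \le u,\\[2pt]
1 - \{1 - \tilde F(u)\}\,\{1 + \xi (x-u)/\beta\}_+^{-1/\xi}, & x > u,
\end{cases}
$$

with $\tilde F$ evaluated as ranks$/(n+1)$ so it never reaches 1 and the
Laplace transform below stays finite. The threshold defaults to the **80th
percentile** of each variable: mean-residual-life linearity tends to hold
well below that for these panels, but probability/quantile agreement of the
fitted tail is typically only adequate from about the 80th percentile
upward. The choice is per-variable configurable, and
`mean_residual_life()` emits the diagnostic curve machine-readably rather
than auto-selecting (automatic threshold selection is deliberately out of
scope).

GPD parameters are estimated by maximum likelihood over (log scale, shape)
with Nelder-Mead from five deterministic starts (a moment-based start plus
fixed perturbations) because tail likelihoods on a few hundred exceedances
are flat; standard errors come from the observed information. Fitted shapes
with $|\hat\xi| < 10^{-4}$ are evaluated through the exponential-limit
formulas to avoid catastrophic cancellation in $(1+\xi z)^{-1/\xi}$.

Margins are then mapped to the **standard Laplace** scale,

$$
Y = \begin{cases} \log\{2 \hat F(X)\}, & \hat F(X) < 1/2,\\
-\log\{2[1-\hat F(X)]\}, & \hat F(X) \ge 1/2,\end{cases}
$$

whose two tails are unit-rate exponential — the natural scale for one-sided
conditional tail modelling with both positive and negative dependence.
Probabilities that are numerically 0 or 1 are clamped into
$[\varepsilon, 1-\varepsilon]$, $\varepsilon = 1/(2n)$, with a counted
warning.

## Conditional dependence model

On Laplace margins, the response given a large conditioning value is
modelled by the conditional extremes (Heffernan-Tawn) form

$$
Y_{\mathrm{resp}} \mid Y_{\mathrm{cond}} = y \;=\; a\,y + y^{b} Z,
\qquad y > u_Y,\quad -1 \le a \le 1,\; b < 1,
$$

with $Z$ independent of the exceedance in the limit. The sign of $a$ is the
sign of the extremal dependence; $a = 1, b = 0$ is perfect/asymptotic
dependence, $a = 0, b = 0$ independence, and intermediate $(a, b)$ capture
asymptotically independent but sub-asymptotically associated pairs — for a
Gaussian copula with correlation $\rho$, the limit is
$a = \mathrm{sign}(\rho)\rho^2$, $b = 1/2$, which is exactly the regime
annual crop-weather panels plausibly occupy.

Estimation maximises the standard pseudo-likelihood treating $Z$ as i.i.d.
Gaussian with free location and scale. Two numerical choices:

* $(\mu, \sigma)$ are profiled out in closed form, so the search is
  two-dimensional; it runs in unconstrained coordinates
  ($a = \tanh \alpha$, $b = 1 - e^{-\gamma}$) from five deterministic
  starts (a correlation-based guess plus fixed alternatives), keeping the
  best *feasible* optimum. If every starting point is infeasible the
  deterministic defaults are appended, so a degenerate user-supplied start
  cannot strand the fit.
* The working model affects only point estimation: everything downstream
  resamples the **empirical** residuals, so no Gaussianity of $Z$ is
  assumed where it would matter (kernel smoothing of the residual
  distribution is intentionally not offered; the empirical version is the
  conservative default and one fewer tuning knob).

The dependence threshold defaults to the **90th percentile** of the
conditioning variable; `threshold_stability()` refits over the 50th-90th
candidates with bootstrap bands as supporting evidence, and
`residual_independence_diag()` checks the independence assumption on $Z$
(rank correlation with the conditioning exceedance plus binned
location/scale summaries). On the Laplace scale the regression form $y^b$
requires $y > 0$, so scan thresholds below the Laplace median are floored
at zero. Fits with numerically degenerate residual spread (perfect
dependence) report $b$ with an `b_unidentified` flag rather than a
meaningless point value.

### Joint parameter constraints

The box $[-1,1] \times (-\infty, 1)$ alone admits fits whose extrapolated
conditional quantiles beat those of *perfect* dependence — a logical
inconsistency. Following the constraint scheme of Keef, Papastathopoulos
and Tawn, a candidate $(a, b)$ is admissible only if the fitted conditional
quantile (at the 2.5%/97.5% residual levels) does not exceed the
perfect-positive-dependence bound, nor fall below the
perfect-negative-dependence bound, both **at the largest observed
conditioning exceedance and in the $y \to \infty$ limit** (the limit side
is evaluated analytically from the sign of the dominating term). The
predicate is exposed as `constraints_feasible()` and can be switched off
for comparison; the source only names the conditions, so the two-point
bound evaluation at those reference levels is this package's concrete
reading, checked in the tests against an independent numeric evaluation of
the same bounds. The profile likelihood surface with its feasibility mask
(`profile_surface()`) makes the constrained optimum inspectable.

## Extrapolation and uncertainty

Conditional loss probabilities are estimated by Monte Carlo from the fitted
model: on the Laplace scale, exceedances of the level $v_c$ of quantile
$q_c$ are $v_c + \mathrm{Exp}(1)$ — this samples the *exceedance* law, i.e.
$P(\cdot \mid \mathrm{Hazard} > q_c)$, not the law at equality — residuals
are drawn with replacement from the fitted empirical residual set, and
$y_{\mathrm{resp}} = \hat a y + y^{\hat b} z$. The default grid is the 91st
to 99.99th conditioning percentiles with **1000 simulated observations**
per level; the severe-loss level is the response's 90th percentile.
Counting exceedances on the Laplace or original scale is identical by
monotonicity of the transform (an invariant under test).

Uncertainty comes from a **full-refit paired bootstrap**: observation rows
are resampled with replacement 100 times and the entire chain — both
marginal GPDs, the transform, the dependence fit, the simulation — is
re-estimated per replicate (refitting only the dependence stage is
available behind `refit_marginals = FALSE`; full refit is the default
because it is the more conservative accounting of marginal estimation
error). Interval bounds at level $1-\alpha$ are the
$\lceil \alpha/2\, m\rceil$ and $\lceil (1-\alpha/2)\, m\rceil$ order
statistics of the $m$ successful replicates — for 100 replicates at 95%,
the 3rd and 98th. Failed replicates are excluded and counted (never
silent); more than 50% failures aborts. Seeds are derived deterministically
from one master seed per stage and per replicate, so any single replicate
is reproducible in isolation and whole runs are byte-identical.

## Headline summaries

`fragility_table()` reads each (region, crop, hazard, orientation) curve at
the **98th** conditioning percentile (for reflected low-precipitation
hazards this is the 2nd percentile of precipitation); cells whose bootstrap
interval includes zero are flagged `shown = FALSE` as carrying no evidence
of tail association. An alternative reading — the maximum over conditioning
levels rather than the value at 0.98 — is noted but not implemented: the
fixed-level version is the comparable one across cells. `worst_case()` is
the per-region maximum *upper* interval bound over all crop-hazard
combinations, with ties broken lexicographically by (crop, variable) since
a reported single worst case needs a deterministic rule.

## The synthetic generator: what it emulates, what it does not

Real FAO/CRU-derived panels are external inputs; validation instead runs on
`synthetic_spec()` / `gen_region_fixture()` panels whose truth is known:

* panel layout (10-16 countries, up to 42 years, country-specific levels
  and scales so per-country standardization is non-trivial, ~5% missing
  records, non-negative yield and precipitation, `tmax >= tmin`);
* bivariate tail dependence between yield losses and one hazard with
  configurable family, sign and strength — Gaussian copula
  (asymptotically independent; the primary recovery target because it
  exercises the sub-asymptotic regime), logistic/Gumbel copula
  (asymptotically dependent, $\chi = 2 - 2^\alpha$), independence, perfect
  dependence, and the exact conditional-model form itself; negative
  dependence is produced by reflecting one margin, mirroring the
  reflection device used for droughts;
* heavy-tailed margins (Student-t with 5 df by default) so the GPD stage
  has signal at a few hundred observations per region.

`oracle_cond_prob()` is the corresponding brute-force oracle: it estimates
the same conditional probability directly from the generative law (exact
conditional sampling for the Gaussian copula, chunked unconditional
simulation otherwise), never touching the fitted pipeline.

What the generator does **not** emulate: serial and spatial correlation of
weather, trends and technology-driven non-stationarity in yields,
informative missingness, and within-season extreme timing. Passing tests
therefore demonstrate that the estimation chain recovers known
tail-dependence structure from panels of this size and shape — not that
real crop-weather panels satisfy the model's assumptions; the threshold
stability and residual diagnostics exist precisely to interrogate those
assumptions on real data.

## Validation sizes and reproducibility

The automated checks run at sizes chosen to give the relevant statistics
room to bind while remaining desk-scale: GPD recovery on 5000 excesses
(plus 20 small-sample comparisons against a brute-force grid maximizer, to
$10^{-6}$ in log-likelihood); Kolmogorov distance of transformed margins at
$n = 2000$ against the 1% critical value; Gaussian-copula $(a, b)$ recovery
at $n = 50000$, with the error shrinking as the sample doubles up to that
size (at a fixed threshold quantile the estimator carries a small
penultimate bias, so beyond the reference size the error approaches that
floor rather than zero); oracle agreement
at $\rho \in \{0.3, 0.5, 0.7\}$ within three combined Monte-Carlo standard
deviations (the pipeline's own standard deviation taken from its bootstrap
replicates, the oracle's from $10^7$ conditional draws); interval coverage
over 200 regenerated worlds at $n_{\mathrm{boot}} = 50$; and a
byte-identity rerun of the full reference analysis on a packaged
two-region fixture at the default settings. `validate_install()` bundles a
reduced battery of the same checks as a smoke test.

## Known limitations

* The conditional model is fitted pairwise; joint conditioning on several
  hazards ($d > 2$) is out of scope.
* Threshold choice remains a judgement call supported by diagnostics; no
  automatic selector is provided.
* Percentile bootstrap intervals on 100 replicates are themselves noisy in
  the far tail ($q_c = 0.9999$), where simulated exceedances extrapolate
  well beyond the observed range — the widening intervals there are the
  honest signal of that.
* Standardization assumes within-country stationarity of level and scale
  over the panel years; strong yield trends would be read as variance,
  which dilutes (not inflates) apparent tail dependence.
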