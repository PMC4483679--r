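---
title: "Methods: temperature-mortality regression and Bayesian-network vulnerability analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temperature-mortality regression and Bayesian-network vulnerability analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tempmort)
```

This vignette is the package's own account of its methods: the models and
their assumptions, the tunable parameters and why their defaults are what
they are, what the synthetic-data generator does and does not emulate, and
the numerical and design choices made where a choice was genuinely open.

## Stage one: the per-region mortality model

Daily cardiovascular deaths $Y_t$ in one region are modelled as Poisson
with canonical log link:

$$\log E[Y_t] = \alpha + \beta\,h(T_t;\tau) + s(\mathrm{rh}_t, 3) +
s(\mathrm{time}_t, 7/\text{yr}) + \lambda\,\mathrm{DOW}_t .$$

Assumptions worth stating explicitly:

* **Poisson counts.** No overdispersion correction is applied
  (quasi-Poisson/negative-binomial variants are out of scope); at a few
  deaths per day and with the seasonal smooth absorbing slow structure,
  this is the standard starting point for this model family.
* **Hinge exposure.** Temperature enters only beyond a reference
  threshold $\tau$: the 10th percentile of daily mean temperature for the
  cold model, the 90th for heat, recomputed per region from its own
  series. The cold hinge is $\max(\tau_{low} - T, 0)$, so $\beta > 0$
  always means "risk rises as conditions become more extreme" on both
  sides.
* **Stratified lags.** Mortality responds to temperature over preceding
  days. Rather than a full distributed-lag model, the indicator is
  averaged within three lag windows — 1–3, 4–8 and 9–14 days. The cold
  model includes a hinge on each of the three windows (cold effects
  persist up to two weeks); the heat model includes only the 1–3-day
  window (heat effects are acute). The reported slope
  $\beta_{\text{total}}$ is the *sum* of the included hinge coefficients,
  interpreted as the effect of a sustained 1 °C exceedance across the
  windows; its standard error is the delta-method (here exact linear)
  combination from the coefficient covariance. The first 14 days of a
  series lack full lag history and are dropped, as are days with missing
  weather (complete-case).
* **Fixed-df smooths.** The humidity and calendar-time smooths are
  natural cubic *regression* splines with fixed degrees of freedom (3 for
  humidity; 7 per year, rounded, never below 4, for time), with interior
  knots at equally spaced quantiles and centered columns. Fixing the df
  — rather than penalized selection by GCV/REML — makes the whole model a
  plain Poisson GLM, fitted by iteratively reweighted least squares.
  Note that a *natural* spline basis reproduces linear functions exactly
  but is linear beyond its boundary knots; it does not span all cubics,
  and the package's contracts are stated (and tested) accordingly.

**Fitting.** IRLS stops when the relative deviance change falls below
$10^{-8}$ or after 100 iterations (then a convergence error carries the
deviance trace). The coefficient covariance is the inverse Fisher
information $(X^\top W X)^{-1}$, the linear predictor is clamped to
$\pm 30$ during iteration for numerical safety, and
$\mathrm{AIC} = -2\ell + 2p$. The implementation is cross-checked in the
test suite against `stats::glm` on identical designs and against a dense
grid-search likelihood maximization on small problems.

**Reported effect.** The percent change per 1 °C beyond threshold is
$(\exp(\beta_{\text{total}}) - 1) \times 100$. Where the point estimate is
negative — temperature showing no deleterious effect — the reported value
is floored at 0 and flagged, keeping the raw value available
(`percent_change_raw`). The floor matters downstream: risk labels are cut
at 1 % (cold) and 10 % (heat), boundary inclusive ("10 % or more").

**Indicator choice.** The model is fitted once per temperature indicator
(daily mean, maximum, minimum) and the indicator with minimal AIC wins;
exact ties resolve in the order mean, max, min. Under the generator's
defaults the three indicators are nearly indistinguishable — tmax/tmin are
small perturbations of tmean and, at ~5 deaths/day, count noise swamps the
difference — so the property "the generating indicator wins" is exercised
in the tests under a deliberately informative design (baseline 50
deaths/day and substantial independent day-to-day variability in the
diurnal half-range) where the comparison is about the exposure metric
itself.

## Exposure construction

Station observations are interpolated to grid-cell centroids by inverse
distance weighting, $w_i = d_i^{-p}$ with great-circle (haversine)
distances in km, and averaged (unweighted) over each region's cells.
Choices, all configurable:

* power $p = 2$ (the classic IDW exponent);
* all stations contribute — no search radius or $k$-nearest cutoff;
* a target coincident with a station returns that station's value exactly;
* grid cells default to 0.1° (0.5° in the synthetic world, where 2×2-cell
  rectangular regions keep the geometry trivial); polygons are rasterized
  by centroid-in-polygon membership (ray casting).

Because station positions are fixed, the normalized weight matrix is
precomputed once per run; days with missing station values fall back to
per-day interpolation over the stations that did report.

## Stage two: discretization and the Bayesian network

**Supervised discretization.** Continuous factors are cut against the
binary risk label by recursive entropy minimization with the minimum
description length stopping rule (Fayyad–Irani). Candidate cuts are
midpoints between adjacent distinct values whose class composition
differs; the accepted partition is invariant to strictly increasing
transformations of the factor. When MDL rejects every cut — typical when a
factor carries no signal — a single median cut is used so the network
always receives at least two states, and the fallback is flagged.
Automatic cuts follow the half-open convention (a value equal to a cut
belongs to the upper state); *manual* interval specifications, provided to
reproduce published splits verbatim, honor their printed bracket types
instead, and values outside a manual scheme's outer bounds are extended to
the nearest state with a warning.

**The network.** A discrete Bayesian network is the pair $(G, P)$: a DAG
over the 10 factors plus the risk label, and one CPT per node,
$P(x) = \prod_i P(x_i \mid pa(x_i))$. Structure is learned by simulated
annealing over single-edge moves (add/delete/reverse, drawn uniformly
among acyclicity-preserving legal moves), accepting worse candidates with
probability $\exp(\Delta/\text{temperature})$ and returning the best DAG
ever visited — the search can never end below its starting score.

Open choices, decided as follows:

* **Score: BIC** (natural-log), $\sum_i [\ell_i - \tfrac{\log n}{2}
  (r_i - 1) q_i]$. It is decomposable (edge moves rescore only the
  affected nodes, memoized per family), consistent, and the standard
  companion of annealing-style searches. No prior-based alternative
  (BDeu) is wired in by default.
* **Schedule defaults:** initial temperature 1.0, geometric cooling
  0.995, 50 moves per temperature, stop at $10^{-3}$, 20,000-iteration
  cap, mandatory seed. On the ≤11-node problems here this converges
  reliably; the tests and the acceptance script pass smaller explicit
  schedules matched to their 3-node problems, which converge in a few
  hundred moves — the schedule scales with the problem, it is not a
  tolerance.
* **CPT smoothing: Laplace (+1).** With 26 training rows, zero-count
  parent configurations are the norm; smoothing keeps every CPT row
  proper and every posterior defined. `smoothing = 0` gives MLE with
  uniform rows for unseen configurations.
* **The risk label is an ordinary node.** No edges are forced in or out;
  optional blacklists/whitelists are available (e.g. to forbid edges into
  climatic zone).
* **Inference by exact enumeration.** With at most 11 nodes of ≤3 states
  the full joint is small; marginal CPTs $P(\text{risk} \mid \text{factor})$
  and posteriors are computed from it exactly, and rows are checked to sum
  to 1 within $10^{-9}$. Whether published marginal CPTs were
  network-derived or empirical two-way frequencies is not decidable from
  their description; both are implemented (`method = "network"`, the
  default, and `method = "empirical"`).
* **Prediction ties** break toward the first-listed state of the target
  node — `low_risk` for risk nodes, the conservative call.

**Evaluation.** Two-fold cross-validation with *stratified* seeded fold
assignment (class proportions preserved to within one region; with 7–9
positives among 26 a simple random split can starve a fold). Metrics are
pd, pf and accuracy per target state, **pooled** over the two folds'
confusion matrices by default. Pooling is the aggregation consistent with
published cold-network rows on 26 instances; per-fold averaging is
available behind `aggregate = "per_fold"` because one published
heat-network cell (high-risk pf = 0.063) is inconsistent with any pooled
integer matrix on a 19/7 split and suggests per-fold averaging was used
for it. Zero-denominator metrics are reported as missing, never as 0.

## The synthetic world

The generator emulates the study conditions end to end with known truth:

* **26 regions, 4 years** (1461 days from 2008-01-01), **baseline 5
  deaths/region-day**; true heat slope 0.0953 per °C (a 10 % change) for
  high-risk regions and 0.03 for low-risk, true cold slopes 0.02 / 0;
* **40 stations** with uniform coordinates over a 20°×14° extent,
  seasonal-sinusoid temperature (annual mean 18 °C, amplitude 8 °C, daily
  noise 2 °C, fixed per-station offsets), tmax/tmin as positive
  half-ranges about tmean, humidity an opposite-phase sinusoid clipped to
  [0, 100];
* **mortality** drawn Poisson from the stage-one model itself, with the
  hinge applied to the 1–3-day lag mean — the short-lag exposure the
  analysis model uses — so the analysis model nests the truth and
  parameter-recovery simulations have a well-defined target; a
  multiplicative day-of-week pattern and a mild quadratic humidity term
  (log-rate $-2\times10^{-4}(\mathrm{rh}-70)^2$) are on by default, and an
  optional seasonal log-rate sinusoid (off by default) can be switched on
  to exercise confounder control — by default there is *no* baseline
  seasonality beyond the temperature/humidity/DOW terms, so the smooths
  face a known truth;
* **factor tables** sampled per region from a small ground-truth Bayesian
  network over the 10 factors plus cold/heat risk labels (cold risk driven
  by education and the elderly share; heat risk by hospital beds and the
  industrial share), with numeric factors emitted uniformly within
  state-specific intervals so the discretizer can recover the state
  boundaries; high/low-risk labels select each region's true slopes, so
  end-to-end label recovery is meaningful.

Reproducibility: a single master seed is forked per sub-generator through
labelled streams (`fork_seed(seed, "stations")`, `"mortality-R01"`, ...),
so enlarging the station network never perturbs the mortality draws, and
identical configurations yield byte-identical artifacts.

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real data: real climate normals or spatial
autocorrelation beyond a per-station offset; census marginals; ICD coding
and death-registration artifacts; air-pollution confounding (explicitly
unavailable in this model family's typical data); overdispersion;
reporting gaps. Recovery of the true slopes here shows the estimator is
correct under its own assumptions, not that those assumptions hold in any
particular surveillance system.

## Numerical choices and degenerate inputs

* Percentiles use linear interpolation between order statistics
  (`quantile` type 7), configurable.
* Thresholds require ≥100 non-missing days; designs require ≥30 usable
  days after exclusions; rank-deficient designs raise a collinearity
  error naming the dependent columns (inspectable via
  `check_rank = FALSE`).
* The mortality generator refuses $|\log \mu_t| > 50$, naming the largest
  contributing term.
* Day-of-week reference level is Monday; the year constant is 365.25;
  dates are ISO-8601.
* Expected problem sizes: the parameter-recovery and coverage simulations
  run 100–200 single-region replicates at the study conditions;
  structure-recovery uses 5,000-row samples of a 3-node chain over 20
  seeds; enumeration-oracle checks cover models with ≤12 total states.

## Known limitations

* With 26 regions and a few deaths per day, single-region cold estimates
  are noisy (three correlated hinge terms); labels derived from them are
  themselves noisy, and the end-to-end cross-validated accuracy on the
  synthetic world reflects that honestly — the module-level tests, which
  separate label noise from classifier behavior, are the sharper
  instrument.
* At low counts the many-parameter spline design induces a small
  downward finite-sample attenuation of hinge slopes (it vanishes as
  counts grow); the recovery simulations quantify it.
* The annealing search optimizes a score over DAGs; on equivalence
  classes the BIC cannot distinguish members, so structure recovery is
  asserted up to the Markov-equivalence class (same skeleton and
  v-structures).
* k-fold CV with k > 2, repeated CV and ROC analysis are out of scope.
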