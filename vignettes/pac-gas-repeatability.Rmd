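---
title: "Methods: repeatability and precision of PAC gas measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeatability and precision of PAC gas measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pacflux)
```

# The measurement and its model

Portable accumulation chambers (PACs) measure the gas exchange of a single
small ruminant over about 50 minutes: the animal is sealed into a chamber of
known volume and the concentrations of methane (ppm), oxygen and carbon
dioxide (both %) are read at entry, mid-way, and at the end of the run. The
concentration change, the elapsed time, and the chamber's free volume give
a volumetric flux in l/h:

$$\mathrm{flux} = \frac{C_x - C_y}{T_x - T_y} \times 60 \times
  \frac{V - \mathrm{LW}}{D},$$

with $V$ the chamber volume (853 l in the emulated design), LW the
animal's liveweight (kg, read as liters displaced, exactly as the
conversion is defined), and $D$ the concentration scale (10^6 for
ppm-scale CH4, 100 for %-scale O2 and CO2). For the produced gases the
difference runs last-minus-first; for O2, which declines inside the
chamber, the package evaluates the concentration *drop* over the elapsed
time, so consumption is reported positive. `trace_to_flux_lph()` is the
scalar reference implementation; `flux_table()` applies the identical
arithmetic to a whole trial.

Two readings determine the slope; the package uses the first and last
readings with their actual recorded times, and uses the middle reading only
for a linearity quality flag (deviation from the chord midpoint beyond
`lin_tol` times the first-to-last change, default 5%). Negative fluxes are
preserved and flagged, never clamped or dropped: no exclusion rule is part
of the protocol, and downstream variance components should see the data as
measured.

The daily mass output uses the ideal-gas extrapolation as the PAC protocol
prints it:

$$\mathrm{g/d} = \mathrm{flux}\ (\mathrm{l/h}) \times
  \frac{P \times 0.1}{8.3145\,(T + 273.15)} \times M \times 1440,$$

with $P$ in hPa, $T$ in °C, molar mass $M$ (16, 44, 32 g/mol) and 1440
min/day. Dimensionally this mixes an hourly flux with a per-minute day
length; evaluated verbatim it reproduces the protocol's published daily
values (9.19 g/d CH4, 591.40 g/d CO2 from the mean fluxes at mean ambient
conditions, to within 1–2% because the published figures were averaged
over unrounded per-record values). The package therefore implements the
formula exactly as defined and documents, rather than "fixes", the unit
inconsistency. Keep this in mind before comparing absolute g/d values with
figures derived from a dimensionally strict conversion, which would differ
by a constant factor.

# Variance decomposition

Per gas, the flux of animal $i$ on day $j$ is modelled as

$$y_{ij} = \mu + a_i + d_j + e_{ij}, \qquad
  a_i \sim N(0, \sigma^2_{\mathrm{ani}}),\;
  d_j \sim N(0, \sigma^2_{\mathrm{day}}),\;
  e_{ij} \sim N(0, \sigma^2_e),$$

a two-way crossed random-effects model: day effects (weather, feeding
schedule) shift all animals measured that day, animal effects persist
across days. Derived summaries:

* $H_{\mathrm{ani}} = \sigma^2_{\mathrm{ani}} / (\sigma^2_{\mathrm{ani}} +
  \sigma^2_{\mathrm{day}} + \sigma^2_e)$, the animal share of total
  variance;
* $\mathrm{CV} = \sigma_{\mathrm{ani}} / \mu$, the between-animal
  coefficient of variation;
* repeatability, by default $\sigma^2_{\mathrm{ani}} /
  (\sigma^2_{\mathrm{ani}} + \sigma^2_e)$.

The repeatability denominator is a genuine modelling choice. Treating the
day effect as a measurement-occasion shift common to the whole cohort —
which is what a crossed design estimates it to be — the correlation
between two measurements of the same animal on different days is
$\sigma^2_{\mathrm{ani}} / (\sigma^2_{\mathrm{ani}} + \sigma^2_e)$, and
that is the default. The more conservative convention that counts day
variance as noise is available via
`derive_summaries(vc, repeatability_denominator = "total")`. The
repeatability analysis itself follows the protocol's model: liveweight and
humidity as fixed covariates (humidity as a continuous covariate), animal
and day random; `repeatability_by_window()` re-fits it on days $1..n$
(prefix windows of consecutive days).

## Estimation

Two estimators are provided deliberately:

* `fit_anova_balanced()`, the closed-form expected-mean-squares
  (Henderson method) estimator for the complete balanced layout with one
  record per animal-day: $\hat\sigma^2_e = MS_E$,
  $\hat\sigma^2_{\mathrm{ani}} = (MS_A - MS_E)/n_{\mathrm{days}}$,
  $\hat\sigma^2_{\mathrm{day}} = (MS_D - MS_E)/n_{\mathrm{animals}}$,
  negatives truncated to zero and flagged.
* `fit_reml()`, restricted maximum likelihood, which also handles missing
  cells and fixed covariates. The fit is obtained from `lme4::lmer` and
  then polished on an independently coded restricted log-likelihood
  evaluated through Henderson's mixed-model equations (BFGS on the log
  scale followed by Newton steps until the gradient is below 1e-9), so
  that reported optima are tight. On balanced data with interior estimates
  the two estimators coincide; the package tests hold them to 1e-6
  relative agreement, which is the practical resolution of the likelihood
  surface away from the boundary — components estimated at less than about
  2% of the total variance sit on likelihood plateaus where tighter
  parameter agreement is not numerically meaningful.

Standard errors come from the observed information: the numeric Hessian of
the restricted log-likelihood at the optimum, computed in relative
coordinates (multiples of the estimates) so that finite-difference steps
respect each component's scale — methane variances are of order $10^{-6}$
(l/h)$^2$ while oxygen's are of order $10^{-3}$. Components on the zero
boundary are flagged and get `NA` standard errors; the quadratic
approximation is invalid there.

Restricted log-likelihoods are always re-evaluated on the package's own
fixed convention (`reml_loglik()`, with the $(n-p)\log 2\pi$ constant), so
nested fits are comparable regardless of backend. `lrt_nested()` compares
models sharing fixed effects whose random sets are nested; because the
dropped variances lie on the parameter-space boundary under the null, the
p-value uses the $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ mixture for one
dropped component and $\tfrac14\chi^2_0 + \tfrac12\chi^2_1 +
\tfrac14\chi^2_2$ for two. Simulation in the test suite confirms the
type-I error is close to nominal at the sizes used.

# Precision by number of days

The 95% confidence-interval range of an $n$-day average is

$$P_n = 1.96\sqrt{\sigma^2_e / n},$$

strictly decreasing in $n$ with the inverse-square law $P_{4n} = P_n/2$.
`precision_curve()` reports both $P_n$ and the half range $P_n/2$: the
published per-gas precision values are quoted under *both* conventions
(the oxygen and CO2 seven-day values, 0.05 and 0.03 l/h, equal the full
range from the printed error variances, while the methane values, 0.0010
l/h at seven days and 0.0019 at two, equal the half range). Rather than
silently choosing one reading of the "±", both are surfaced and the
inconsistency is left visible. `days_for_precision()` inverts the curve:
the smallest $n$ with $P_n \le$ target, i.e.
$\lceil 1.96^2 \sigma^2_e / \mathrm{target}^2 \rceil$, guarded against
floating-point edge effects at the ceiling boundary.

# Ranking consistency across days

`day_correlation_matrix()` reshapes one gas to animals × days and
computes pairwise-complete Pearson correlations (Spearman optionally, as a
robustness check), day-on-day regression slopes with their standard
errors, and $R^2 = r^2$. Under the additive model the expected inter-day
correlation is the intraclass correlation
$\sigma^2_{\mathrm{ani}} / (\sigma^2_{\mathrm{ani}} + \sigma^2_e)$ — day
effects shift all animals equally and cancel from a between-animal
correlation — and the test suite verifies the empirical mean off-diagonal
correlation against this value by simulation.

`ranking_consistency()` ranks animals by flux within each day (ascending)
and accumulates bottom-$k$ / top-$k$ membership per animal across days
(default $k = 10$). Ties at the $k$-th boundary are broken by stable
animal-id order and the affected days flagged. Fractions of days are also
reported rounded to the nearest integer percent, the convention in which
such persistence figures are usually quoted (13 of 17 days reads as 76%).

# The prediction equation and its validation

The prediction model regresses a gas flux on date (class), measurement
group (class), breed (class), age, liveweight, relative humidity,
temperature and pressure (covariates), with a random animal intercept.
Evaluation is 4-fold cross-validation stratified by animal and date:
each animal's records, in date order, are spread across folds with a
seeded assignment whose remainders go to the currently smallest folds, so
fold sizes differ by at most one and nearly every animal appears in
several folds. Variance components are re-estimated on every training
fold — fixing them globally would leak held-out information. Held-out
records are predicted as fixed effects plus the animal's BLUP when the
animal was seen in training, fixed effects alone otherwise; held-out class
levels unseen in training are predicted at the reference level and flagged
per record. If the training response is degenerate (zero residual
variance, where the REML fit is undefined), the animal effect is fitted as
fixed — the no-shrinkage limit of the mixed model — so that noise-free
data are predicted exactly.

Reported metrics: per-fold and pooled $r^2$ (squared Pearson correlation
of predicted vs actual on held-out records), RMSE, fold means, and the
mean bias (predicted − actual). The bias is surfaced deliberately:
published evaluations of such equations have reported predicted means far
from the actual means, and a mean-bias diagnostic makes any scale
discrepancy visible instead of burying it in $r^2$, which is insensitive
to calibration.

# The synthetic trial generator

`simulate_trial()` emulates the design the analysis targets: 48 ewe lambs
× 17 consecutive days, 4 runs/day over 12 chambers of 853 l, readings at
0/25/50 min. Its defaults are the study conditions: published mean fluxes
(0.0094, 0.3582, 0.2194 l/h for CH4, O2, CO2), published per-gas variance
components, liveweight 46 ± 4.0 kg, ambient conditions 8.33 ± 2.45 °C,
1000.05 ± 15.79 hPa, 76.68 ± 8.66% RH. Choices the emulated design leaves
open, fixed once here:

* **Ambient baselines** (CH4 2.0 ppm, O2 20.9%, CO2 0.04%): typical
  outdoor air. Only concentration *differences* enter the flux equations,
  so baselines cannot affect downstream statistics.
* **Linear accumulation**: the mid reading sits on the chord between the
  first and last readings. The flux equations are two-point differences,
  so linearity is the minimal model consistent with them; it also makes
  trace construction exactly invertible, which the round-trip tests
  exploit (traces → `flux_table()` recovers the generating fluxes to
  below 1e-10 l/h).
* **Reading noise** defaults to 0 — the instrument's reading-level
  precision is not reported — and is opt-in per gas (`reading_noise`), as
  is uniform jitter of the recorded times (`time_jitter`, e.g. ±2 min).
* **Liveweight constant within the trial**, drawn once per animal: the
  emulated study reports a single mean ± SD.
* **Independence across gases** of the random effects: each gas is
  modelled separately downstream, so no cross-gas correlation is imposed.
* **Breed and age** are labels only (three breed labels, ages uniform in
  10–11 months); they carry no effect on simulated fluxes, which makes
  them useful null covariates for the prediction model.
* **Seeding**: one master seed, from which each stochastic component
  (animal attributes, animal/day/residual effects per gas, environment,
  chamber allocation, jitter/noise) derives its own fixed sub-seed.
  Identical inputs give identical trials, and enabling one noise source
  does not perturb the draws of the others.

Records whose implied readings would be physically impossible (negative,
or a percentage outside 0–100) abort the simulation with a diagnostic
naming the record. This is not rare at the full methane defaults: the
published methane variance components give a flux standard deviation of
about 0.0035 l/h against a mean of 0.0094, so a Gaussian model produces
occasional negative methane fluxes large enough to drive the 50-min trace
below zero (roughly one record in 1,400, hence a substantial fraction of
full-size trials contain at least one). Single-gas simulations
(`gases = "O2"`) are the natural tool for replicate studies of one trait;
for methane-inclusive trials, seeds that imply an impossible record simply
fail fast rather than silently censoring the tail, which would distort
the variance structure being studied.

What the generator does **not** emulate: within-chamber mixing dynamics,
chamber leakage, diurnal emission cycles, feed-intake effects, or any
skewness/heteroscedasticity of real emission data. Passing tests
demonstrate that the estimators recover the parameters of the additive
Gaussian model — they cannot certify behaviour under real-data features
the generator omits.

# Problem sizes and tolerances used in the checks

The test suite and the acceptance script size their simulations to keep
Monte-Carlo error well inside the tolerance being asserted: 500 replicate
default-size trials for ANOVA unbiasedness (5% relative), 200 for
REML recovery of the oxygen animal share (1 percentage point; the
estimator's mean at this design size is about 32.0% against a generating
31.8%, a small ratio bias inherent to plugging variance estimates into a
share), 600 replicates in the acceptance script (Monte-Carlo standard
error ≈ 0.26 points), 300 replicates for the intraclass-correlation check
(±0.02), 150 for the boundary LRT type-I rate, and 10,000 random cases
for the precision-curve brute-force comparison. Smaller layouts (12–24
animals, 6–10 days) are used where the property under test does not
depend on the full design size.

# Worked example

```{r example, eval = FALSE}
params <- sim_params(seed = 2)
trial <- simulate_trial(params, trial_design())
flux <- flux_table(trial)

vc <- fit_reml(flux, model_spec("O2"))
vc
precision_curve(vc$sigma2[["error"]], 17, gas = "O2")[c(1, 3, 7, 17), ]
ranking_consistency(flux, "CH4", k = 10)
cross_validate(flux, prediction_spec("O2", n_folds = 4, seed = 2))
```

The numbered scripts under `analysis/` run these stages over the default
trial and write every table under `results/`; `run_pipeline()` does the
same in one call from a YAML configuration.

# Known limitations

* The g/d extrapolation is faithful to the protocol, including its unit
  inconsistency (see above).
* Repeatability depends on the denominator convention; both are exposed,
  and comparisons across studies should check which one was used.
* Variance-component standard errors are asymptotic (observed
  information); for 17 days the day-variance SE is optimistic.
* The prediction equation inherits the limits of its covariates: without
  feed-intake data its ceiling is the animal repeatability, and on
  synthetic data its $r^2$ mainly reflects the generating animal and day
  variances, not any biological regression structure.
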