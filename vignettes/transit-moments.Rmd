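---
title: "Statistical-moment analysis of biomagnetic gastrointestinal transit"
author: "acbtransit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical-moment analysis of biomagnetic gastrointestinal transit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acbtransit)
```

## The measurement and the estimands

AC biosusceptometry (ACB) tracks a magnetically marked meal through the rat
gut noninvasively: a gradiometric coil sensor placed on the abdominal
surface reads a voltage proportional to the amount of magnetic tracer near
it, falling off steeply with distance. Recording the signal alternately at
the gastric and the cecal projection every 10 minutes for at least 7 hours
yields two time series per animal and meal: a decaying gastric curve
(emptying) and a sigmoidal cumulative cecal curve (arrival).

Three transit times summarize these curves by their first statistical
moments:

* **MGET**, mean gastric emptying time: the mean of the emptying-rate
  distribution. With the gastric signal normalized to a retention fraction
  $R(t)$ ($R(0) = 1$, $R \to 0$), integration by parts gives
  $\mathrm{MGET} = \int_0^\infty R(t)\,dt$ — the area under the emptying
  curve.
* **MCAT**, mean cecum arrival time: the mean of the arrival-rate
  distribution. With the cumulative cecal curve normalized by its plateau,
  $C(t) \in [0, 1]$, $\mathrm{MCAT} = \int_0^\infty (1 - C(t))\,dt$ — the
  area between the arrival curve and its maximal cumulative value.
* **MSITT**, mean small-intestinal transit time:
  $\mathrm{MCAT} - \mathrm{MGET}$, by definition and always exactly in
  this package.

Moments use the entire curve rather than a single landmark. The classical
half-emptying time $t_{50}$ (first crossing of $R = 0.5$, provided by
`t50()`) is faithful only under pure-exponential emptying; solid meals
show a lag phase that $t_{50}$ misrepresents but the moment integrates
correctly.

## Normalization and its defaults

The raw signals are in mV with an arbitrary gain, so both curves are
normalized affinely; all transit times are invariant under positive affine
transforms of the raw signal once the baseline is right.

* **Gastric baseline.** `normalize_gastric()` defaults to the *tail*
  estimate — the mean of the last 3 samples — on the grounds that a
  protocol recording for at least 7 h ends with an essentially empty
  stomach. This is the robust choice for field recordings whose
  electronics have an unknown offset. For simulated recordings, whose
  sensor model is offset-free by construction, the tail estimate would
  subtract a fraction of the genuine residual signal and bias MGET
  downward; analyses of simulated data in this package therefore use
  `baseline_mode = "zero"`. Both modes accept an explicit numeric
  baseline.
* **Cecal baseline.** Mean of the first 2 samples (no tracer can have
  reached the cecum within minutes of ingestion); the curve is then
  scaled by its maximal cumulative value $C_{\max}$ so the plateau is 1.
* **Clipping and flags.** Retention below 0 is integrated as 0 (unbiased
  under zero-mean noise); values below $-0.1$ indicate a wrong baseline
  and raise a quality warning. Noise can make the cecal curve locally
  non-monotone; optional isotonic (pool-adjacent-violators) smoothing via
  `smooth = TRUE` enforces monotonicity, but the default integrates the
  raw clipped curve, which is unbiased and keeps the estimator simple.
* **Time origin.** $t = 0$ is meal ingestion, when the tracer is entirely
  gastric, so $R \equiv 1$ and $C \equiv 0$ on $[0, t_\text{first}]$.
  Curves are never shifted; a record whose first reading is at 5–10 min
  contributes that leading segment analytically.

## Numerical choices in the moment estimators

Integration is trapezoidal on the native sampling grid — the estimator the
10-min protocol actually supports; no resampling or curve fitting is
imposed on the data. On a uniform grid with complete emptying the area
form equals the rate-weighted mean
$\sum_i t_{\text{mid},i}\,(R_i - R_{i+1}) / (R_0 - R_\text{end})$ exactly
(an algebraic identity for piecewise-linear curves, verified by a property
test), so "area under the curve" and "temporal average weighted by the
intensity curve" are the same computation.

Truncated records are a real hazard for moment estimators, which weight
the tail heavily:

* If the final retention exceeds `plateau_epsilon` (default 0.02, i.e.
  98% emptied), `tail_policy = "truncate_warn"` (default) integrates the
  record as-is and warns that MGET is underestimated;
  `"exponential_extrapolate"` fits a mono-exponential to the last 5
  samples and adds its analytic area out to 5 time constants — a
  convenience for records cut short, not a model claim.
* If the final arrival fraction is below $1 - $`plateau_epsilon`, the
  plateau was not reached: MCAT is right-censored (truncation can only
  decrease it — also a property test) and the result is flagged.

These flags propagate into the `warnings` column of the results table,
the way a physiologist would annotate a questionable recording.

## The forward simulator

No public archive of raw ACB transit recordings exists, so the package
carries its own generative model, chosen so that every estimator can be
tested against closed forms.

The gut is a linear chain: a stomach emptying into $N$ identical
small-intestinal compartments (transfer rate $k_t$) draining into the
cecum. Emptying is first-order with rate $k_e$ for liquid meals
(retention $e^{-k_e t}$) and power-exponential for solid meals
(retention $e^{-(kt)^\beta}$, hazard $\beta k (kt)^{\beta-1}$, zero at
$t = 0$ for $\beta > 1$ — the lag phase of a solid meal). The analytic
moments come free: mean gastric residence is $1/k_e$ (liquid) or
$\Gamma(1 + 1/\beta)/k$ (solid), the chain adds $N/k_t$, and MCAT is
their sum, by additivity of mean residence times in a linear chain.

The presets `liquid_like()` ($1/k_e = 100$ min) and `solid_like()`
($\beta = 2$, $\Gamma(1.5)/k = 140$ min; $N = 4$, $k_t = 0.05$/min so
the small-intestinal mean is 80 min) echo the reference liquid and solid
group means — echoes for realism, not claims about any animal.

The system is integrated by fixed-step classical Runge–Kutta (deSolve,
step 0.1 min); being linear and mass-conserving, the scheme holds total
mass to machine precision and the liquid stomach trajectory to within
$10^{-6}$ of the closed form at this step size.

The sensor maps mass to mV as
$S = \kappa\, m\, (d^{-p} - (d + L)^{-p})$: linear in the amount of
magnetic material, power-law in the sensor-to-organ distance $d$, with
the far coil pair of the first-order gradiometer (baseline $L = 15$ cm)
subtracted. The falloff exponent defaults to $p = 6$ (excitation
$\propto d^{-3}$ times detection $\propto d^{-3}$); deriving the true
response would require full coil modelling, so $p$ is a parameter, not a
claim. Defaults $d = 2$ cm and $\kappa = 1000$ put a full stomach near
15 mV, a plausible scale for a small-animal sensor. By default each
sensor sees only its own organ; a crosstalk matrix of
compartment-to-site distances can make either site see any compartment.
Measurement noise is additive Gaussian with SD equal to
`sigma_fraction` (default 0.02) of the peak noiseless stomach signal,
from a single seeded generator per simulation call.

Recordings are sampled from $t = 0$ (at ingestion the tracer is entirely
gastric, so the first reading is well defined) every `dt_sample_min`
(10 min) for `duration_min` (default 420 min, the 7-h protocol). Where
an experiment in this package needs the tails essentially complete — the
noiseless oracle comparison — it simulates 700 min, the grid on which the
sampled exponential's area matches $1/k_e$ to well under 1%; at 420 min
about 2–4% of tracer has not yet reached the cecum and the plateau
renormalization alone biases MCAT by several percent, which is a
truncation property of the estimand, not an implementation artifact.

## The simulated kill-and-measure validation study

The classical invasive measure of transit has animals killed at fixed
times after ingesting the marker, and the distance the marker front
traveled along the excised small intestine measured. The simulator's
counterpart (`simulate_validation_study()`) draws one animal per record
(6 kill times × 3 animals = 18), gives each a lognormal transit "tempo"
(mean 1, CV 15%) rescaling all its rates, reads the gastric signal once
at the kill time, and takes the front as the most distal compartment
holding at least 1% of the meal, mapped to $j/N \times 100$ cm.

Two defaults differ from the transit-recording presets, both fixed at
design time:

* the chain has $N = 10$ compartments with $k_t = 0.125$/min (the
  small-intestinal mean stays 80 min) so the front is resolved to 10 cm —
  with $N = 4$ the front rule quantizes to quarters of the intestine and
  the early kill times are uninformative;
* the single-reading noise is `sigma_fraction = 0.01`. Over 10–60 min a
  lagged solid meal empties only ~13% of its load, so the signal decrease
  spans a small range; 1% single-reading noise puts the decrease–distance
  correlation robustly in the strong-linearity regime this experiment is
  meant to emulate, across seeds.

`validation_correlation()` then computes the Pearson correlation between
the decrease in gastric intensity (nominal full-stomach signal minus the
observed reading) and the front distance.

## The statistical layer

Group results are mean ± sample SD ($n - 1$). Liquid and solid meals are
measured in the same animal, so regimes are compared by the paired
Student t test, two-sided (no direction is pre-specified). The t
distribution is evaluated in-house through the regularized incomplete
beta function with a continued-fraction (modified Lentz) expansion, so
the package's p-values do not depend on the host's statistical runtime;
`stats::pt` serves as an independent oracle in the tests, where the two
agree to $10^{-6}$. Session-to-session repeatability is expressed as the
coefficient of variation, $100\,\mathrm{sd}/\mathrm{mean}$. Three paired
comparisons are reported without multiplicity adjustment, mirroring the
source analysis.

## The reference table and its two honest discrepancies

`gi_table1()` ships the published per-rat transit times (6 rats × 2
meals) with the printed integer Mean and SD rows, and `table1_report()`
recomputes everything from the per-rat integers. Rounding for this
report is half-away-from-zero to integer minutes and is applied only
here, never inside the estimators. Two things deliberately do **not**
reproduce, and the report says so rather than forcing them:

* **Rat 5, liquid meal:** the printed triple (MGET 92, MCAT 231, MSITT
  138) violates the defining identity by 1 min (231 − 92 = 139). This is
  what printing independently rounded values does (e.g. 230.9 − 92.4 =
  138.5 rounds to exactly that triple). The fixture keeps the cell as
  printed; the report shows the residual and accepts it only within the
  1-min printed precision. The other 11 cells satisfy the identity
  exactly.
* **p-values:** from the printed integers the paired MGET test gives
  $t = 2.469$, $p = 0.057$ (and MCAT $t = 1.850$, $p = 0.12$), whereas
  the source, computing on unrounded data, reported $p < 0.04$. The
  unrounded data are not printed, so that figure is not desk-reproducible;
  the report prints the recomputed values alongside a note.

## Problem sizes used by the shipped experiments

The test-suite and acceptance experiments run at sizes chosen to make the
statistical claims meaningful while staying quick on a single core:
noiseless oracle comparisons on one 700-min recording; parameter recovery
over 20 seeded 420-min recordings at 2% noise (median relative MGET error
is the statistic); the validation study at its design size of 18 animals;
and the liquid-vs-solid direction check over 20 seeded 6-animal paired
cohorts.

## Limitations

The generative model is a stand-in, not a validated digital twin. It
omits, among other things: baseline drift and sensor repositioning error
between readings (noise is i.i.d. Gaussian); gastric signal spread and
the scanning step that locates the point of maximal intensity (the
sensor is assumed already at the correct projection); physiological
features such as duodenogastric reflux, discrete antral ejection, phase-2
variability of the migrating motor complex; and any 3-D coil geometry
(the power-law response is a parameterization). Passing tests on this
synthetic data shows the estimators are correct for curves of the kind
the protocol produces — complete monotone-in-mean decays and sigmoids
with mild noise — not that every real recording will be as well behaved;
the quality flags exist precisely because real ones sometimes are not.
The printed reference table's group statistics are reproduced from its
integers; its underlying raw curves were never published, so curve-level
agreement with the original animals is not testable.
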