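# acbtransit

Statistical-moment analysis of gastrointestinal transit from AC
biosusceptometry (ACB) recordings in small animals.

ACB follows a magnetically marked meal through the gut with a coil sensor
held on the abdominal surface: the gastric-projection signal decays as the
stomach empties, and the cecal-projection signal rises as the meal
arrives. From these two intensity time series (mV, sampled every 10 min
for ≥ 7 h) the package estimates, per animal and meal:

- **MGET** — mean gastric emptying time, the first moment of the
  emptying-rate distribution: with the gastric signal normalized to a
  retention fraction R(t) (R(0) = 1), `MGET = ∫ R(t) dt`;
- **MCAT** — mean cecum arrival time: with the cumulative cecal curve
  normalized by its plateau, `MCAT = ∫ (1 − C(t)) dt`;
- **MSITT** — mean small-intestinal transit time, `MCAT − MGET`;
- **t50** — the classical half-emptying time, for comparison with MGET.

It is aimed at GI-motility labs using biomagnetic (or any two-site
tracer-intensity) recordings — e.g. for drug or medicinal-plant transit
studies — and at anyone who needs a tested reference implementation of
moment-based transit analysis. Because no raw ACB recordings are publicly
deposited, the package also ships a compartmental forward simulator
(first-order emptying for liquid meals, power-exponential lagged emptying
for solids, a chain of small-intestinal compartments, and a gradiometric
sensor response `κ·m·(d⁻ᵖ − (d+L)⁻ᵖ)`) whose moments are analytic, so
every estimator is testable against closed forms; plus the paired
small-sample statistics used to compare meals, and a reproduction report
for the published 6-rat liquid/solid transit-time table.

## Worked example

Simulate one liquid-meal recording (420 min at 10-min intervals, 2%
noise), analyze it, and compare a cohort of 6 animals across meals:

```r
library(acbtransit)

rec <- simulate_recording(liquid_like(), noise = noise_params(seed = 11),
                          animal_id = "rat01")
analyze_recording(rec$stomach, rec$cecum, gastric_baseline = "zero")
#> <transit_times> animal=rat01 meal=liquid
#>   MGET     97.14 min
#>   MCAT    176.32 min
#>   MSITT    79.18 min
#>   t50      72.47 min
#>   warnings: incomplete emptying: final retention 0.033 > 0.020; MGET is
#>   underestimated; arrival plateau not reached (final fraction 0.947);
#>   MCAT is right-censored
```

The generating model has MGET = 100 min and MCAT = 180 min; the estimates
land within a few percent, and the flags are honest: a 7-h record of this
animal still holds ~3% of the meal in the stomach, so both moments are
slightly truncation-biased (record longer, or use
`moment_config("exponential_extrapolate")`, to close the gap).

```r
pr <- run_pipeline(n_animals = 6, seed = 1)   # paired liquid + solid cohort
pr$group_summaries$liquid$mget
#> n = 6, mean = 95.11, sd = 13.57
pr$group_summaries$solid$mget
#> n = 6, mean = 141.7, sd = 26.08
pr$paired_tests$mget
#> Paired t test: t = 8.557, df = 5, two-sided p = 0.000359 (mean difference 46.58, n = 6)
```

Solid meals empty markedly slower than liquid ones in the same animals —
the qualitative effect the method exists to detect.

The published reference table reproduces from its printed integers:

```r
table1_report()$ok
#> [1] TRUE
```

(one printed cell is internally inconsistent by 1 min — a rounding
artifact the report documents rather than hides; see the vignette).

A command-line front end with `simulate`, `analyze`, `validate` and
`table1` subcommands is installed at
`system.file("cli/acbtransit.R", package = "acbtransit")`.

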