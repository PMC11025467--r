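---
title: "Methods: stem CO2 efflux, zero-growth partitioning and drought quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stem CO2 efflux, zero-growth partitioning and drought quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(stemflux)
```

## The measurement problem

Stem CO₂ efflux (Rs) is the standard field proxy for woody-tissue
respiration: a closed chamber is clamped around a stem segment, and the rate
at which CO₂ accumulates inside gives the efflux of the enclosed surface.
In drought studies the interesting signal is not the efflux itself but its
departure from the efflux *expected* at the measured stem temperature, since
temperature alone drives most of the seasonal variation. `stemflux`
implements that full chain: flux estimation, temperature normalization,
dendrometer-based growth and water-status tracking, and the reference-year
regression residual analysis that isolates the drought effect.

## Chamber flux model

The chamber is a closed, recirculating system of volume $V_1$ at pressure
$P$ and air temperature $T$. With the 1-Hz concentration trace $c(t)$ in
µmol mol⁻¹, efflux per enclosed wood volume $V_2$ is

$$R_s = \frac{P \, V_1}{R \, T \, V_2} \cdot \frac{\partial c}{\partial t}
\quad [\mu mol\; m^{-3} s^{-1}],$$

with $R = 8.314$ J mol⁻¹ K⁻¹. The slope is fitted by ordinary least squares
over the ~60 s trace; `fit_trace_slope()` reports the slope standard error
and R², flags fits with R² below a configurable threshold (default 0.9) as
`low_r2`, and flags negative slopes (`negative_slope`) which are excluded
from downstream regressions but never silently dropped. An optional
*deadband* discards the first k seconds after chamber closure (default 0:
the measurement protocol modelled here reports no closure artefacts).

Segment geometry uses two orthogonal calliper diameters: volume as an
elliptical cylinder $\pi (d_1/2)(d_2/2) L$ and lateral surface as the
mean-diameter cylinder $\pi \bar d L$. At field eccentricities
($d_1/d_2 \lesssim 1.3$) the mean-diameter surface is within 1 % of the
elliptic perimeter, and for circular segments it preserves the exact
identity $A/V_2 = 4/d$, which links the per-volume and per-surface efflux
ranges (e.g. 6 µmol m⁻³ s⁻¹ on a 4 cm stem ⇔ 0.06 µmol m⁻² s⁻¹). End faces
are excluded: the chamber collar seals them.

## Q10 normalization

Within a campaign the plots are visited in sequence over ~4 h, so stem
temperature $T_s$ drifts between plots. Efflux is therefore normalized to a
reference temperature:

$$R_{ref} = R_s \cdot Q_{10}^{(T_{ref} - T_s)/10}.$$

Two conventions circulate for the exponent sign; the one adopted here
scales warmer-than-reference measurements *down*, which is what
"normalization" must do (a measurement taken 10 °C above the reference with
$Q_{10}=2$ is halved). The opposite, literal printed convention found in
parts of the literature is available via `literal_exponent = TRUE` for
exact reproduction of analyses that used it. The reference temperature
defaults to 15 °C — the convention behind the R15 statistic — and $Q_{10}$
defaults to 2, the mean reported for oak species; both are arguments, not
constants. Normalization is exactly invertible:
`normalize_q10(normalize_q10(x, ts), t_ref = ts)` returns `x` to machine
precision.

## Zero-growth partitioning

Band dendrometers record irreversible growth superimposed on reversible
water-driven shrinking and swelling. The zero-growth decomposition assumes
growth occurs only when the diameter exceeds its preceding maximum $M(t)$:

$$GRO(t) = M(t) - D(t_0), \qquad TWD(t) = M(t) - D(t),$$

so $D(t) = D(t_0) + GRO(t) - TWD(t)$ holds identically, $GRO$ is
non-decreasing and $TWD \ge 0$. Both start at zero by definition (the
running maximum begins at the first observation). Numerically the identity
is *bit-exact* for physically possible series: all diameters lie within a
factor two of each other, so the floating-point subtractions involved are
exact (Sterbenz), a property the test suite asserts on a thousand random
walks.

Choices the decomposition needed that its verbal description leaves open:

* **Gaps.** The running maximum carries across data gaps — a stem does not
  reset because a logger failed — but the first observation after a gap
  longer than `gap_hours` (default 6 h) is flagged and its day's increment
  is reported as missing rather than spanning the hole.
* **Days.** Daily increment is last-observation-of-day differencing on
  local calendar days; at 1-h resolution this differs from midnight
  interpolation by at most one hour of growth.
* **Smoothing.** The 7-day moving average is *centered* (a trailing option
  exists); a window reports a value only when it holds at least
  `min_periods = 4` non-missing days, otherwise missingness would silently
  shrink the averaging basis at series edges and around gaps.
* **Sensor jumps.** Hour-to-hour changes beyond 500 µm are flagged, never
  auto-corrected.

Cumulative TWD (`cumulative_twd()`) sums daily TWD maxima from a chosen
start date (July in the seasonal comparisons), treating missing days as
zero contribution.

## Micrometeorological derivations

VPD uses the Magnus form with coefficients 0.6108 kPa, 17.2694 and a
denominator of exactly $237.3 + T_a$. The coefficient set yields kPa; the
package reports hPa by default (`units = "kpa"` gives the raw value)
because hPa is the unit hourly forest micrometeorology is conventionally
reported in. Inputs are validated to $RH \in [0, 100]$ and
$T_a > -237.3$ °C.

Deep (25 cm) soil water content lost to a probe malfunction is
reconstructed from a shallow co-sensor by per-treatment OLS calibration
(`fit_swc_calibration()`), with pairs matched to the nearest timestamp
within ±30 min and predictions clipped to the physical [0, 100] % range;
filled values carry an explicit flag. Gaps are represented as missing
values throughout — no interpolation happens inside micromet series.

## Drought quantification

All regressions consume campaign/plot means (`campaign_plot_means()`): each
point is the mean over the sprouts measured on one plot on one date, which
is the replication level at which treatment inference is meaningful.

The reference (wet) year yields per-species efflux–temperature fits. Both a
linear fit and a log-linear exponential fit are reported; the exponential
R² is recomputed on the *original* scale so the two models are comparable
on the same criterion. Drought-year points are then scored against the
linear reference: residual $r = R_s - \hat R_s(T_s)$ and percent of
expected $100 \cdot R_s / \hat R_s(T_s)$, summarised as mean ± SD across
the four plots per date and species. Points whose predicted efflux is
non-positive — possible below the x-intercept of a steep linear fit,
roughly 11.7 °C with field-typical coefficients — cannot define a percent;
they are excluded with a warning and counted. Per point,
$r = \hat R_s (p/100 - 1)$ exactly. The package deliberately reports the
full per-date distribution rather than a single "drought decreased efflux
by X–Y %" range: such ranges depend on an aggregation choice (dates ×
species × plots) that should remain with the analyst.

The species comparison of R15 against mean increment rate is a single OLS
with a species indicator and interaction — mathematically the classical
ANCOVA — giving the intercept difference (maintenance respiration at zero
increment) and slope difference (growth–respiration coupling) with
two-sided t-tests. `ratio_at_rate()` expresses R15 at a given increment
rate as a percentage of the zero-increment R15 (100 % at rate 0 by
construction). Increment rates are in µm day⁻¹ throughout. Pearson
correlations of R15 with sprout diameter and with the 7-day increment
average are computed within species and date, so the between-species
size/flux contrast cannot masquerade as a diameter effect. Two-sided
p-values are used throughout and no multiple-testing correction is applied,
matching the inferential conventions of the field design emulated here.
Mixed-effects models (random sprout and measurement-day effects) are out of
scope by design: the pipeline exports the analysis-ready long table
(`mixedmodel_input.csv`) they would consume.

## The synthetic scenario generator

`scenario_config()` fixes the study conditions the tests assume; every
default is an argument. The generator emulates:

* **Design.** Four treatment plots (control/thinned × ambient/30 %
  throughfall reduction), 2 species × 6 sprouts per plot, one wet and one
  drought season, with 6 and 4 chamber campaigns respectively; plots are
  visited in a fixed morning order, so each plot sees a different stem
  temperature.
* **Micrometeorology.** Hourly air temperature as seasonal + diel
  sinusoids with AR(1) day-level weather noise (afternoon maximum,
  midsummer campaign-window temperatures ~21–25 °C, May/October ~14 °C);
  humidity anticorrelated with temperature; precipitation as a marked
  Bernoulli process; deep SWC from a bucket model (precipitation refill,
  VPD-proportional drawdown toward a residual minimum). The drought year
  gets a warmer, rainless mid-June–August window during which summer SWC
  falls below 10 %, and the wet year's deep probe is withheld before 10
  July to exercise the shallow-sensor calibration path.
* **Growth and water status.** The seasonal growth rate is the sum of two
  Gaussian pulses in day-of-year (centres ~160 and ~240) — the simplest
  shape producing the double-peaked increment course of such stands —
  scaled to a wet-year annual increment of ~7.1 mm (oak) and ~6.3 mm
  (hornbeam) and halved in the drought year. Diel shrinkage follows daily
  mean VPD (zero at midnight, peaking midday; oak amplitude larger than
  hornbeam), and a sustained shrinkage term tracks soil water depletion.
  Growth carries across winters; observation noise is 2 µm.
* **Fluxes.** Campaign true fluxes follow the per-species linear
  temperature relations (slopes 23.3 and 30.5, intercepts −271.5 and
  −374.2 µmol m⁻³ s⁻¹), multiplied by the suppression factor f (default
  0.3) inside the drought window, by lognormal plot × date (sdlog 0.12)
  and sprout (sdlog 0.25) factors with mean 1, and by a small
  per-measurement factor (sdlog 0.08). The paper-style designs this
  emulates publish no within-plot variance components, so these sdlogs are
  order-of-magnitude realism choices, fixed once; they produce
  plot-to-plot percent SDs of roughly 5–30 points. Traces are generated as
  the exact inverse of the chamber equation with 0.5 ppm noise, so
  `compute_flux()` on a noise-free trace returns the true flux to machine
  precision.

Ground truth (true fluxes, true annual growth, imposed suppression) is
recorded beside the data and consumed only by tests, never by the pipeline.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: chamber leaks and non-steady-state diffusion,
corticular photosynthesis and sap-flow CO₂ transport, dendrometer
temperature sensitivity and bark swelling, spatial SWC heterogeneity, and
any mechanistic soil–plant water transport. The generator validates the
*estimators*, not the field protocol.

## Numerical and engineering choices

* Seeds: every generator draws under `withr::with_seed` from offsets of the
  scenario seed, so a fixed seed reproduces byte-identical outputs,
  including rerun pipelines.
* Timestamps are handled as UTC POSIXct; the study clock is treated as a
  fixed-offset local time with no DST transitions.
* Degenerate inputs raise classed conditions
  (`stemflux_validation_error`, `stemflux_insufficient_data_error`,
  `stemflux_degenerate_fit_error`, `stemflux_domain_error`,
  `stemflux_missing_input_error`) naming the offending file, column or row,
  so pipeline callers can map them to exit codes.
* Flat traces (zero variance) report slope 0 with R² 0 and a `low_r2`
  flag rather than an undefined R².
* A floor of 6 µmol m⁻³ s⁻¹ keeps generated cold-edge campaign fluxes
  positive, mirroring the smallest effluxes such campaigns report.

## Problem sizes

The shipped tests and the acceptance script run the generator at its
default study scale: 48 sprouts × 2 seasons of hourly dendrometer data
(~493 k observations), 480 chamber traces of 60 samples, and ~41 k hourly
micromet records; Monte-Carlo checks use 1,000 trace replicates, 1,000
random-walk partitions and 2,000 interaction-test simulations. These sizes
were chosen to exercise every code path at realistic volume while keeping
a full run in minutes on one core.

## Known limitations

* The zero-growth assumption attributes osmotic or thermal swelling above
  the previous maximum to growth; alternative partitioning concepts are
  out of scope.
* The exponential efflux–temperature fit is log-linear OLS, not nonlinear
  least squares; with multiplicative errors this is also the better
  statistical model, but coefficients differ slightly from an NLS fit.
* Percent-of-expected is undefined where the linear reference predicts
  non-positive efflux; cold drought-year campaigns would need an
  exponential reference instead.
* The pipeline is single-threaded by design; the heaviest default run is
  well under a minute per stage.
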