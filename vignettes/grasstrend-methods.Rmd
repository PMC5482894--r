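---
title: "Methods: grassland AGB dynamics from NDVI time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grassland AGB dynamics from NDVI time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grasstrend)
```

This vignette documents the models behind `grasstrend`, the parameters
that matter, the synthetic-data generator that stands in for field and
satellite archives, and the numerical and design decisions that were
genuinely open.

## The estimation chain

The package estimates grassland aboveground biomass (AGB, kg/hm²) and
its dynamics in five statistical steps.

**Field NDVI.** A plot's NDVI is the mean, over its nine 1 m² quadrats,
of the narrow-band index $(R_{800} - R_{680})/(R_{800} + R_{680})$
computed from canopy reflectance exactly at 800 nm and 680 nm. No band
averaging or interpolation is applied: field spectrometers deliver 1 nm
resolution, so the single-wavelength values are the measurement.
Quadrats without a spectrum still count in the plot's mean AGB; a plot
with no spectra at all has `NA` NDVI rather than an invented zero.

**Regression families.** Calibration and AGB modelling both choose
among four two-parameter families: linear $y = a + bx$, exponential
$y = a e^{bx}$, logarithmic $y = a + b\ln x$, and power $y = a x^b$.
The nonlinear families are fitted by Levenberg–Marquardt least squares
in the *original* response space, initialised from the log-transform
closed form. Fitting in original space (rather than transform-then-OLS)
was an open choice; it was taken so that $R^2 = 1 - SS_{res}/SS_{tot}$
and $RMSE = \sqrt{SS_{res}/n}$ are computed on the same scale for every
family and model selection compares like with like. RMSE uses divisor
$n$ by default (`rmse_divisor = "n-p"` is available); with only two
parameters per family the choice barely moves the selection. Selection
maximises $R^2$, breaking ties by minimal RMSE and then by the
simplicity order linear < power < exponential < log. When a nonlinear
fit fails to converge — rare, since the initialisation is already the
transform-space optimum — the initialisation itself is returned with a
warning rather than aborting a whole pipeline run.

**Calibration direction.** The calibration regresses *field* NDVI on
*satellite* NDVI. That direction is the only one that lets the fitted
model be applied to satellite rasters to produce field-equivalent NDVI.
Predictions are clipped to $[-1, 1]$, the index's definitional range. A
single pooled model across grassland types is the default; `by_type =
TRUE` fits one per type for users who want to test the pooling
assumption.

**AGB models and their application.** One model per grassland type
(meadow, steppe), fitted on field NDVI, applied per pixel to calibrated
NDVI with a type raster (1 = meadow, 2 = steppe, 0 = non-grassland)
deciding which model each pixel gets. Two guard rails keep silent
extrapolation visible rather than hidden: negative predictions are
floored at 0 and counted, and pixels above NDVI 0.8 — the saturation
guard, the largest value a survey of these grasslands encounters — are
converted anyway but counted in the same QA record. For the log and
power families, non-positive NDVI carries no biomass signal and maps
to 0.

**Trend and persistence.** The per-pixel trend is the OLS slope of
annual AGB on the year index $i = 1..n$, computed in sum form
$$slope = \frac{n\sum i\,AGB_i - \sum i \sum AGB_i}
               {n\sum i^2 - (\sum i)^2},$$
algebraically $\mathrm{cov}(i, AGB)/\mathrm{var}(i)$ (the test suite
asserts the equivalence to $10^{-9}$). Slopes are classified by
magnitude: below −10 "significant decrease", $[-10, 0)$ non-significant
decrease, $[0, 10)$ non-significant increase, $\ge 10$ significant
increase. **These "significant" labels are magnitude thresholds in
kg·hm⁻²·yr⁻¹, not statistical tests**; the threshold is a parameter.
The year index origin is cosmetic (slopes are invariant to it) but
fixed at 1 for reproducibility.

Persistence uses classical rescaled-range analysis. For each window
length $\tau$ the series is split into $\lfloor n/\tau \rfloor$
non-overlapping windows (trailing points discarded); each window is
demeaned, $R$ is the range of the cumulative deviation sums, $S$ the
population standard deviation (divisor $\tau$), and $R/S$ is averaged
over windows with $S > 0$. The Hurst exponent $H$ is the OLS slope of
$\log(R/S)$ on $\log\tau$ (natural logs; the base cancels in the
slope). $H > 0.5$ is classified sustainable, $H < 0.5$
anti-sustainable, exactly $0.5$ random; `tol` widens the random band if
wanted, and `tol = 0` reproduces the strict rule.

The window scheme, $S$ definition, and $\tau$ grid are not fixed by the
method's usual presentation, so they are explicit decisions here:
non-overlapping windows and population $S$ (the most common classical
choices), and a default grid of $\{3, 4, 6, 12, 13\} \cap [2, n]$ for
short annual records ($n \le 16$) versus all integers $4..\lfloor n/2
\rfloor$ plus $n$ for long series. All are arguments. Classical R/S is
biased upward on short series — at $n = 13$ severely so; that is a
property of the estimator, not something the package corrects silently.
An Anis–Lloyd expected-$R/S$ correction is available
(`anis_lloyd = TRUE`, default off), and the test suite verifies it
shrinks the white-noise bias at $n = 64$.

**Future dynamics.** Sustainable pixels keep their trend class (four
`s_*` classes); anti-persistent pixels become
`anti_sustainable_uncertain` regardless of trend; $H = 0.5$ pixels get
`random_uncertain`, a class introduced for completeness (it is
measure-zero for continuous data) which `paper_mode = TRUE` collapses
into the anti-sustainable class. Area fractions are reported per class,
overall and by type, plus two aggregates: *improvement* =
`s_nonsig_increase` + `s_sig_increase`, *degradation* = the two
decrease classes.

## The synthetic-data generator

The generator is first-class, tested code: it produces every input the
pipeline consumes, with the quantities the pipeline estimates known
exactly.

**Survey** (`simulate_survey`). Defaults mirror a 64-plot campaign:
31 meadow and 33 steppe plots, nine quadrats each. Plot NDVI is uniform
on (0.52, 0.78) for meadow and (0.12, 0.48) for steppe — the two types
on opposite sides of 0.5 and below the 0.8 saturation guard. AGB
follows a linear meadow law ($a = 121.7$, $b = 900$) and a power steppe
law ($a = 4007$, $b = 1.8$), chosen so the *expected* plot mean over
each type's NDVI range equals 706.7 and 498.7 kg/hm² (for the convex
power law this is $a\,E[x^{1.8}]$, not the law's value at the central
NDVI). Quadrat AGB noise is 60 kg/hm² — large enough that family
selection is a genuine contest, small relative to the type means.
Satellite NDVI is a linear map of field NDVI
($sat = 0.0556 + 1.1111\,field$, noise 0.01), i.e. the satellite reads
slightly high; inverting it gives the calibration the pipeline should
recover ($field \approx 0.9\,sat - 0.05$). Spectra are built by fixing
$R_{800} = 0.5$ and solving the NDVI formula for $R_{680}$ (adjusting
$R_{800}$ when the solution leaves $[0,1]$) — the simplest invertible
construction; the round trip through `compute_narrowband_ndvi` is exact
to $10^{-12}$ and the suite asserts it.

Four plots (the 4/64 share a survey of this kind encounters) are
flower-contaminated: coverage above 20% and measured NDVI shifted by
−0.05 at unchanged biomass. The sign matters and was a genuine
decision: large white/pink flowers atop the canopy are not
photosynthetic tissue, so they *mute* the red/NIR contrast and depress
NDVI at a given biomass. Contaminated plots therefore lie above the
clean NDVI–AGB curve, a model fitted on all plots sits above the clean
relation (overestimating meadow AGB), and refitting without them lowers
predictions at fixed NDVI — the direction the sensitivity analysis
checks. An inflating shift would produce the opposite geometry.

**Stacks** (`simulate_stack`). Each pixel's annual series is
$baseline + trend \cdot i + \sigma \cdot fGn_H(i)$: an additive linear
trend over fractional Gaussian noise, the canonical stationary process
with a defined Hurst exponent (the increments of fractional Brownian
motion). fGn is generated by circulant embedding of its exact
autocovariance
$\gamma(k) = \tfrac12(|k{+}1|^{2H} - 2|k|^{2H} + |k{-}1|^{2H})$, with
an exact $O(n^2)$ Durbin–Levinson fallback should the embedding ever be
numerically non-positive-definite. Defaults: 30 × 30 pixels, 13 years,
trend field $N(3, 6)$ kg·hm⁻²·yr⁻¹ (≈ 69% of true slopes positive,
matching a landscape where roughly 70% of grassland is improving),
$H = 0.7$ (persistent, near surveyed grassland averages of 0.66–0.68),
noise scale 40 kg/hm² around a 400 kg/hm² baseline, grid split into a
meadow west half and steppe east half. The trend and fGn are additive
and independent — the generator makes no claim about their interaction.
An optional 16-day mode emits 23 within-year layers whose seasonal
curve peaks at exactly the annual value, so annual maximum-value
compositing must reproduce the annual stack bit-for-bit; that is the
compositing oracle.

**What the generator does not emulate**, and hence what passing tests
do not show about real data: cloud and atmospheric contamination (MVC
is exercised, but against clean seasonal curves), spatial correlation
of noise between pixels, sensor bandpass differences beyond a linear
offset, NDVI saturation dynamics at high leaf area, mixed pixels at
type boundaries, and radiative-transfer realism of spectra (the red
edge is a piecewise-linear sketch). Recovery results here say the
estimators are implemented correctly, not that a 13-year real archive
pins down $H$ per pixel.

## Raster conventions and numerics

Rasters are `nrow × ncol × ntime` arrays with `NA` as nodata, row 1 at
the northern edge, and a four-number affine georeference (corner x/y,
cell size); serialization is lossless plain text (long CSV plus a JSON
header). Aggregation uses the arithmetic block mean by default —
consistent with reporting mean AGB/NDVI — with max and median options;
edge blocks the factor does not divide use the cells available, and
mean aggregation of a nodata-free grid conserves the global mean to
$10^{-10}$. MVC needs no tie-break (a maximum is one of its inputs).
Nodata policy for per-pixel statistics defaults to strict (any missing
year masks the pixel); the trend offers a pairwise-complete mode that
recomputes the sums over available years.

Degenerate inputs are errors, not guesses: empty quadrat lists, mixed
plot ids, zero-variance predictors, non-positive $x$ under log/power,
constant windows in R/S (skipped per window; an all-constant series is
an error), and fewer than three valid $R/S$ points.

## Problem sizes

The test suite and the acceptance script run everything at desk scale,
sizes chosen to give the stochastic checks comfortable margins:
10,000 random 13-point series for the slope/OLS equivalence; a
50 × 50 × 13 stack for trend recovery; 50 replicates of $n = 1024$ fGn
per target $H \in \{0.3, 0.5, 0.7, 0.9\}$ for Hurst recovery (the
classical estimator's bias and spread at that length keep all four
means within ±0.1 of target while preserving strict ordering);
30 × 30 × 256 fGn stacks for map-scale sustainability classification;
and the 64-plot survey defaults everywhere a survey is needed.

## Known limitations

- $H$ from 13 annual points is high-variance and upward-biased;
  per-pixel sustainability classes on short records are indicative.
  The long-series acceptance checks use 256–1024 time steps precisely
  because the estimator, not the record, is what the package can
  guarantee.
- Family selection between near-indistinguishable families (log vs
  linear on a narrow NDVI range, power vs exponential on steppe data)
  is noise-sensitive; selection stability is a property of the data,
  and the candidate list is always attached to the selected model for
  inspection.
- No map projections, no reprojection, no real-product quality
  filtering; the raster container is deliberately minimal.
- The transfer of AGB models fitted on *field* NDVI to *calibrated
  satellite* NDVI assumes the calibration fully reconciles the two
  scales; that assumption is inherited from the study design, not
  testable inside the package.
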