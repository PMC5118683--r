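---
title: "Detecting land-cover change hotspots from annual map series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting land-cover change hotspots from annual map series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcluc)
```

## The problem and the model

Annual categorical land-cover maps classified from satellite imagery are
noisy: a pixel's label can flip from year to year even where nothing on the
ground changed, and a single anomalous year (a drought, a fire, an extreme
El Niño season) can corrupt the maps at either end of a record. Estimating
change by simply differencing the first and last maps inherits all of that
noise. The approach implemented here is more robust in two ways.

First, pixels are aggregated into *big grid cells* of `blockSize` x
`blockSize` pixels (default 10 x 10; at 250 m pixels, a 2.5 x 2.5 km
cell). Within each cell the per-class cover *fraction* is tracked through
time, which suppresses pixel-level classification speckle while retaining
spatial detail far finer than administrative units.

Second, change is estimated by regression rather than differencing. For
each cell and class, the annual fraction series $f_t$ is fit by ordinary
least squares on the year index $t = 0, \dots, n-1$:

$$ f_t = a + b\,t + \varepsilon_t $$

with slope $b$ (fraction per year), its standard error
$\mathrm{se}(b)$ from the residual variance on $n - 2$ degrees of
freedom, and a two-sided t test of $b = 0$. A cell-class pair is a change
**hotspot** when $p < \alpha$ (default $\alpha = 0.1$). Net change over
the record is

$$ \Delta = b \times \text{interval} \times \text{cell area}, $$

reported only for significant slopes (non-significant cells carry 0 in the
hotspot layer but keep their raw fit), and its one standard deviation is
$\mathrm{se}(b) \times \text{interval} \times \text{cell area}$. Zonal
tables then sum gains (positive significant $\Delta$) and losses (negative
significant $\Delta$) separately per zone and class, with zone-level
uncertainty $\sqrt{\sum \mathrm{sd}^2}$ under an independent-cells
assumption.

Before aggregation, the five forest types of the 15-class legend (DBLE,
DNLE, EBLE, ENLE, MIXED) are merged into a single forest class FORE;
trend analysis covers the eight conversion-prone classes AGRI, BARE,
CLSH, FORE, GRAS, OPSH, SPAS and URBN.

## Key parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `blockSize` | 10 | pixels | cell edge; 10 x 10 pixels = 2.5 km at 250 m |
| `interval` | 13 | years | multiplier converting slope to net change |
| `alpha` | 0.1 | — | significance level of the slope t test |
| `cellArea` | 6.25 | km² | area of a fully valid cell |
| `minValid` | 1 | pixels | minimum valid pixels for a defined fraction |

Two conventions deserve comment.

**The interval multiplier.** A 2001–2013 record has 13 annual maps but
spans 12 inter-year intervals. Net change is nevertheless defined as slope
x 13, matching the convention this method is known by; the
endpoint-differencing baseline on a noiseless linear series consequently
reports 12/13 of the regression's net change (`endpointChange()`
documents the discrepancy rather than silently "fixing" it). The
ground-truth generator uses the same x13 convention so designed and
estimated net fractions are directly comparable.

**The fraction denominator.** Cell fractions are taken over *all* valid
pixels, including classes outside the analysis set (water, snow). The
eight analysis-class fractions may therefore sum to less than 1, but the
full-legend fractions sum to exactly 1 in every fully valid cell — which
makes two invariants exact: per-cell slopes over the full legend cancel to
zero (OLS is linear), and unmasked zonal nets conserve to zero in closed
scenarios. Cells with some nodata pixels are kept with a reduced
denominator rather than dropped, to avoid biasing coastal and water-edge
cells; `minValid` tightens this when desired. Significance masking breaks
the zonal conservation property, deliberately: only defensible changes
enter the budgets.

**Significance is per (cell, class) with no multiple-testing correction**,
which is the convention of hotspot mapping at this scale: the alpha
describes the per-cell false-positive rate, and the null calibration test
verifies it (about 10% of null series are flagged at alpha = 0.1). A
Benjamini–Hochberg option (`fdr = TRUE`) exists for users who want
family-wise control, but it is off by default.

## The ensemble fusion rule

When several classification models produce maps plus per-class membership
probabilities, the fusion stage adopts the unanimous label wherever all
models agree, and otherwise averages the per-model probability vectors —
equal weights by default, or weights proportional to supplied overall
accuracies — and takes the argmax. Arithmetic averaging of posteriors is
the standard Bayesian-model-averaging reading of this rule; the weighting
scheme is pluggable, and no geometric pooling is offered. Exact
probability ties are broken deterministically towards the lowest class
code and counted in the result, so arbitrary choices remain visible.

## What the synthetic generator emulates — and what it does not

`scenarioConfig()` / `generateSeries()` realise an annual label stack in
which named regions undergo constant-rate class conversions: a fraction
`annualRate` of each region's area converts from one class to another
every year. Conversion counts use largest-remainder rounding with the
remainder carried across years, so cumulative conversions track the
designed linear trajectory to within half a pixel and region-level
fraction series are affine in the year index. Spatially, `"clustered"`
mode accretes conversions around existing target-class patches
(breadth-first nearest eligible pixels, ties broken in row-major order) —
reproducing the contiguous geometry of urban rings and spreading forest —
while `"random"` mode scatters them uniformly. `applyNoise()` then flips
each pixel-year independently with probability `noiseRate`, drawing the
replacement from a row-stochastic confusion matrix; anomaly years apply a
one-year elevated rate, modelling a bad mapping year rather than a
persistent shift.

The built-in `demoScenario()` uses a 200 x 200 grid (20 x 20 cells) over
2001–2013 with urban expansion into agriculture at 1%/yr (clustered),
grassland reclamation to agriculture at 1.2%/yr (random), shrubland
succession to forest at 1.5%/yr (clustered), and 5% per-pixel-year noise —
rates and noise chosen as representative of regional land-change
magnitudes over a 13-year record and of maps with ~85–95% per-pixel
accuracy.

The ground truth is derived from the configuration, never from the
realization: each cell's designed slope is `annualRate` times its overlap
with the region. That is exact in expectation for `"random"` transitions;
in `"clustered"` mode conversions concentrate around seeds, so only
*region-level* designed totals are exact and per-cell recovery tests use
random mode.

Three features of real data are deliberately not emulated, and passing
tests therefore say nothing about them: spatially *correlated*
classification error (noise here is iid per pixel-year, while real
classifiers err coherently along class boundaries and terrain), class
confusion structure (the default confusion is uniform over the other
classes; a realistic matrix would concentrate confusion among
spectrally similar classes), and nonlinear or abrupt change (fires,
floods, stepwise construction), which a linear trend cannot represent —
the regression will average a breakpoint into a shallower slope.

Independent per-year noise also implies a known attenuation: with flip
rate $\rho$ and uniform confusion over $K-1$ alternatives, observed
fraction slopes shrink by the factor $1 - \rho K/(K-1)$. At the demo's
$\rho = 0.05$, recovered regional nets run ~5% below the designed values,
visible in the worked example; this is a property of classification error
itself, not an estimator defect, and the fraction-level Gaussian
simulations used for calibration are free of it.

The simulated classifier ensembles (`generateClassifierOutputs()`) make
the predicted label equal the true class with probability `reliability`
and otherwise uniform over the other classes; the predicted class receives
a membership probability drawn uniformly from `winnerMass` (default
0.55–0.95) and the remainder is split by a symmetric Dirichlet, so labels
are always the argmax of their own probabilities and label accuracy equals
`reliability` exactly. The mean probability mass on the *true* class then
tracks reliability only approximately — with a symmetric remainder one
cannot fix both the accuracy and the mean true-class mass at the same
value — and the construction pins down the measurable quantity.

## Numerical choices

- The OLS kernel is the closed-form normal-equations solution, vectorised
  over all (cell, class) series at once; unit tests verify agreement with
  R's QR-based `lm()` to 1e-10.
- A constant series is reported with slope exactly 0 and an undefined
  (NA) p-value, treated as non-significant downstream; any other
  zero-residual series (a perfect line) gets p = 0. Degeneracy is detected
  against a relative threshold (`1e-18` times the series' sum of squares),
  not exact floating-point zero.
- Cells missing any year, or with fewer than 3 years, are nodata in every
  trend band.
- A cell belongs to the zone covering its centre pixel (for even block
  sizes, the upper-left of the two central candidates).
- Rasters are stored as ESRI ASCII grids with 17 significant digits, so
  write→read round-trips are bit-exact; CRS and analysis parameters travel
  in JSON sidecars.
- All randomness flows from explicit integer seeds; the pipeline derives
  one sub-seed per stage from the run seed, and identical configuration +
  seed reproduces every artifact byte for byte.

## Problem sizes used in validation

The shipped validation suite calibrates the method at sizes chosen to make
Monte-Carlo error small relative to the quantities checked: 10,000 null
series for the false-positive rate, 50 seeds x 2,000 cells for net-change
recovery (designed net fraction 0.13 from a +0.01/yr slope), 10,000 cells
for the one-SD coverage (nominal coverage of a ±1 SE band under the t
model with 11 df is $P(|t_{11}| \le 1) \approx 0.662$), 1,000 series each
for the oracle-agreement and anomaly-robustness checks, and the 200 x 200
demo landscape for the end-to-end conservation and recovery properties.

## Known limitations

- Linear trends only: no Theil–Sen or Mann–Kendall alternative, no
  breakpoint detection.
- The change floor is one pixel footprint (5.3 ha for a 231.656 m
  sinusoidal-grid pixel, `detectionFloor()`); sub-pixel change is
  invisible, and labels are hard (no fuzzy membership fractions).
- No reprojection or resampling: inputs must be co-registered, and zone
  rasters must align with the pixel or cell grid.
- Zone-level SDs assume independent cells; spatially correlated error
  would make them optimistic.
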