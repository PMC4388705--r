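---
title: "Methods: a satellite-driven semi-empirical NEE model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a satellite-driven semi-empirical NEE model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neeflux)
```

## The model

Net ecosystem exchange is modelled as the balance of two semi-empirical
components,

$$\mathrm{NEE} = R_{eco} - \mathrm{GPP},$$

with the micrometeorological sign convention: negative NEE is net carbon
uptake by the ecosystem. Gross primary productivity follows a
rectangular-hyperbola (Michaelis–Menten type) light response at canopy
scale,

$$\mathrm{GPP} = \frac{\alpha\,\beta\,\mathrm{PAR}}{\beta + \alpha\,\mathrm{PAR}},$$

where the apparent quantum use efficiency $\alpha$ and the apparent maximum
photosynthetic rate $\beta$ are tied to ambient CO$_2$ through the
temperature-dependent compensation point $\tau$:

$$\alpha = \frac{C_a - \tau}{C_a + 2\tau}\,\alpha_0,
  \qquad \beta = (C_a - \tau)\,g_x,
  \qquad \tau = 42.7 + 1.68\,(T - 298) + 0.0012\,(T-298)^2,$$

with $T$ the air temperature in Kelvin and $C_a$ fixed at
350 μmol mol$^{-1}$ by default (configurable). Ecosystem respiration is a
Van't Hoff exponential in soil temperature at 5 cm,

$$R_{eco} = b_0\,e^{b\,T_{soil}},$$

so $b_0$ is the respiration rate at 0 °C and $e^{10b}$ the Q$_{10}$. The
four parameters $(\alpha_0, g_x, b_0, b)$ carry the seasonality of canopy
development and substrate supply; the drivers (PAR, air and soil
temperature) carry the diurnal and synoptic signal.

Notes on conventions adopted where the source material is ambiguous:

* **Sign.** The single-expression composite form of the model is written
  uptake-positive in parts of the literature; this package defines model
  output as $R_{eco} - \mathrm{GPP}$ throughout so that it is directly
  comparable to measured NEE series (negative = uptake). `nee_composite()`
  retains the uptake-positive orientation as an independent evaluation route
  and is cross-checked against the factored form in the tests.
* **Units of $g_x$.** $g_x$ is reported in the literature both as
  μmol CO₂ m⁻² s⁻¹ and as m s⁻¹ (a conductance). The package treats it
  operationally as the proportionality constant $\beta/(C_a-\tau)$ and
  makes no unit conversion.
* **$\tau$ clipping.** The quadratic is a local approximation; it is clipped
  to $[0, 0.99\,C_a]$ so the light-response terms stay defined at extreme
  temperatures.

## Vegetation indices

NDVI, EVI and LSWI are computed from 8-day composite surface reflectance of
the blue, red, NIR (841–875 nm) and SWIR (1628–1652 nm) bands with the
standard formulas (EVI with $G=2.5$, $C_1=6$, $C_2=7.5$, $L=1$). Records
failing the (pre-decoded, boolean) QC flag, missing, or carrying reflectance
outside $[0,1]$ are filled per index by linear interpolation between the
nearest valid neighbours, with nearest-value extension at the series edges.
The original compositing product's bit-level QC semantics and the exact
published gap-filling algorithm are out of scope; the interpolation rule is
a declared stand-in, pluggable via the `fill` argument.

## Windowed inversion

Parameters are estimated every 8 days on the DOY 1, 9, …, 361 grid shared
with the satellite composites, using **all** valid half-hourly NEE in the
window (up to 384 points; default minimum 96, i.e. 25 % coverage — a common
flux-community floor). The fit minimises
$\sum_i (\mathrm{NEE}_{mod,i} - \mathrm{NEE}_{obs,i})^2$ over box
constraints $\alpha_0 \in [0, 0.125]$ (the theoretical quantum-efficiency
ceiling), $g_x \in [0, 1]$, $b_0 \in [0, 20]$,
$b \in [0, 0.5]$. $\tau$ is evaluated per record from the instantaneous air
temperature.

Numerical choices:

* the optimizer is `stats::nlminb` (bounded PORT quasi-Newton) with analytic
  gradients of the residual vector;
* every window is fitted from the previous window's converged estimate
  (seasonal trajectories are smooth) **and** from a small deterministic set
  of alternative starts, keeping the best objective. The always-on
  multi-start matters in cold-season windows, where the exponential
  respiration term admits a spurious local minimum with $b_0 \to 0$;
* standard errors are the linearized covariance
  $\hat\sigma^2\,\mathrm{diag}\,(J^\top J)^{-1}$ with
  $\hat\sigma^2 = \mathrm{RSS}/(n-k)$ and an analytic Jacobian, computed by
  eigendecomposition so that numerically null directions yield infinite
  (rather than spuriously finite) standard errors. A window is `converged`
  only if the optimizer reports success *and* all SEs are finite, so
  windows with no daytime information (photosynthesis pair unidentified)
  or no data are flagged out;
* no observation weighting or outlier screening is applied within windows.

The respiration pair $(b_0, b)$ is strongly negatively correlated within a
window — a given respiration level can be matched by trading base rate
against temperature sensitivity — which the Monte-Carlo tests confirm
(sampling correlation ≈ −0.95). `invert_window_fixed()` supports holding
either of them at an external value (reported with SE 0), which measurably
shrinks the variance of the other.

## Calibration and prediction

Each inverted parameter is regressed (simple OLS, one predictor at a time)
on the aligned 8-day predictors: the three vegetation indices and the
window means of air temperature, soil temperature and soil water content
over valid half-hours. Only converged windows enter. $R^2$ is the squared
Pearson correlation; significance is a nominal two-sided $p < 0.05$ gate
with no multiple-testing correction across the 4 × 6 grid (mirroring common
practice for this model family). Per parameter the significant admissible
candidate with the highest $R^2$ is selected; by default the photosynthesis
parameters and $b_0$ admit vegetation indices (they track canopy state)
while $b$ admits the environment predictors (its variation is climatic, not
phenological). If nothing is significant the parameter falls back to the
median of its converged inverted values, flagged as a constant.

Prediction applies the selected linear maps to a (gap-filled) predictor
series and clips to the inversion bounds; forward simulation then evaluates
the model per half-hour with the containing window's parameters.

All regressions use every converged window of the calibration period rather
than growing-season windows only; a season filter is a config extension, and
with the default bounds the off-season windows mostly carry near-zero
photosynthesis parameters that anchor the regression intercepts.

## Validation metrics

$R^2$ is deliberately the squared Pearson correlation of modeled vs
observed (the $R^2$ of the modeled~observed regression), not
$1-\mathrm{SSE}/\mathrm{SST}$: it is invariant to affine miscalibration,
which is instead reported through the regression slope and intercept.
Day/night strata split at PAR < 5 μmol m⁻² s⁻¹ (flux-community convention;
the source material does not state a threshold). The windowed $R^2$ series
uses the same 8-day grid with a 10-pair minimum per entry for stability.

## The synthetic world

`generate_scenario()` emulates a high-elevation alpine steppe-meadow flux
site so that every stage is testable offline:

* **Radiation**: clear-sky PAR = 2200 μmol m⁻² s⁻¹ × sin(solar elevation),
  from latitude 30.5° N and the standard solar-declination formula. No
  cloud transmissivity — PAR is deterministic.
* **Temperature**: annual mean 1.3 °C, seasonal semi-amplitude 10.5 °C
  (monthly means ≈ −10 … +11 °C), diurnal semi-amplitude 8 °C, plus daily
  AR(1) synoptic anomalies (sd 2.5 °C, lag-1 0.7). Soil temperature at 5 cm
  is a damped (× 0.7 seasonal, × 0.3 diurnal), lagged (8 days) copy with the
  synoptic anomalies smoothed over 5 days. The synoptic noise is what keeps
  window-mean air and soil temperature distinguishable as regression
  predictors; without it they are near-collinear sinusoids and predictor
  attribution for $b$ is a coin flip.
* **Moisture**: monsoon-season rain events (probability following the
  phenology curve, exponential amounts) feed a first-order bucket for VWC.
  Episodic moisture is deliberately *not* a smooth copy of phenology, again
  so the predictor set is not collinear. The drought switch suppresses rain
  frequency in a configurable mid-season span.
* **Canopy**: NDVI and LSWI follow double-logistic seasonal curves (green-up
  DOY 140, peak 215, senescence 290; NDVI 0.12–0.50, LSWI −0.05–0.25, inside
  the ranges typical for such sites). LSWI leads greenness by 12 days —
  canopy/surface water rises with monsoon onset ahead of peak greenness —
  which also breaks the exact collinearity that a single shared curve would
  impose and makes "which index generated which parameter" answerable at
  all. Reflectance bands are *constructed*: red and blue fixed at 0.10 and
  0.05, NIR solved from the NDVI target, SWIR from the LSWI target, so those
  two curves are reproduced exactly and EVI is emergent (three indices share
  four bands; hitting all three independently is overdetermined).
* **Parameters and fluxes**: per window,
  $\alpha_0 = 0.006 + 0.08\,\mathrm{LSWI}$,
  $g_x = 0.004 + 0.06\,\mathrm{EVI}$, $b_0 = 0.3 + 5\,\mathrm{EVI}$,
  $b = 0.135 - 0.004\,\bar T_{soil}$, each plus Gaussian window noise and
  clipped to the inversion bounds. These maps put the peak parameters in the
  published ranges for alpine grassland (peak $\alpha_0 \approx$ 0.021–0.033,
  $g_x \approx$ 0.011–0.025, $b \approx$ 0.06–0.19). Half-hourly NEE is
  $R_{eco} - s\,\mathrm{GPP} + \varepsilon$ with observation noise
  $\sigma = 0.5$ μmol m⁻² s⁻¹ by default and $s$ a GPP-suppression factor
  (< 1 only in drought windows of a drought scenario). The suppression is a
  *model-unrepresented* process: within a window it is absorbable by
  rescaling $(\alpha_0, g_x)$, so inversion still fits, but the calibrated
  VI regressions over-predict GPP in dry windows and the windowed $R^2$
  drops there — the mechanism the validation tests probe.
* **Determinism**: one scenario seed derives fixed sub-seeds for rain, QC
  corruption, parameter noise and observation noise; generation never
  touches (and always restores) the caller's RNG state.

What a green synthetic test does **not** establish: realism of radiative
transfer or reflectance spectra, storage/advection errors of real eddy
towers, u*-filtering and gap-filling artefacts, energy-balance closure, or
transferability of the calibration across sites. The generator's NEE is by
construction the model plus noise (except for drought suppression), so
end-to-end recovery tests demonstrate correctness of the machinery, not
adequacy of the model for any particular ecosystem.

## Known limitations

* Soil moisture influences the real fluxes but not the model form; dry-year
  performance degrades accordingly (and the drought scenario reproduces
  that signature qualitatively).
* The analytic standard errors are linearized; near bounds or with strong
  $b_0$–$b$ correlation they understate the true uncertainty (the tests
  require only factor-2 agreement with Monte-Carlo spread).
* The calibration is single-predictor linear by design; no multiple
  regression, no cross-site hierarchy.
* The 8-day windows assume the parameters are constant within a window;
  day-to-day variability inside a window is only summarised by the standard
  errors.
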