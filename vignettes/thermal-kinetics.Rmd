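---
title: "Thermal kinetics of nanoparticle-assisted photothermal therapy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal kinetics of nanoparticle-assisted photothermal therapy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pttherm)
```

## The measurement and the model

In plasmonic photothermal therapy (PTT), a near-infrared laser irradiates a
tumor into which gold nanorods (GNRs) have been injected; the nanorods'
surface-plasmon absorption converts light into localized heat. An infrared
thermographic camera records the skin surface during the exposure, giving a
stack of temperature-calibrated frames. `pttherm` implements the
quantitative analysis of such recordings for a study design with four laser
wavelengths (808, 940, 975, 1064 nm) crossed with two intratumoral
injection arms (GNR vs saline), four animals per group.

The analysis reduces each recording to a hotspot ROI temperature trace and
models the heating as the step response of a first-order thermal system,

$$T(t) = (T_0 - T_\infty)\,e^{-t/\tau} + T_\infty,$$

where $T_0$ is the surface temperature at laser-on, $T_\infty$ the
steady-state temperature the tissue would approach under continued
irradiation, and $\tau$ the thermal time constant — the time to cover
$1 - e^{-1} \approx 63.2\%$ of the span. A first-order model is the
simplest dynamical description of a lumped thermal mass under a constant
heat input, and it is adequate here: at realistic noise levels the fits
reach $R^2 > 0.99$ (see below).

Derived quantities compare the injection arms at each wavelength:

* $T_{max}$ — the maximum ROI-mean temperature over the 90 s exposure
  (for monotone first-order heating, the end-of-exposure value);
* $\Delta T = T_{max} - T(0)$ — the temperature change per animal;
* effective temperature enhancement
  $\tilde T_{enh} = 100\,(T_i - T_{PBS,i})/T_{PBS,i}$ — percent excess of
  the GNR-arm group-mean $T_{max}$ over the saline-arm group mean at the
  same wavelength. Note that this quantity divides by a Celsius
  temperature, so it is anchored to the Celsius scale and not invariant
  under a common offset; it is implemented exactly as defined, with this
  property documented rather than "fixed";
* heating efficiency $HE = \Delta T_{GNR}/\Delta T_{saline}$ — a ratio of
  changes, hence offset-invariant;
* the normalized heating curve
  $\tilde T(t) = (T(t) - T_{min})/(T_{max} - T_{min})$, which strips
  amplitude and isolates kinetics for cross-group comparison.

Group contrasts (GNR vs saline on $T_{max}$ and on $\tau$) use the
two-tailed pooled-variance Student t-test at $\alpha = 0.05$, the
convention for this assay; a Welch variant sits behind a flag. No
multiple-testing correction is applied, matching the source analysis
convention; with eight tests this is a descriptive, not confirmatory,
choice.

## ROI extraction

The operator convention this package reproduces is a fixed circle of 30
pixel diameter placed over the hottest part of the tumor. `locate_roi()`
determinizes the "encompassing the maximum temperature values" rule as:
the center is the pixel attaining the global maximum over all frames at or
after laser-on, with ties broken by first occurrence in (frame, row,
column) order. Membership uses the pixel-center rule (centers within
`diameter/2`, inclusive), verified in the test suite against brute-force
enumeration. If the maximum lies closer than one radius to the frame edge,
the center shifts minimally inward **to the nearest integer center** that
fits — integer centers all carry the identical member-pixel count, so ROI
means stay comparable across animals. Whether the original operators chose
the ROI on the final frame or the hottest frame is unknowable from a
publication; the spatiotemporal-maximum rule is this package's
determinization and is recorded in the ROI JSON emitted by the CLI.

Per frame, `roi_trace()` reports the arithmetic mean and the *population*
SD over the member pixels — the SD is a descriptive spatial spread over a
fixed pixel set, not a sampling estimate. Because averaging a spatially
scaled first-order field preserves the exponential time dependence, the
ROI-mean trace has the same $\tau$ as the underlying field; the suite
checks recovery within 1% on rendered stacks.

## Fitting

`fit_first_order()` minimizes $\sum_k (T_k - T(t_k))^2$ over
$(T_0, T_\infty, \tau)$ with Levenberg–Marquardt iterations
(`minpack.lm::nls.lm`) and the analytic Jacobian. Choices that matter:

* **Fit window.** Only $t \in [0, \text{exposure}]$ is fitted; the
  pre-exposure baseline (negative times) is excluded — the model clock
  starts at laser-on.
* **Weights.** Unweighted by default: the per-frame SD channel measures
  spatial spread, not the measurement error of the mean. A weighted mode
  (`weighted = TRUE`) is available.
* **Initialization.** $T_0^{(0)}$ = first sample, $T_\infty^{(0)}$ = mean
  of the final 5% of samples, $\tau^{(0)}$ = the linearly interpolated
  time of first crossing of $T_0^{(0)} + (1-e^{-1})(T_\infty^{(0)} -
  T_0^{(0)})$, falling back to exposure/3. On non-convergence the fit
  restarts deterministically from $0.5\times$ and $2\times$ $\tau^{(0)}$.
* **Bounds.** $\tau \in (0, 10\cdot\text{exposure}]$; the upper bound
  keeps near-linear traces from chasing an unidentifiable asymptote.
* **Degenerate input.** Traces whose span is below `span_floor` (default
  1 °C) return `converged = FALSE` with reason `"degenerate span"` instead
  of a meaningless fit.
* **Uncertainty.** 95% confidence intervals use the linearized covariance
  $\hat\sigma^2 (J^\top J)^{-1}$ with $\hat\sigma^2 = SSE/(n-3)$ and a
  Student-t quantile on $n-3$ df. The CI construction behind a published
  "95% confidence bound" is rarely stated; the linearization is this
  package's choice and its calibration is tested empirically (coverage
  within [90%, 99%] at the study's noise level over 300 replicates).
* **Fit quality.** $R^2 = 1 - SSE/SS_{tot}$;
  $RMSE = \sqrt{SSE/n}$ with denominator $n$ (not $n-p$) — a descriptive
  residual scale; switching to $n-p$ is a one-line change.

The test suite holds the fitter to a *separable grid-search oracle*: for
fixed $\tau$ the model is linear in $(T_0, T_\infty)$, so scanning $\tau$
over [1, 200] s at 0.01 s steps with a closed-form linear solve at each
point gives an independent global SSE reference. The fitted SSE must never
exceed the oracle's by more than $10^{-6}$ relative.

`normalized_temperature()` takes $T_{min}/T_{max}$ as the observed extrema
over the exposure window (the window is otherwise unspecified in the
field's usage); a robust variant uses the 1st/99th percentiles and clips
to [0, 1].

## What the simulator emulates — and what it does not

`simulate_trace()`/`simulate_stack()` generate data with the statistical
structure the analysis assumes, parameterized by `default_group_params()`:
per-group means and SDs of $(T_0, \tau, T_{max})$ for all eight groups.
The defaults encode the reported outcomes of the in-vivo study this
pipeline is designed around: control-arm time constants of 67.8 ± 1.8 s
(808 nm), 57.7 ± 12.3 s (940 nm), 38.3 ± 5.1 s (975 nm) and 66.9 ± 4.8 s
(1064 nm); a GNR-arm time constant of 35.4 ± 9.8 s at 940 nm, with the
other GNR arms derived from the reported reductions (~33 s below control
at 808/1064 nm, ~7 s at 975 nm); and group-mean maximum temperatures of
68/69/84/69 °C (GNR) and 52/64/79/56 °C (saline). $T_\infty$ is not
reported anywhere — it is back-computed by `tinf_from_tmax()` so that the
90 s endpoint of the mean curve lands exactly on the group-mean $T_{max}$.
Initial temperatures follow from $T_{max} - \Delta T$ (29–31 °C across
groups, a plausible skin-surface baseline under anesthesia).

Where no value was reported, one realistic choice was made once: SD of
$T_0$ across animals 1 °C; the GNR-arm $\tau$ SDs at 808/975/1064 nm
reuse the matched control-arm SDs; the unprinted saline-arm $T_{max}$ SD
at 940 nm is set to 3 °C (the magnitude of its neighbors). Per-animal
draws are truncated normal (redrawn until $\tau > 1$ s and
$T_\infty > T_0$, with a capped retry count) because the printed SDs — up
to 12.3 s on $\tau$ — admit nonphysical draws.

**Noise model.** The camera model carries a per-pixel noise SD (default
0.7 °C) plus an optional bias within the ±2 °C accuracy band of the
emulated camera and a 0.01 °C readout quantization. For trace-level
simulation the ROI-mean noise is `noise_sd / sqrt(effective_roi_pixels)`.
The default `effective_roi_pixels = 1` treats the noise as fully
correlated across the ~700 pixels of a 30-px ROI: empirically, residuals
of first-order fits to ROI-averaged thermography traces sit near 0.7 °C,
far above what independent pixel noise would leave after averaging
(≈ 0.03 °C), implying frame-level drift dominates. The parameter is
exposed so users can explore intermediate correlation regimes.

**Spatial model.** Rendered stacks place an isotropic Gaussian hotspot
(default SD 8 px, consistent with a ~0.8 cm beam on a down-scaled
160×120 frame; 640×480 available by configuration) on a rectangular body
footprint at baseline skin temperature over an ambient background
(24 °C). A Gaussian is the simplest spatial shape whose ROI mean still
follows first-order kinetics exactly. Five seconds of pre-exposure frames
(negative times) are included so baseline handling and ROI placement can
be exercised.

The simulator does **not** model bioheat conduction (no Pennes PDE),
tissue optical properties, nanoparticle plasmonics, perfusion, motion, or
spatially varying emissivity. Passing tests therefore validate the
*analysis chain* — extraction, fitting, metrics, statistics — under the
assumed data-generating model, not the biophysics of a real exposure.

## Reproducibility and problem sizes

Every simulation entry point takes an explicit seed; cohort runs expand
one global seed into per-animal substreams by a stable hash of (group,
animal index), so enlarging a design never perturbs existing draws. The
run report excludes wall-clock state, making `run_thermal_pipeline()`
byte-identical under a fixed seed and configuration.

Validation sizes were chosen to be statistically informative at desk
scale: 104 traces for the fit-quality check, 300 replicates for CI
calibration and bias, 50 traces against the grid-search oracle, 100
replicated eight-group cohorts (3 200 fits) for the ordering and
significance-frequency checks. The full suite runs in well under a
minute on one core.

## Known limitations

* The first-order model cannot represent overshoot, two-compartment
  kinetics, or the cooling phase after laser-off; the fit window stops at
  the end of the exposure by design.
* $\tilde T_{enh}$ inherits the Celsius anchoring of its definition;
  comparisons across studies with different baselines should prefer $HE$.
* The ROI placement rule is a determinization of a manual step; on real
  data with motion it would need registration upstream.
* Proprietary radiometric camera formats are out of scope; interchange is
  calibrated multi-page TIFF (float32 °C, or uint16 counts with linear
  scale/offset in a JSON sidecar) and CSV traces.

```{r}
report <- run_thermal_pipeline(run_config(seed = 1), outdir = NULL)
report$enhancement
```
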