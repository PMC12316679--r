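---
title: "Vessel architecture imaging: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vessel architecture imaging: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaimri)
```

## The measurement model

Vessel architecture imaging (VAI) exploits a hybrid dynamic susceptibility
contrast acquisition that records a gradient-echo (GE) and a spin-echo (SE)
image of the same slice within each dynamic, during the first pass of a
gadolinium bolus. The two echoes have complementary vessel-size sensitivity:
the GE transverse relaxation change responds to vessels of all calibers,
whereas the SE change is selectively sensitive to microvessels (radius below
roughly 10 µm). From the dynamic signals $S(t)$ and the pre-contrast baseline
$S_0$ (mean over the pre-injection dynamics), the contrast-induced relaxation
rate changes are

$$\Delta R_2^*(t) = -\ln\!\big(S_{GE}(t)/S_{GE,0}\big)/TE_{GE}, \qquad
  \Delta R_2(t) = -\ln\!\big(S_{SE}(t)/S_{SE,0}\big)/TE_{SE},$$

with $TE_{GE} = 25$ ms and $TE_{SE} = 78$ ms by default. Both are
concentration-proportional during the first pass. All downstream vessel
architecture measures are computed on a first-pass window of 4 dynamics
(6.4 s at the 1.6 s dynamic interval) before and 8 dynamics (12.8 s) after
the bolus peak; the peak is located on the GE curve, which carries the larger
susceptibility effect, and the same window indices are applied to the SE
curve. The window restriction excludes timepoints with little or no
relaxation change, where the ratio estimators below would be dominated by
noise.

Three voxel-wise measures are derived:

* **Vessel density index** $Q = \Delta R_2 / (\Delta R_2^*)^{2/3}$
  (units s$^{-1/3}$), computed by default as the ratio of window means.
* **Vessel size index**
  $VSI = 0.867\,(D \cdot rCBV)^{1/2}\, Q^{-3/2}$ (µm), the weighted-average
  microvessel radius; $D$ is the parenchymal diffusion coefficient in
  µm²/s and $rCBV$ the blood-volume fraction, which makes the units work
  out to µm exactly.
* **Microvessel type indicator** (MTI): the vortex curve plots
  $\Delta R_2^*(t)$ against $\Delta R_2(t)$ over the window; inter-compartment
  bolus delays open it into a loop. MTI is the signed polygon area, with the
  shoelace sum negated so that a clockwise loop is positive. A positive MTI
  indicates arteriole dominance (the bolus drives the GE effect before the
  capillary SE effect), a negative MTI venule dominance.

Supporting maps: $rCBV$ from the ratio of analytic gamma-variate integrals of
tissue and arterial curves, anchored so the normal-appearing white matter
(NAWM) mean is 3.2%; GE- and SE-derived cerebral blood flow (CBF) by
block-circulant SVD deconvolution; $D$ from a mono-exponential fit to the
diffusion decay at $b \ge 200$ s/mm².

## Estimator choices

**Q estimator.** "Ratio over the window" admits three readings: the ratio of
window means (default), the mean of pointwise ratios, and the regression
slope of $\Delta R_2$ on $(\Delta R_2^*)^{2/3}$. The ratio of means is the
most noise-robust single-number summary and uses all window points
symmetrically; the alternatives are available through `q_method`. The ratio
of means carries a small systematic (Jensen) bias whenever
$\Delta R_2^*$ varies across the window — exact when the window is flat,
within 5% when the window values vary by up to a factor of two, and about
−1.5% to −3% on realistic bolus shapes sampled at 1.6 s (quantified on the
phantom below). This bias is a property of the published estimator, not of
the implementation, and cancels in group contrasts to first order.

**MTI orientation.** "$\Delta R_2^*$ plotted against $\Delta R_2$" is read as
$y = \Delta R_2^*$, $x = \Delta R_2$. With arterioles driving $\Delta R_2^*$
first, the arteriole-dominated loop is traversed clockwise in that plane, so
the shoelace sum is negated to make clockwise positive. MTI is reported as
the raw loop area (units s$^{-2}$), not normalized by bolus amplitude; ROI
values are means of voxel-wise areas.

**ROI summaries** report the mean of voxel-wise values over the valid ROI
mask rather than metrics recomputed from ROI-averaged curves (a
curve-averaging mode would change the Jensen bias but not the ranking of
tissues; the voxel-wise route matches how the maps are used).

**rCBV integrals** use the analytic closed form
$k\,\beta^{\alpha+1}\Gamma(\alpha+1)$ of the fitted gamma-variate rather than
numeric trapezoids, so recirculation never contaminates the first-pass area.
Tissue fits use the full curve with free arrival time; a window-restricted
mode exists. The AIF anchoring absorbs any global amplitude error of the
semi-quantitative arterial curve; the sensitivity mode (`rcbv_scaling =
FALSE`) skips the anchor and reproduces the expected behaviour of implausibly
high, variable raw rCBV.

**oSVD deconvolution.** The AIF is zero-padded to twice the series length and
embedded in a circulant matrix, making the deconvolution insensitive to
tracer arrival delays. Singular values are truncated per voxel by an
oscillation-index search (threshold 0.095, the standard literature value; the
method reference for the acquisition does not state one). The search ascends
from a conditioning floor of $10^{-4}$ of the largest singular value — the
unregularized pseudo-inverse of the padded circulant matrix is numerically
meaningless because its trailing singular values sit at rounding level — and
accepts the first solution below the threshold. Both the GE and the SE
tissue curves are deconvolved against the single GE-derived AIF: the arterial
input is defined on $\Delta R_2^*$ of large arteries, to which the SE echo is
insensitive, so an SE-derived AIF would not be physically meaningful. CBF is
reported in relative units; absolute calibration is out of scope.

**Diffusion.** The three orthogonal-direction signals are combined by
geometric mean, so the fitted decay constant equals the trace-mean ADC
exactly; the fit is ordinary least squares on log-signal over
$b \ge 200$ s/mm², which removes perfusion-sensitive low-b points. A
weighted mode (weights $\propto$ signal²) exists for noisy data.

**ROI rules.** NAWM loses a 3D zone of 1 cm around the ventricles (exact
anisotropic Euclidean distance transform, boundary inclusive: a voxel at
exactly 10 mm is excluded — the conservative reading of "a zone of 1 cm").
Distances are center-to-center on the voxel grid; at a 3 × 3.3 × 5 mm
acquisition scale sub-voxel surface modelling would suggest precision the
data do not have. Lesion masks are subtracted from every analysis ROI, and
NAWM is made disjoint from the hyperintensity mask. The 10% highest-rCBV
voxels are removed globally over the union of the analysis ROIs (a per-ROI
mode exists); the threshold is the 90th percentile under the
linear-interpolation quantile rule, the same rule used for all reported
IQRs.

**Statistics.** Group comparisons use OLS with normal-theory t intervals
(univariable; multivariable with age and sex; a group-by-age interaction with
age mean-centered before the product, keeping the group main effect
interpretable at the cohort mean age). The independent t-test pools
variances by default (classical Student); paired tests compare NAWM and
lesion values within patients. No multiple-testing correction is applied,
matching the analysis this package models; that is a documented limitation,
not a recommendation.

## The synthetic phantom

No patient data ship with the package, so a digital phantom generator
provides ground truth for every stage. Its forward model runs the analysis
equations in reverse: a gamma-variate arterial curve (α = 3, β = 2.5 s,
arrival one dynamic after the injection at dynamic 9 — a first-pass width of
about 10 s, typical of an antecubital power injection); tissue curves as the
AIF convolved with an exponential residue scaled so the analytic integral
ratio equals the per-tissue rCBV; $\Delta R_2^*$ linear in concentration
(calibrated so NAWM peaks at 10 s$^{-1}$, a physiologic scale at these echo
times); $\Delta R_2$ through the $2/3$-power law applied to the concentration
curve lagged by $\tau_{SE}$, whose sign sets the vortex-loop orientation;
signals by mono-exponential echo decay; diffusion volumes by
$\exp(-b\,D)$ identical across directions; optional Rician noise on the
magnitude signals with SNR defined on the pre-contrast baseline.

Default tissue parameters (Q 0.44/0.45/0.39/0.29 s$^{-1/3}$, rCBV
5.5/5.0/3.2/3.0%, D 8.5/7.5/8.0/11 × 10⁻⁴ mm²/s, MTT 4.5/4.5/5.5/6 s for
CGM/DGM/NAWM/WMH, $\tau_{SE}$ = −0.8 s, −0.9 s in the lesion) give
closed-form VSI values of 18.0 µm in NAWM and 31.9 µm in the lesion
compartment, consistent with published in-vivo ranges. The arterial voxel
amplitude (peak $\Delta R_2^*$ = 60 s$^{-1}$) is deliberately not consistent
with the tissue calibration: real AIFs underestimate arterial concentration
(partial volume, signal saturation), which is exactly why the NAWM anchor
exists; the phantom reproduces that situation with a global raw-rCBV factor
around 7.5 that the anchor absorbs to machine precision.

What the phantom does **not** emulate: motion, geometric distortion,
contrast leakage, recirculation, partial-volume mixing at tissue borders,
and spatially varying coil sensitivity. Passing recovery tests on the
phantom therefore demonstrates the correctness of the computational chain
under the stated forward model, not robustness to acquisition artifacts.

The SE forward model is a pure time-shifted power law of the GE compartment
— the minimal construction under which Q, VSI and MTI are all identifiable.
An explicit arteriole/capillary/venule mixture would be richer but is not
needed to validate the published pipeline.

## Numerical behaviour and known limitations

* **Window-mean bias of Q.** On the noise-free default phantom the pipeline
  recovers NAWM Q within 2% but sits at −2.5% (gray matter) to −3.0%
  (lesion) of truth: the Jensen gap of the window-mean ratio
  (−1.4% to −1.9% at these transit times), plus the interaction of the fixed
  window with the lagged SE curve (−0.2% to −1.6%). Sampling the same
  physiology at a 0.4 s dynamic interval roughly halves the bias. The bias
  is deterministic, shared across groups, and amplified 1.5-fold in VSI
  (which stays within 5% of its closed form).
* **Degenerate inputs.** Nonpositive signals make the log-ratio undefined;
  such voxel-timepoints propagate as missing and any window containing one
  invalidates the voxel rather than imputing (imputation would bias the loop
  areas). All-equal rCBV values remove no voxels in the high-rCBV filter.
  Zero-variance t-tests are errors, not p = 0. Ties in the peak search take
  the earliest dynamic.
* **Fit initialization.** Gamma-variate fits start from curve moments
  (arrival at the 10%-of-peak crossing, shape from the time-to-peak with
  α = 3, amplitude from the peak value) and refine by Levenberg–Marquardt;
  non-convergence is an error carrying the best-so-far parameters. Voxel
  fits that fail mark the voxel invalid.
* **Problem sizes.** The default phantom is 32 × 32 × 8 voxels with 100
  dynamics — large enough for every ROI rule to be non-trivial (about 3400
  analysed voxels) while keeping a full subject analysis around two seconds
  and the whole validation suite under a minute. Statistical calibration
  uses 2000 simulated null cohorts of n = 60 (40 patients / 20 controls,
  the design the power calculation of the modelled study targeted).
* **Curves are not smoothed** by default (the analysis this package models
  describes none); a width-3 moving-average flag exists for noisy phantom
  experiments.

## A worked subject

```{r, eval = FALSE}
library(vaimri)
phantom <- generate_phantom(phantom_config())
subject <- run_subject(phantom, vai_config(), outdir = "subject01")
subset(subject$summary, metric %in% c("q", "vsi", "mti"))
```

The emitted bundle contains the seven parameter maps (Q, VSI, MTI, rCBV,
CBF\_GE, CBF\_SE, D) as NIfTI, the per-ROI summary CSV, the VSI histogram
bins (2 µm bins to 50 µm, with the above-50 µm overflow counted separately)
and a provenance JSON recording every parameter value and exclusion count.
Cohort tables from `make_cohort()` feed `run_cohort()`, which produces the
univariable/multivariable/interaction regression tables, the paired
NAWM-versus-lesion tests and the VSI-IQR group comparison in one report.
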