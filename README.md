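# vaimri

Quantitative microvascular mapping from hybrid gradient-echo / spin-echo
dynamic susceptibility contrast MRI ("vessel architecture imaging", VAI),
for researchers studying the cerebral microvasculature — e.g. in cerebral
small vessel disease, where white matter hyperintensities are late-stage
markers and the underlying microvascular rarefaction is the quantity of
interest.

A combined GE–SE echo-planar sequence records both echoes during the first
pass of a gadolinium bolus. Because the spin echo is selectively sensitive
to microvessels (radius < 10 µm) while the gradient echo sees all vessel
sizes, the pair of relaxation-rate curves

&nbsp;&nbsp;ΔR₂\*(t) = −ln(S_GE(t)/S_GE,0)/TE_GE,&nbsp;&nbsp;
ΔR₂(t) = −ln(S_SE(t)/S_SE,0)/TE_SE

carries vessel-architecture information. Over a first-pass window of 4
dynamics before to 8 dynamics after the bolus peak the package computes,
per voxel:

* **Q = ΔR₂/(ΔR₂\*)^⅔** — vessel density index (s^−1/3);
* **VSI = 0.867·(D·rCBV)^½·Q^−3/2** — vessel size index, the
  weighted-average microvessel radius in µm;
* **MTI** — microvessel type indicator: the signed area of the vortex loop
  traced by (ΔR₂(t), ΔR₂\*(t)), positive (clockwise) for
  arteriole-dominated voxels, negative for venule-dominated ones;
* **rCBV** from analytic gamma-variate integral ratios, anchored so the
  normal-appearing white matter mean is 3.2%, with the 10% highest-rCBV
  voxels excluded from analysis;
* **CBF** (GE- and SE-derived) by block-circulant SVD deconvolution with
  oscillation-index regularization;
* **D** — parenchymal diffusion coefficient from a mono-exponential fit for
  b ≥ 200 s/mm².

Around the maps sit the ROI construction rules (1 cm periventricular
exclusion zone via an exact anisotropic Euclidean distance transform, lesion
mask subtraction), per-ROI summaries (mean, SD, median, IQR), the
group-level statistical layer (univariable / multivariable OLS with age and
sex, group×age interaction, paired NAWM-vs-lesion t-tests, VSI-IQR group
comparison), and a synthetic phantom generator with exact ground truth so
the entire chain is testable without patient data.

## Worked example

```r
library(vaimri)
phantom <- generate_phantom(phantom_config())   # 32x32x8 digital subject
subject <- run_subject(phantom, vai_config(), outdir = "subject01")
subset(subject$summary, metric %in% c("q", "vsi", "mti"))
```

```
  roi metric   mean n_voxels
  CGM      q  0.429     2120
  CGM    vsi 21.151     2120
  CGM    mti -4.499     2120
  DGM      q  0.439       84
  DGM    vsi 18.315       84
  DGM    mti -3.926       84
 NAWM      q  0.383     1176
 NAWM    vsi 18.474     1176
 NAWM    mti -1.296     1176
  WMH      q  0.281       32
  WMH    vsi 33.344       32
  WMH    mti -0.711       32
```

Reading the numbers: the lesion compartment (WMH) shows the expected lower
vessel density (Q 0.28 vs 0.38 s^−1/3 in NAWM) and larger vessel size (VSI
33 vs 18 µm); MTI is negative everywhere (venule-dominated tissue, as
encoded by the phantom's negative SE lag); NAWM rCBV is anchored at exactly
3.2%. The bundle written to `subject01/` contains the seven NIfTI maps, the
per-ROI CSV, VSI histogram bins and a provenance JSON.

Cohort-level statistics run on a wide per-subject table:

```r
cohort <- make_cohort(n_patients = 40, n_controls = 21, seed = 1)
results <- run_cohort(cohort, outdir = "cohort01")
```

A thin CLI over the same functions lives at `inst/cli/vai.R`
(`simulate`, `run-subject`, `run-cohort`).

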