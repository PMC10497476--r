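---
title: "Patlak parametric imaging and framing-protocol evaluation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patlak parametric imaging and framing-protocol evaluation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patlakpet)
```

## The model

For an irreversible tracer such as ¹⁸F-FDG, the two-tissue compartment
model with trapping (k4 = 0) admits the Patlak linearization: past an
equilibration time $t^*$,

$$\frac{C_T(t)}{C_p(t)} = K_i\,\frac{\int_0^t C_p(\tau)\,d\tau}{C_p(t)} + V,$$

where $K_i = K_1 k_3 / (k_2 + k_3)$ is the net influx rate and $V$ the
combined blood volume and reversible-compartment distribution volume.
`patlak()` estimates $(K_i, V)$ by ordinary least squares on the
transformed points; `patlak_voxelwise()` does the same for every voxel at
once, exploiting the fact that the abscissa depends only on the input
function, so the regression design is shared and the per-voxel solution is
a closed-form matrix expression. A consequence worth knowing: because OLS
is linear in the ordinates and the design is shared, the ROI mean of
voxelwise parameters equals the fit of the ROI-mean TAC to floating-point
precision. The test suite exploits this as an internal consistency oracle
(an independently coded OLS on the ROI-mean curve), mirroring the way
kinetic-modeling packages are validated against a reference implementation.

When the measured curve includes a fractional blood volume $V_b$,
$C_{meas} = (1-V_b) C_{tis} + V_b C_p$, the $V_b C_p$ term contributes a
constant to the ordinate and therefore moves only the intercept; the
fitted slope is $(1-V_b) K_i$. Ground-truth maps produced by the phantom
carry the tissue-level $K_i$; comparisons of fitted slopes against truth
must account for the $(1-V_b)$ shrinkage (the parameter-recovery tests use
$V_b = 0$ for this reason).

## Conventions and tunable parameters

* **Time units.** Schedules and file formats use seconds; all kinetic math
  uses minutes. $K_i$ is stored in mL/min/cm³ and printed also in
  μL/min/cm³.
* **Frame values** are time-averages of the decay-corrected concentration
  over the frame, attributed to the frame mid-time for all regression and
  integration. Frames are half-open intervals $[start, start+dur)$. This
  mid-time attribution is a documented choice; clinical packages do not
  state theirs.
* **$t^*$** (default 10 min; 30 min supported and exercised in the tests)
  is inclusive: frames with mid-time $\ge t^*$ enter the regression. The
  plasma integral always runs from 0 using all frames.
* **Plasma integral**: trapezoid on the (mid-time, value) pairs with a
  $(0,0)$ sample prepended — activity is zero at injection. Whether
  clinical tools prepend such an anchor is unstated; ours is documented
  and applied consistently (Patlak transform, AUC, resampling).
* **Weights**: unweighted OLS by default; `weights = "duration"` is
  available. Reference descriptions of the method mention no weighting.
* **Negative $K_i$** values are reported as-is; masking/filling is
  explicit (`fill` argument, default 0, optionally `NA`).
* **IDIF ROI**: a cylinder of 4-mm transversal (in-plane) radius around
  the supplied centerline; the vessel runs axially, so "transversal" is
  interpreted as x–y distance, with the z extent given by the centerline's
  z range. Voxels are included by a voxel-center test with no
  partial-volume weighting, consistent with analyses that apply no
  partial-volume correction. Plasma is taken equal to whole blood
  (ratio 1.0) by default, appropriate for FDG.
* **AUC over a common window** (default 0–60 min): when a protocol's last
  frame mid-time falls short of the window end, the last value is held
  constant to the window end. Without this, sparse-protocol AUC "errors"
  would be dominated by the integration-window truncation rather than by
  bolus undersampling, which is not what the comparison is meant to
  measure. The held tail is documented behavior, shared with
  `resample_if()`'s hold-last extrapolation rule.

## Rebinning

`rebin()` maps values onto a target schedule by overlap-duration-weighted
averaging. All six presets align on a 1-s grid, so rebinning from a 1-s
source is exact: the time integral over any aligned interval is conserved
to 1e-9 relative, rebinning onto the source schedule is the identity, and
coarsening contracts the value range (weighted means are contractions).
Weighting is by overlap duration only — the data are decay-corrected, so
no decay-weighting is applied; this differs slightly from count-based
rebinning of raw data, a documented surrogate bias. Misaligned boundaries
get fractional-overlap weights with a warning; a target frame strictly
inside one source frame is temporal upsampling and is refused. True
protocol comparisons on patient data reconstruct each protocol from list
mode; image-domain rebinning is this package's desk-scale surrogate.

## The synthetic phantom

The phantom emulates a decay-corrected 60-min FDG study on a
32 × 32 × 48 grid of 4 × 4 × 2.886 mm voxels: a straight 2-voxel-radius
blood cylinder along z (the descending-aorta analog), ellipsoidal organs,
and a spherical lesion.

* **Input function**: the tri-exponential bolus
  $C_p(t) = (A_1 t - A_2 - A_3)e^{-\lambda_1 t} + A_2 e^{-\lambda_2 t} +
  A_3 e^{-\lambda_3 t}$ with the widely used FDG population parameter
  values as synthetic defaults ($A_1 = 851.12$ kBq/mL/min,
  $A_2 = 21.88$, $A_3 = 20.81$ kBq/mL, $\lambda = 4.134, 0.0104,
  0.119$ /min). It reproduces the qualitative shape of measured aortic
  IDIFs — a sharp sub-minute peak and a slowly decaying tail — which is
  what the framing-sparsity experiments need.
* **Tissue curves** come from the two-tissue irreversible forward model,
  computed with an exact piecewise-linear convolution recurrence on a
  0.25-s grid. Region micro-parameters (in `inst/extdata/
  phantom_regions.csv`) were chosen once so the macro $K_i$ values match
  representative whole-body magnitudes (lesion 23.5, gray matter 36.5,
  white matter 11.6, lung 0.9, liver 3.7, spleen 4.5, bone marrow 9.8,
  kidney 5.5, muscle 1.6 μL/min/cm³) with $k_2+k_3$ between 0.3 and
  1.0 /min — fast enough equilibration that Patlak at $t^* = 10$ min is
  within a few percent of the asymptote.
* **Noise** is Gaussian with SD $\alpha\sqrt{\max(C, C_{floor})/\Delta t}$
  per voxel and frame ($C_{floor} = 0.01$ kBq/mL), i.e. variance
  proportional to activity and inversely proportional to frame duration —
  a count-statistics surrogate appropriate for decay-corrected
  reconstructions. $\alpha = 1$ by default, giving a few percent noise on
  late 2-min frames and tens of percent on 1-s bolus frames at the voxel
  level; no published noise magnitude exists for the scanner setting this
  emulates, so $\alpha$ is a free parameter, not a calibration.
* Phantoms are generated **directly on the requested schedule**
  (frame-averaged noiseless curves plus schedule-specific noise) rather
  than by rebinning a simulated 1-s image. The two constructions follow
  the identical variance law — averaging independent Gaussians over
  sub-frames reproduces $\alpha^2 C/\Delta t$ — and the direct route keeps
  the multi-seed, six-protocol experiments fast and memory-light. The
  TAC-level equivalence of rebinning and direct frame-averaging is
  asserted in the test suite.
* Optional per-frame 3D Gaussian smoothing (separable, edge-renormalized)
  mimics reconstruction-time filtering; off by default.

What the phantom does **not** emulate: scanner sensitivity profiles,
attenuation/scatter physics, reconstruction artifacts, motion, plasma
metabolites, or partial-volume effects. Passing tests therefore
demonstrate correctness of the estimators and pipeline on data satisfying
the model assumptions, not robustness to all the physics of real
reconstructions.

## The protocol-comparison experiment

`run_full_study()` treats replicate phantoms with different noise seeds as
"subjects" (default 10, mirroring typical study sizes). Per protocol and
replicate, the IDIF is extracted from that protocol's own data (a
`shared_if` mode resamples the reference IDIF onto the other protocols
instead, for input-function-controlled comparisons). Relative differences
are reported in percent versus the reference protocol (default P-100f),
pooled over ROIs × replicates; paired t-tests compare each protocol's
per-ROI $K_i$ against the reference across replicates; raw p-values are
reported without multiplicity correction, matching common practice in
protocol-comparison studies.

One design point was genuinely open: which two samples the variance F-test
should compare. Comparing a protocol's relative-difference vector against
the *reference's* is degenerate — the reference's own relative differences
are identically zero. We therefore compare each protocol's
relative-difference sample against that of the least-sparse non-reference
protocol, which reproduces the intended "does sparsity inflate the spread
of differences" question and also supports protocol-vs-protocol
significance statements. This is our reading, documented rather than
asserted as anyone's certain intent.

## Numerical choices

* Sub-grid for function-based frame averaging: 0.05 s (trapezoid error on
  the steep bolus ramp is quadratic in the step; 0.05 s keeps the first
  1-s frame's average within 0.01% of adaptive quadrature). Sampled-curve
  averaging uses the exact cumulative trapezoid of the 0.25-s simulation
  grid, whose boundaries align with all preset frame edges.
* The exponential-kernel convolution in the forward model uses `expm1`
  for stability at small $\beta h$ and an update that is exact for
  piecewise-linear inputs; accuracy is limited only by the input sampling
  (verified against a stiff ODE solver to 0.1%).
* Degenerate inputs: fits with all-equal abscissae error; nonpositive
  plasma frames are dropped with a warning and fewer than two usable
  frames is an error; empty cylinder masks error with a diagnostic rather
  than returning silently empty TACs; identical paired samples report
  $t = 0, p = 1$ (zero-variance differences with nonzero mean report an
  infinite statistic with a warning).
* All randomness flows from explicit integer seeds; phantom generation is
  bit-reproducible, and the study runner derives per-replicate,
  per-protocol seeds from the base seed.

## Problem sizes used in the checks

The oracle-equivalence experiment uses the default 32 × 32 × 48 phantom,
ten noise seeds and all six presets (540 ROI fits per parameter); the
recovery and AUC checks are noiseless single-phantom computations. These
sizes were chosen as the smallest geometry that exercises the cylindrical
ROI, all organ regions, and every preset's frame structure.

## Known limitations

* Rebinning operates on reconstructed images, not list-mode data; the
  documented decay-weighting bias applies if inputs are not
  decay-corrected.
* The Patlak intercept of the forward model approaches its asymptote
  slowly for small $k_2+k_3$; intercept comparisons at $t^* = 10$ min
  carry a transient bias for such regions (slope bias is much smaller).
* The IDIF cylinder uses voxel-center membership; with 4-mm in-plane
  voxels and a 4-mm radius, the mask is 5 voxels per slice and sits well
  inside the 8-mm phantom vessel, so no partial-volume contamination is
  simulated or corrected.
* Micro-parameter fitting (nonlinear compartment models), Logan/RE plots,
  time-delay and dispersion correction, and automatic vessel segmentation
  are out of scope.
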