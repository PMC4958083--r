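---
title: "Image-based red-marrow dosimetry: model, numerics and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-based red-marrow dosimetry: model, numerics and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marrowDose)
```

## The problem

Red bone marrow (RM) is the dose-limiting organ in most radio-immunotherapy
regimens. Its absorbed dose is conventionally estimated from serial plasma
samples: the plasma time-activity curve is multiplied by a fixed
red-marrow-to-plasma concentration ratio of 0.19. That ratio is not constant
in reality, so a plasma-based estimate can systematically understate the
marrow dose. With hybrid PET/CT, the marrow activity concentration can
instead be measured directly in the lumbar vertebrae (LV), the most
accessible large reservoir of active marrow. `marrowDose` implements that
image-based chain end to end: automatic delineation of the vertebrae on
low-dose CT, extraction of the intraosseous (marrow-bearing) volume, mapping
of that volume onto the serial PET scans, and MIRD-schema dosimetry down to
self and total RM absorbed dose per unit injected activity. A synthetic
CT/PET phantom with analytic ground truth ships with the package so the
whole chain is testable without patient data.

## Data model and grid conventions

CT volumes carry Hounsfield units on the native low-dose grid
(1.17 x 1.17 x 5 mm); PET volumes carry Bq/mL on a 4 mm isotropic grid,
one volume per scan time (nominally 1, 24, 48, 96 and 144 h post
injection). Voxel `(i, j, k)` (0-based) sits at `origin + (i,j,k) * spacing`
mm; voxel centers are the sampling points everywhere (interpolation,
rasterization, cylinder and box membership). `rebinTrilinear()` resamples
the CT onto the PET grid with the output anchored at the input origin and
`ceil(extent / target)` voxels per axis, so a mask drawn on the rebinned CT
lies voxel-for-voxel on PET. Out-of-support interpolation queries clamp to
edge values rather than inventing data. Study metadata with no natural NIfTI
home (modality, acquisition time, injected activity, patient weight) lives
in a JSON sidecar.

## Automatic delineation

Delineation runs per axial slice on the rebinned CT, in three stages
mirroring the contours `c1 -> c2 -> c3`:

1. **Loose region (c1).** A physical box around the vertebral column,
   dilated by about 1 cm (whole voxels, rounded outward). This seeds the
   contour and bounds everything downstream; voxels outside c1 are never
   segmented.
2. **Outer bone contour (c2).** A two-region piecewise-constant
   (Chan-Vese-type) active contour with a distance-regularization term:

   `E(phi) = muReg R(phi) + muLength L(phi)
     + lambdaIn int_{phi>0} (I - cIn)^2 + lambdaOut int_{phi<0} (I - cOut)^2`

   where `phi` is a level-set function (positive inside), `L` the smoothed
   contour length, and `cIn`, `cOut` the region mean intensities recomputed
   every iteration under the smoothed Heaviside weighting
   (`H_eps(x) = (1 + (2/pi) atan(x/eps)) / 2`, width `eps = 1.5` voxels).
   The evolution runs a fixed 30 iterations per slice. The inside region,
   intersected with c1 and with interior holes filled (c2 is defined by its
   *outer* contour), is the per-slice bone region; stacking slices gives the
   3D mask.
3. **Intraosseous volume (c3).** Per-slice binary erosion of c2 by a
   cross-shaped structuring element reaching `k` voxels vertically and
   horizontally, `k` in {1, 2, 3} (small / medium / large kernel,
   3 being the default), removing the cortical shell so only the
   marrow-bearing interior remains. A square element is available as an
   option; erosion acts on the rebinned 4 mm grid, since the entire
   pipeline runs there.

### Numerical scheme

Several choices make the 30-iteration budget reliable; they are the
package's own design, exposed through `contourParams()`:

* **Intensity normalization.** Each slice is affinely rescaled to
  `[0, 1]` before evolution, so the region-fit weights are independent of
  the HU range and the evolution is invariant to intensity offsets. Region
  means are reported back in HU in the diagnostics.
* **Double-well distance regularization.** The naive penalty
  `R(phi) = int (|grad phi| - 1)^2 / 2` acts as *backward* diffusion
  wherever `|grad phi| < 1`; at useful step sizes this shreds flat regions
  into checkerboards. The double-well variant keeps the diffusion rate
  bounded and is integrated with its own stable step `muReg = 0.2`
  (stability requires < 0.25).
* **CFL-capped data step.** The Dirac-weighted data and length forces are
  scaled by `dt` and then capped at one voxel per iteration. The cap makes
  the scheme stable regardless of image contrast, while a large `dt`
  (default 300) lets weak contrast — for example soft-tissue background a
  few voxels inside the loose region, where the force is two orders of
  magnitude smaller than at a cortical edge — still advance the contour.
  Without the cap, a step size large enough to cross the 1 cm loose margin
  in 30 iterations overshoots at bone edges and destabilizes.
* **Slice gating.** The evolution is strictly per-slice, so slices of c1
  that contain no bone (intervertebral gaps) present a structureless image
  in which a two-region fit returns an arbitrary split. Each connected
  component of a slice result is therefore kept only if its mean CT value
  exceeds `minBoneHU` (default 120 HU, roughly midway between soft tissue
  at ~40 HU and a vertebral cross-section at ~200 HU, so that a kept
  component is majority bone). Constant slices return an empty region with
  a degenerate-convergence warning.
* **Polarity.** The contour is seeded enclosing the vertebra and the
  inside region is returned; if the converged inside mean falls below the
  outside mean — a degenerate seeding the normal workflow never produces —
  the complement is returned with a warning, making the resolution
  deterministic.

Slices whose c3 area is a strong outlier are visible in the per-slice
diagnostics (`iterations`, region means, kept voxel counts); the package
deliberately does not edit contours post hoc.

## Manual VOIs and evaluation

The manual comparator is the radiologist's construction: five cylindrical
VOIs of 1.9 cm diameter and 2 cm height, one per vertebral body; on the
4 mm grid a 2 cm cylinder spans exactly five slices. Rasterization is by
voxel-center inclusion. Note the nominal volume of five such cylinders is
5 x 5.67 = 28.35 mL continuous; voxelization on a 4 mm grid biases a single
cylinder's volume upward by up to ~19 % when centered on a voxel center —
an inherent property of center-inclusion rasterization at this grid
coarseness, which is why volume-accuracy checks use a finer grid. In the
phantom workflow the cylinders are auto-placed at the true vertebral-body
centroids, standing in for the operator. Overlap between automatic and
manual VOIs is the Dice similarity coefficient
`DSC = 2|A n M| / (|A| + |M|)` by voxel counts, computed by default over
the union of all five segments.

## Dosimetry chain

For a region with time-activity samples `C(t_i)` (Bq/mL):

* **Cumulated concentration**: trapezoidal integral over the sampled
  range, plus the unmeasured lead-in `[0, t1]`, plus a physical-decay tail
  `C(t_last) / lambda` after the last scan. The lead-in defaults to
  constant back-extrapolation (a `t1 x C(t1)` rectangle); with the first
  scan at 1 h this contributes well under 1 % of the total for Zr-89
  kinetics, and `linear-from-zero` and `exclude` variants are available.
  PET values are treated as the true concentration at scan time, so decay
  between scans is already in the measured curve and only the tail needs
  the physical-decay assumption.
* **Residence time**: `tau = A_cum / A_injected` hours, with the region's
  cumulated concentration converted to cumulated activity via its volume.
  For red marrow the reference-anatomy marrow volume from the S-value
  configuration is used, matching the MIRD convention. Integrating
  concentration first and scaling by volume afterwards is mathematically
  identical for a fixed volume.
* **Remainder of body**: the maximum possible residence time under
  physical decay alone is `T_half / ln 2`; the remainder receives that
  maximum minus the source-organ sum, so the balance closes exactly by
  construction, and a source sum exceeding the maximum is reported as an
  inconsistency naming the excess.
* **Weight scaling**: `tau x (reference weight / patient weight)`, the
  conventional reference-anatomy correction; it is isolated in
  `scaleByWeight()` so an alternative convention can be swapped in.
* **Dose**: `self = S(RM<-RM) tau_RM` and
  `total = sum_s S(RM<-s) tau_s + S(RM<-RB) tau_RB`, in mGy/MBq. S values,
  the reference marrow volume and reference body weight are user-supplied
  configuration (a clearly-labelled synthetic placeholder template ships in
  `inst/extdata/`); the package does not compute or claim any S values.
* **Comparators**: the plasma method multiplies a plasma curve by the
  fixed 0.19 ratio; `fitEffectiveHalfLife()` fits
  `ln C(t) = ln C0 - lambda_eff t` by least squares and returns
  `ln 2 / lambda_eff`, which is below the 78.41 h physical half-life of
  Zr-89 whenever biological clearance is present.

## The synthetic phantom

`phantomSpec()` emulates the study's acquisition geometry: five vertebral
bodies as cylinders (radius 20 mm, height 28 mm, 10 mm gaps — typical
lumbar dimensions) with a 3 mm cortical shell at 400 HU, trabecular
interior at 120 HU and soft-tissue background at 40 HU, on the native CT
grid, with seeded additive Gaussian CT noise. The matched PET series puts
`C(t) = C0 2^(-t / T_eff)` (defaults `C0 = 2000` Bq/mL, `T_eff = 73` h)
into the marrow, 5 % of that into the background, and applies a Gaussian
point-spread (7 mm FWHM by default) and multiplicative noise, on the same
4 mm grid the rebinned CT produces. Identical seeds give bit-identical
phantoms.

Two modelling notes. The cortical shell is radial only: real endplates are
sub-millimetre against 5 mm slices, whereas voxel-scale axial caps would
fill whole slices with cortical bone that in-plane erosion could never
remove. And all analytic truth masks (any grid) come from
`truthMasks()`, so segmentation accuracy is measured against geometry, not
against another rasterization pipeline.

What the phantom does *not* emulate — and hence what passing tests do not
show about patient data: anatomical vertebra shape and posterior elements,
neighbouring bony structures, beam hardening, PET scatter and
reconstruction artifacts, patient motion, and spatial red/yellow marrow
heterogeneity (activity is homogeneous throughout the intraosseous
volume). Validation on the phantom demonstrates correctness of the
operators and the chain, not clinical segmentation performance.

## Problem sizes and run times

The shipped tests and the acceptance script run the full chain on the
default five-vertebra phantom (native CT 77 x 77 x 43, rebinned/PET grid
23 x 23 x 54), twice (noise-free and 20 HU noise), plus 100-replicate
parameter-recovery and oracle checks; the whole suite completes in well
under a minute on a single core. The phantom is intentionally compact in
the transaxial plane — the vertebral column plus a soft-tissue margin —
since everything outside the loose region is never touched.

## Known limitations

* The contour is two-phase and per-slice; it finds the outer bone contour
  but cannot separate posterior elements from the body, which is why the
  manual cylinders, not c2, serve as the clinical-style comparator.
* The 15 % of cases needing manual VOI adjustment in clinical practice
  have no counterpart here; the package only surfaces per-slice
  diagnostics.
* Whether the original implementation eroded on the native 1.17 mm or the
  rebinned 4 mm in-plane grid is not documented; erosion here acts on the
  4 mm grid (the whole pipeline's grid). On the native grid the same
  kernel sizes would remove a much thinner cortical layer.
* The dosimetry treats a single marrow source plus remainder of body by
  default; additional organs enter simply as extra entries in the
  residence-time set and S-value table.
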