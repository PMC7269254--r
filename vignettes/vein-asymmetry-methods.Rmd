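---
title: "Automated cerebral vein quantification on SWI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated cerebral vein quantification on SWI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Deoxygenated venous blood shortens T2\*, so cerebral veins appear as thin
hypointense structures on susceptibility-weighted imaging (SWI) and, more
conspicuously, on its minimum intensity projection (MinIP). In several
conditions — most prominently migraine with aura during the acute phase —
one hemisphere can transiently show more prominent focal veins than the
other. Radiologists judge this *visual venous asymmetry* (VVA)
qualitatively; `swivein` implements a fully automated counterpart that
segments veins per hemisphere, measures their volume, and turns the
inter-hemispheric difference into a calibrated classifier.

## The measurement model

All volumes are assumed co-registered on a symmetric template grid whose
mid-sagittal plane is world $x = 0$ (spatial normalization is an input
contract, not part of the package; `resample_to_grid()` provides affine
resampling when an affine is available). For each subject the pipeline
computes, per axial slice and separately for SWI and MinIP:

1. **CLAHE** — contrast-limited adaptive histogram equalization restricted
   to the bounding box of the in-slice brain mask. Tile mappings are
   clipped-histogram CDFs, bilinearly interpolated between tile centres.
2. **Otsu threshold** — the histogram cut over the in-mask pixels that
   maximizes between-class variance. Restricting to in-mask pixels matters:
   the dark background outside the head would otherwise dominate the
   histogram and the threshold would collapse.
3. **Binarize/invert** — veins are dark, so foreground is
   `pixel < threshold` (the classical "invert then binarize" fused into one
   strict comparison; a pixel exactly at the threshold is background).
4. **Top-hat** — white top-hat on the binary slice,
   $I - \mathrm{open}(I, S)$ with a $3\times3$ square structuring element
   by default: any connected structure that contains a full translate of
   $S$ is removed, which deletes the bulky inverted background while thin
   vein cross-sections survive.

The SWI candidate map $I_1$ and the MinIP candidate map $I_2$ are then
intersected with the hemisphere masks $H$:

$$V_\mathrm{left} = I_1 \cap I_2 \cap H_\mathrm{left}, \qquad
  V_\mathrm{right} = I_1 \cap I_2 \cap H_\mathrm{right}.$$

The absolute cerebral vein volume (ACVV, ml) of a hemisphere is its voxel
count times the voxel volume. The hemisphere with the larger ACVV is the
calculated dominant hemisphere (CDH); the asymmetry statistics are

$$\mathrm{DCVV} = \mathrm{CDH} - \mathrm{CNDH} \ \mathrm{(ml)}, \qquad
  n\mathrm{DCVV} = 100 \cdot \frac{\mathrm{DCVV}}{\mathrm{CDH} + \mathrm{CNDH}}\ (\%).$$

A cohort of DCVV scores with reader VVA labels is calibrated by ROC
analysis: candidate cutoffs are midpoints between consecutive sorted unique
scores, a subject is positive when its score is *strictly greater* than the
cutoff, and the reported cutoff maximizes the Youden index
$J = \mathrm{sens} + \mathrm{spec} - 1$ (ties toward the smaller cutoff).
`classify_vva()` uses the same strict rule, so ties map to "no VVA".
Calibration is in-sample; no cross-validation is claimed.

Group means of per-subject nDCVV are *not* the nDCVV of group-mean volumes
(the ratio is nonlinear), so the package always computes nDCVV per subject
before any averaging.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| CLAHE tile grid | 8 × 8 | tiles | common default of the operation; tiles are reduced so that each spans ≥ 8 px/axis (equalizing a handful of pixels amplifies noise on apex/base slices) |
| CLAHE clip limit | 0.01 | fraction of tile pixels | common default; lower values suppress noise amplification but also reduce adaptivity |
| Otsu bins | 256 | bins | standard 8-bit histogram resolution |
| Top-hat element | 3 × 3 square | pixels | the standard neighbourhood of the binary operation; a disk of radius *r* mm is available |
| MinIP slab | 14 mm, sliding | mm | clinical slabs are 12.8–16 mm; the sliding mode materializes one slab per slice so the SWI/MinIP intersection is voxelwise |
| Exclusion ellipsoid | centre (0, −18, 8), radii (32, 38, 26) | mm, template space | the thalami and basal ganglia have intrinsically low SWI signal and would be falsely segmented; no atlas is assumed, and a user mask can replace the ellipsoid |
| Midline tolerance | 1e−6 | mm | voxels centred exactly on x = 0 belong to neither hemisphere (no double counting) |

## Numerical choices

* **Ties and determinism.** Otsu ties break toward the smallest threshold;
  binarization is strict at the threshold; ROC cutoff ties break toward the
  smallest cutoff; equal hemispheric volumes are reported as `"tie"` and
  classified as "no VVA". Two runs on identical input are bit-identical.
* **Exact mirror equivariance.** Flipping the inputs across the
  mid-sagittal plane must swap the left/right outputs *exactly*, and the
  test suite asserts identity, not approximate equality. CLAHE is the only
  stage where this is delicate: tile membership and interpolation weights
  are therefore computed in integer arithmetic with mirror-symmetric tie
  rules (a pixel centre exactly on an interior tile edge is assigned toward
  the image centre; a centre on both a tile edge and the image midline is
  split half/half between the two tiles), and the four-term interpolation
  sum is ordered so that a left-right mirror only commutes additions, which
  floating point arithmetic preserves.
* **Boundary handling.** Morphological erosion pads with background zeros,
  so foreground touching the image border erodes; implementations differ on
  this point, which is why it is pinned and tested.
* **Degenerate slices.** A slice whose in-mask region is empty or constant
  cannot be thresholded; it contributes no vein voxels and is recorded in
  `skipped_slices` rather than failing the run.
* **MinIP modes.** Sliding slabs nest, so output values never increase with
  slab thickness; block slabs of different thickness do not nest, and only
  the block mode is idempotent under re-projection (re-projecting a sliding
  MinIP widens the effective window). Both modes are provided because
  scanner MinIPs may come as non-overlapping blocks.

## What the phantom emulates

`generate_phantom()` builds a mirror-symmetric ellipsoidal "brain" of
homogeneous bright parenchyma on a dark background, draws each vein as a
smooth random polyline tube clipped to its hemisphere, multiplies by a
smooth low-order bias field, and adds Gaussian noise; the MinIP is derived
with `compute_minip()`. Defaults: 96 × 112 × 80 grid at 1 mm (≈ 0.9 M
voxels, so a full generate-and-quantify run takes a few seconds), 45 veins
per hemisphere, tube radius 0.5–1.2 mm (1–2.4 voxel diameters), 60 %
intensity drop, 10 % bias amplitude, 3 % noise.

Two generator choices deserve explanation:

* **Vein orientation.** Walks are seeded radially inward with a superior
  bias, mimicking superficial cortical veins ascending toward the dural
  sinuses. On this deliberately small grid the 14 mm slab is relatively
  about twice as thick as on a full-size brain, so isotropically oriented
  veins would produce long in-plane MinIP streaks that merge into bulky
  structures — which the top-hat then removes, *reducing* measured volume
  on the denser hemisphere. Radially oriented veins project compactly, the
  regime real anatomy occupies.
* **Vein load.** 45 veins per hemisphere put the measured ACVV near 1.5 %
  of hemisphere volume, matching the proportion implied by in vivo
  hemispheric vein volumetry (≈ 2 %). Hemispheric asymmetry is controlled
  by the left/right *count* ratio; scaling vein caliber instead was
  rejected because thicker veins are exactly what the 3 × 3 top-hat
  removes.

What the phantom does **not** emulate: real parenchymal texture
(grey/white contrast, sulcal CSF), susceptibility physics (dipole blooming,
TE and field-strength dependence of vein contrast), Rician noise (available
via flag conceptually, Gaussian by default at these contrasts), flow and
pulsation artifacts, or pathology other than vein load asymmetry. Passing
phantom tests therefore demonstrates that the implementation realizes the
method faithfully (containment, equivariance, determinism, monotone
asymmetry recovery) — not that the method's clinical operating point
transfers to real images.

A known property inherited from the method itself: Otsu always finds a
threshold, even in a unimodal noise histogram, so a noise-dependent
false-positive floor exists in both hemispheres. On phantoms it is
symmetric in expectation and the measured no-asymmetry nDCVV floor (≈ 9 %
at default noise) sits near the no-VVA cohort values reported in vivo
(≈ 4 %); the dominant-side call remains reliable once true nDCVV exceeds
about 15 %.

## Worked example

```{r, eval = FALSE}
library(swivein)

ph <- generate_phantom(phantom_spec(n_veins_left = 90, n_veins_right = 45,
                                    seed = 42))
q <- quantify_phantom(ph)
q$result
#> ACVV left 2.611 ml, right 1.750 ml | CDH left | DCVV 0.861 ml | nDCVV 19.74%
c(truth_side = ph$true_side, true_ndcvv = round(ph$true_ndcvv, 1))
#>  truth_side true_ndcvv
#>      "left"       "34"

tab <- sweep_asymmetry(phantom_spec(), levels = c(1, 2),
                       seeds_per_level = 10, base_seed = 99L)
calibrate_vva(data.frame(dcvv_ml = tab$measured_dcvv,
                         vva_label = tab$level > 1))
```

## Problem sizes used by the test and acceptance suites

Unit tests run on 48 × 56 × 40 phantoms; the acceptance suite evaluates the
default 96 × 112 × 80 grid with 40 seeds for dominant-side recovery and a
3-level × 20-seed sweep for asymmetry monotonicity; the acceptance script
uses a 3-level × 8-seed sweep. These sizes keep a complete run in the
minutes range on a single CPU while leaving enough replicates for the
batch statistics to be stable.

## Known limitations

* Spatial normalization quality is assumed, not checked; residual
  misregistration biases the hemispheric split.
* The deep-grey exclusion is a geometric ellipsoid, not an atlas.
* The top-hat removes any vein wider than the structuring element in both
  in-plane directions; very dilated veins are under-segmented.
* The false-positive floor rises with noise; at extreme noise the Otsu
  threshold is dominated by the noise distribution.
* Calibration (`roc_youden`) is in-sample by design.
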