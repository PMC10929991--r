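---
title: "Size-specific dose estimation for thoracic CT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Size-specific dose estimation for thoracic CT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssdect)
```

## The problem

The volumetric CT dose index (CTDIvol) printed by a scanner describes the
tube output in a standard acrylic phantom, not the dose to the patient on
the table. The size-specific dose estimate (SSDE) corrects it with a
patient-size-dependent conversion factor,

$$\mathrm{SSDE} = f(D) \times \mathrm{CTDI_{vol}},
\qquad f(D) = 3.704369\, e^{-0.03671937\, D},$$

where $D$ is a patient diameter in cm and the exponential coefficients are
the standard fit for the 32-cm PMMA body phantom at 120 kVp. `ssdect`
implements two diameters on axial thoracic slices and the automation around
them:

* the **water-equivalent diameter** (TG220),
  $D_w = 2\sqrt{\left(\tfrac{\overline{CT}}{1000}+1\right) A/\pi}$, from the
  mean CT number $\overline{CT}$ and area $A$ of the body region; and
* the **corrected effective diameter**,
  $D_{e\!f\!f}^{corr} = \sqrt{AP^{corr}\times LAT^{corr}}$, where the
  anterior–posterior and lateral body dimensions are measured along central
  chords and each tissue segment is re-weighted by its relative electron
  density, $\sum_j \rho_e(j)\, l(j)$ with $\rho_e$ = 0.3 (lung),
  1.0 (soft tissue), 1.2 (bone).

The thorax is the region where the two disagree most — air-filled lungs make
the geometric diameter overstate attenuating size — which is why the
electron-density correction matters there.

## Pipeline

Per slice: segment into {background, lung, other tissue, bone} → extract the
body mask (union of non-background labels, hole-filled so internal air stays
inside, largest connected component so couch fragments are dropped) → find
the centroid and the two orthogonal measurement chords → $D_w$ from the
body-ROI statistics, $D_{e\!f\!f}^{corr}$ from the per-chord tissue runs →
$f$ and SSDE for both diameters. All diameters are processed in cm, pixel
spacings in mm at the I/O boundary, doses in mGy. Full floating precision is
kept internally; only the reporting layer (CSV reports) rounds to one
decimal, the precision of clinical dose tables.

Two segmenters sit behind the same interface:

* `threshold_segment()` — deterministic Hounsfield thresholds (body
  $> -400$ HU, lung $< -300$ HU, bone $> +150$ HU, the rest soft tissue).
  It needs no training, is reproducible out of the box, and is therefore
  the default and the reference standard in tests.
* a trainable **residual U-Net** — five residual convolution blocks in the
  down-sampling path (two 3×3 convolutions plus an identity or 1×1
  projection shortcut), 2×2 max pooling between them, a symmetric 2×
  nearest-neighbour up-sampling path with skip concatenations, and a 1×1
  convolution + softmax head over the four classes. The implementation
  (im2col + GEMM convolutions, Adam, backpropagation) is in compiled code
  under `src/`.

## Geometry choices

**One central chord per axis.** AP and LAT are measured along single chords
through the body centroid, matching the manual ruler-on-image procedure the
automation replaces, rather than averaging parallel rays.

**Axis naming.** The chords lie along the principal axes of the body mask
(computed in physical coordinates, so anisotropic pixels are honoured). The
chord whose direction is closer to the image column axis is *named* LAT, the
other AP; since thoraces are wider than deep, LAT is in practice the major
axis. Naming by image orientation rather than by eigenvalue order keeps the
measurement consistent under rotation of the raster: rotating a slice by 90°
swaps the AP and LAT values. Near-isotropic masks (principal axis ratio
within 1%) fall back to the exact image axes, since the principal directions
of a near-circular mask are numerically meaningless.

**Sampling.** Chord endpoints are found by marching from the centroid at
half-pixel steps and refining the boundary crossing by bisection; tissue
runs are sampled at ≤ 0.5-pixel steps with nearest-neighbour label lookup.
Run lengths therefore carry a quantisation error of about half a pixel, and
chord-length conservation (runs summing to the geometric chord) holds to one
pixel. The 90° swap likewise holds to one pixel rather than bitwise: a
nearest-neighbour lookup at an exact half-pixel coordinate cannot round
mirror-symmetrically under any deterministic tie-break.

**Internal air.** Air pockets inside the body (trachea, oesophagus) scanned
along a chord are scored as lung, the closest attenuation class available —
the segmentation has no "internal air" class. The $D_w$ ROI is the
hole-filled body mask, so internal air does contribute to the mean CT
number, as TG220's outer-contour practice intends.

## The synthetic phantom generator

Real patient data cannot ship with a package, so the test and training data
source is a parametric thorax: an elliptical soft-tissue body (HU 0) on an
air background (−1000), two lung ellipses (−700) mirrored about the AP axis,
and a posterior vertebral disc (+300) centred on the AP chord. Because every
region is an exact ellipse or disc, the mean CT number, body area, chord
intersections — and hence $D_w$ and $D_{e\!f\!f}^{corr}$ — have closed
forms. Ground truth is computed from the geometry, *not* from the raster, so
rasterisation and pipeline error are measurable quantities with targets
(body area converges to $\pi ab$; the threshold pipeline recovers $D_w$
within 1% and $D_{e\!f\!f}^{corr}$ within 2% on noiseless 1-mm cohorts).

`generate_cohort()` draws the body aspect ratio, relative lung size and
relative bone size from narrow anatomical ranges and then solves the body
scale exactly for a target corrected effective diameter sampled uniformly
over 15.9–26.7 cm, the adult range the method is intended for. Defaults:
512×512 rasters at 1 mm pixels (a standard CT matrix; the largest in-range
bodies need the 51 cm field of view), CTDIvol uniform over 4.2–10.5 mGy, and
additive Gaussian HU noise with σ = 20 HU floored at −1024, a plausible
quantum-noise level for a filtered-back-projection chest protocol. The
phantom HU values sit ≥ 100 HU inside the threshold segmenter's brackets, so
on noiseless rasters the threshold segmenter reproduces the ground-truth
class map pixel-for-pixel — the "oracle equivalence" the test suite asserts.

What the phantom does *not* emulate: anatomical texture, ribs and sternum,
contrast enhancement, tube-current modulation, reconstruction artefacts,
truncated fields of view. Passing tests on phantoms therefore demonstrate
the correctness of the measurement and dose mathematics and the viability of
the segmentation-to-SSDE chain, not clinical segmentation performance.

## Network training choices

The published architecture is kept at desk scale: 128×128 inputs, encoder
channels 8–64, ~30 epochs on 50 phantoms with a 20% holdout, no pre-trained
weights (a configuration hook allows plugging a pre-trained encoder). The
optimiser is Adam (learning rate 10⁻³, minibatch 1); HU are clipped to
[−1000, 1000] and scaled to [0, 1] — a fixed physical window, so
normalisation does not depend on the image at hand. All randomness (weight
initialisation, the train/holdout split, shuffling) derives from one seed
and training is bit-reproducible: the compiled backend is single-threaded
deterministic code.

The loss is per-pixel multi-class cross-entropy with **median-frequency
class weighting** by default. The vertebral disc occupies ~0.3% of pixels;
with unweighted cross-entropy the bone class is simply not learned within
the epoch budget (its IoU stays at 0 while the loss keeps shrinking on the
other 99.7% of pixels), which silently destroys the bone term of the AP
correction. Median-frequency balancing gives each present class a gradient
share proportional to the median/its frequency; weighting can be switched
off (`class_weights = "none"`) or set manually.

IoU is reported per class with the convention that a class absent from both
prediction and truth scores 1, so phantoms without bone do not zero the
mean; the convention is stated wherever reports are printed.

## Problem sizes in the shipped tests

The test suite exercises: the closed-form dosimetry against hand-evaluated
values; geometry on constructed rasters (ellipse chords, rotated ellipses,
run scanning) and against the phantom closed forms; a noiseless 100-phantom
cohort at 1 mm for analytic recovery; threshold-oracle equivalence and
σ = 20 noise robustness; a 50-phantom, 30-epoch training run at 128×128
(the long test, a few minutes of CPU); and the agreement statistics against
brute-force formula evaluation. The training sizes are chosen so the whole
suite stays in the minutes range on a laptop core while still spanning every
pipeline stage end to end.

## Known limitations

* The conversion-factor coefficients assume the 32-cm body phantom at
  120 kVp; other tube voltages or the 16-cm head phantom need different
  coefficient pairs, which the package deliberately does not ship.
* Single-slice estimation: no multi-slice $D_w$ profiles and no
  truncated-FOV compensation.
* The DICOM reader covers uncompressed little-endian single-frame CT — the
  subset the fixture dialect mirrors — not encapsulated transfer syntaxes.
* Phantom realism as above; per-class accuracies on real thoraces cannot be
  inferred from phantom IoU values.
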