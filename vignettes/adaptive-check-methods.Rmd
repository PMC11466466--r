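---
title: "Methods: fraction-day plan checks from CBCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fraction-day plan checks from CBCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

During a fractionated course of pelvic radiotherapy the anatomy of the day
differs from the planning CT: the bladder fills or empties, the rectum
changes shape, and the cervix/uterus moves with them, sometimes by more
than the CTV-to-PTV margin.  Online adaptive replanning fixes this but is
expensive; most fractions do not need it.  `adaptcheck` answers the
triage question quantitatively: given the planning CT (with plan,
structures and reference dose) and the fraction-day CBCT, it rebuilds the
contours and the dose on today's anatomy and compares the clinically
decisive dose-volume parameters against the original plan.

The workflow runs in eight steps: data import; isocenter-prealigned rigid
registration of the CBCT to the CT with combined-CT construction by
cropping and splicing; CBCT intensity calibration (a synthetic-CT
stand-in); adoption of the fraction-day influencer segmentation;
intensity-based B-spline registration producing the deformed planning CT
and rigid-organ contours; structure-guided ROI registration propagating
CTV/PTV; dose recomputation at the original plan's output; and the
dosimetric evaluation with a replan recommendation.

## Conventions

Physical coordinates are patient LPS millimetres; voxel indices are
0-based; grid positions refer to voxel centers.  Every transform - rigid
or deformable - maps *fixed*-image points to *moving*-image points
(pull/backward warping), so `resample()` never needs to invert anything
and push/pull mix-ups are impossible by construction.  Intensities are
interpolated trilinearly, labels by nearest neighbour; the out-of-support
fill is -1000 HU for CT-like volumes and 0 for dose and masks.  Masks are
warped by interpolating the 0/1 field and thresholding at 0.5, ties
inside.

## Rigid stage

When the plan provides an isocenter, prealignment is the pure translation
mapping it to the CBCT scan center (the machine guarantees they coincide
up to the setup error); otherwise the grids' geometric centers are
aligned.  The six rigid parameters (rotations about x, y, z and a
translation, rotation center at the fixed-image center) are then refined
over a 3-level block-mean pyramid (shrink 4/2/1) by a deterministic
coordinate pattern search of the metric: per sweep each parameter is
probed one step up and down (initial steps 1.5 degrees / 3 mm) and the
steps halve whenever a sweep brings no improvement, down to
0.01 degrees / 0.02 mm.  A direct search was chosen over simplex or
gradient methods because the sampled mutual-information landscape is
non-smooth at the sample level; the search is deterministic and, unlike
Nelder-Mead, cannot collapse prematurely.  The metric defaults to
mutual information (64-bin joint histogram on up to 40 000 strided
samples) because the CT-CBCT intensity relationship is not the identity;
mean squared difference is available for same-modality work.  CBCT voxels
at exactly the air fill value (outside the scan cylinder) carry no
anatomy and are excluded.  If the optimized transform does not improve
the finest-level metric over the prealignment, the prealignment is
returned unchanged.

On the standard phantom (below) with setup errors up to 5 mm and
1.7 degrees per axis the recovered transform is typically within 0.3 mm
and 0.3 degrees of the truth.

## Synthetic CT and combined CT

CBCT intensities are corrected by a deterministic calibration standing in
for a learned synthetic-CT generator (the module exposes the same
contract - HU-faithful voxels in, nothing else assumed - so a learned
model can be substituted).  The calibration has three robustness
ingredients, each standard in CBCT preprocessing:

* pairs are taken only at low-gradient voxels of the rigidly aligned
  planning CT (edge voxels pair partial-volume values across tissue
  boundaries and poison the estimates), and pairs whose offset deviates
  from the median by more than 150 HU are discarded - organs that moved
  between plan and fraction are anatomy mismatch, not intensity error;
* a monotone piecewise-linear HU map with 16 knots over [-1000, 1500]:
  each knot output is the knot position plus the median CT-minus-CBCT
  offset of its bin (exactly the identity when the images already agree),
  kept monotone by isotonic regression so two HU values are never
  reordered;
* a residual radial bias-field (cupping) correction about the scan axis,
  because a global HU map cannot remove a spatially varying offset.

The combined CT lives on the planning-CT grid: inside the CBCT field of
view it takes the calibrated CBCT value, outside it keeps the planning CT
value, with a 5 mm raised-cosine blend just inside the seam to avoid dose
gradients from splicing artifacts.

## Deformable registration

Both deformable stages share one free-form-deformation core: a cubic
B-spline displacement lattice optimized with L-BFGS-B using exact
analytic gradients of the trilinear sum-of-squared-differences metric
(value and in-cell gradient are computed in one pass), multi-resolution
(block-mean shrink 4 then 2, control spacing halving), with a bending
penalty built from second differences of the control lattice weighted
relative to the starting residual of each level.  Sampling is
border-replicated so the objective is continuous at the image boundary,
control displacements are box-bounded at 0.39 of the control spacing
(clear of the folding regime), and a field that still folds triggers one
retry at tenfold smoothness.  The result maps fixed-image points to
moving-image points like every other transform in the package.

The *intensity* stage registers the planning CT (moving) to the combined
CT (fixed, 20 mm final control spacing); its field yields the deformed
planning CT used for dose calculation and propagates the rigid-organ
contours.  The *structure-guided ROI* stage registers label masks: the
eight organs around the target plus the body outline are rendered into a
single label volume (air 0, skin 1, femoral heads 2-3, pelvis 4, cord 5,
rectum 6, small intestine 7, bladder 8; overlaps resolve to the higher,
more target-important label).  Because arithmetic on label values is
meaningless, each shared label becomes a signed Euclidean distance map
clamped at +/-20 mm and the multi-channel SSD is minimized (25 mm final
control spacing - the guidance is sparse but clean).  Only masks enter
this stage, so CBCT image quality cannot affect it; fewer than three
shared non-air labels is an error.  The resulting field propagates
CTV/PTV onto the fraction anatomy, with PTV-contains-CTV repaired by
union if violated.

On the standard phantom cohort the mean CTV Dice against ground truth is
about 0.76 for rigid alignment alone, 0.80 after intensity DIR and 0.94
after ROI registration - the same ordering, for the same reason, that
motivates structure-guided target propagation clinically: intensity DIR
has almost no contrast to grab at the bladder/CTV interface, while the
organ masks encode exactly the deformation that displaces the target.

## Dose recomputation

The dose engine is a deterministic analytic photon model, *not* a Monte
Carlo transport code: per beam, dose = weight x exp(-(mu/rho) x
radiological depth) x inverse-square x an error-function penumbra
(sigma 3 mm at the isocenter plane, divergence-scaled), with mu/rho =
0.05 cm^2/g (approximately a 6 MV beam) and densities from a four-knot
HU table (-1000 -> 0, 0 -> 1, 1000 -> 1.6, 3000 -> 2.9 g/cm^3).
Radiological depth is an exact Siddon line integral.  The model's job is
to move DVH metrics in physically correct directions when the anatomy
changes (bladder filling, body contour, target displacement); its
absolute numbers are internal-consistency only and are never compared to
published clinical values.

Normalization deserves a note.  The engine's reference contract
normalizes the mean dose of a 1 cm sphere at the isocenter to the
prescription.  For opposed-beam box plans, however, the attenuation
profile of an opposing pair is cosh-shaped with its *minimum* at the
isocenter, so isocenter normalization pins the in-field minimum at the
prescription and a band of central voxels - inside the CTV - necessarily
falls below it, making the clinical constraint CTV V100% >= 99%
unattainable for any such plan.  Reference plans are therefore normalized
clinically instead: D98% of the PTV is set to 100.2% of the prescription
(the 0.2% headroom keeps boundary metrics off the exact float edge), and
the resulting output factor is frozen into the plan.  Fraction
recomputations reuse that frozen factor - a same-monitor-units recompute
on new anatomy - so coverage changes reflect anatomy, never
renormalization.

## Evaluation and decision

The cumulative DVH uses 0.01 Gy bins; D_i is the largest dose received by
at least i% of the volume (linear interpolation between bins) and V_d the
percent volume at or above d Gy (V_100% at the prescription).  Both agree
with direct voxel sorting to within one bin.  The 3D gamma index uses
global normalization (max of the reference dose), a 10% low-dose
threshold on reference voxels, trilinear interpolation of the evaluated
dose at DTA/10 steps within a 3xDTA search radius, sorted by distance so
the early exit is exact; the default criterion is 2%/2 mm.

The fraction report computes CTV V100%/D99%, PTV V100%/D95%,
bladder/rectum/bowel V40Gy, bone-marrow V10Gy and femoral-head V30Gy for
the original and recomputed dose.  Targets are flagged with the clinical
rules: CTV V100% >= 99%, PTV V100% >= 95%, CTV D99% and PTV D95% at least
the prescription (45 Gy full course by default), passing exactly at the
boundary.  The recommendation is `adapt` if any target flag fails,
`review` if any OAR V-metric rose by more than 5 percentage points over
the original plan (a configurable margin - no published OAR trigger rule
exists), else `no_adaptation`.  Two empty masks have Dice 1.0 by
definition (with a warning).

## The synthetic phantom

Clinical CBCT fractions cannot ship with a package, so validation runs on
a self-contained pelvis phantom with exact ground truth: smoothed
geometric organs (body, femoral heads, pelvic ring, cord, rectum,
bladder, small intestine, bone marrow as the eroded bone interior) with
tissue-appropriate HU, a CTV between bladder and rectum, PTV as a 5 mm
expansion, a 4-field box plan (45 Gy / 25 fractions, isocenter at the PTV
centroid snapped to a voxel center), and a fraction-day CBCT derived from
the CT by a known rigid setup error plus a known smooth deformation,
cropped to a cylindrical field of view with cupping (80 HU center-to-edge),
a +30 HU shift and 20 HU Gaussian noise; everything outside the cylinder
is -1000 HU.

The fraction-day deformation defaults emulate reported cervix ART
variation: bladder volume x1.35 and rectum x0.8 (radial fields whose
dense B-spline interpolates the analytic profile at the lattice nodes),
a 5 mm smooth random residual field, and a 4 mm posterior-superior
displacement of the target region - the cervix/uterus rides on the
bladder, and target displacements up to ~2 cm are documented; 4 mm is a
typical, sub-margin value so an ordinary fraction does not trigger
adaptation.  Setup errors are drawn up to 5 mm / 1.7 degrees per axis.
The deformation is checked for folding (Jacobian determinant > 0.05 on a
dense sample) with damped retries.  One RNG stream per case, drawn in
fixed order, makes every case bit-reproducible from `(params, seed)`.

What the phantom does *not* emulate: scatter and beam-hardening physics
beyond the smooth cupping term, anatomically textured tissue, peristalsis
or gas pockets, couch structures, and multi-fraction correlation.  A
passing suite therefore demonstrates the correctness and the directional
behaviour of the algorithms, not clinical segmentation accuracy on real
CBCT.

Problem sizes used by the validation suite: 96^3 voxels at 2.5 mm for
cohort studies (ten seeded fractions), 64^3 for unit tests, and <= 32^3
for gamma-oracle cross-checks.

## Known limitations

* The dose engine ignores lateral scatter transport and MLC sequences;
  rectangular apertures only.
* Intensity DIR is SSD-based and assumes the calibration has removed
  systematic CBCT intensity errors; gross residual bias will leak into
  the field.
* The ROI stage tracks large target displacements only as far as the
  surrounding organ masks move with them; a 20 mm displacement is
  detected reliably but under-segmented (Dice ~0.75), which is acceptable
  for triage (the coverage loss is still flagged) but not for replanning
  contours.
* DICOM ingestion covers uncompressed explicit-VR little-endian image
  series; RT Plan/Structure/Dose travel via the JSON sidecar format.
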