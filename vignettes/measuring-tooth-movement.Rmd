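---
title: "Measuring tooth rotation, inclination and angulation on digital models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring tooth rotation, inclination and angulation on digital models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odontometry)
```

## The measurement problem

Orthodontic follow-up needs *longitudinal* angular measurements of
individual teeth: **rotation** about the occluso-apical axis, buccolingual
crown tip (**inclination**, torque) and mesiodistal crown tip
(**angulation**, tip).  Radiographs only give a subset of these and
superimposition is unreliable; digital arch models make all three
accessible if a stable reference frame can be constructed for both time
points.  `odontometry` implements a trigonometry-based method that reads
all three angles from five anatomical landmarks per tooth — lingual
gingival, mesial, distal, occlusal and vestibular (buccal) gingival —
digitised on an initial model and on a final (e.g. planned set-up) model.

## The procedure

1. **Common space.**  The final model is rigidly best-fitted onto the
   initial one.  The clinical workflow best-fits dense mesh surfaces; this
   package substitutes exact-correspondence least-squares fitting (the
   Kabsch algorithm) on the concatenated landmarks of all teeth except the
   second molars.  For landmark data generated by a rigid motion the
   substitution is exact, which the registration tests verify
   constructively.
2. **Reference frame.**  Plane 1, the occlusal reference, is the total
   least-squares plane through the lingual gingival landmarks of all teeth
   except second molars (gingival landmarks are less affected by changes in
   crown inclination or the curves of Spee/Wilson, and second molars are
   often partially erupted or missing).  Its normal, oriented towards the
   mean occlusal landmark, becomes the +Z axis.  Plane 2, the median
   reference, is perpendicular to Plane 1 and defines the lateral X axis;
   Y = Z x X points anteriorly.  Both planes are built on the initial model
   only and shared with the aligned final model.
3. **Rotation.**  With $(x_m, y_m)$ and $(x_d, y_d)$ the frame XY
   coordinates of the mesial and distal landmarks,
   $\alpha = \operatorname{atan2}(x_m - x_d,\; y_m - y_d)$: the signed
   angle between the mesiodistal line and the anteroposterior Y axis, in
   $(-180^\circ, 180^\circ]$.
4. **Rotation reset.**  Each tooth is realigned by the Z rotation that
   maps its distal-to-mesial line onto +Y.  Without this step, rotation
   leaks into the other two angles; with it, inclination and angulation
   are provably invariant under any rotation of the tooth about the frame
   Z axis (a property the test suite checks to $10^{-9}$ degrees).
5. **Inclination and angulation.**  With
   $v = \text{occlusal} - \text{vestibular gingival}$ in realigned
   coordinates, inclination $= \operatorname{atan2}(v_x, v_z)$ (projection
   on XZ against Z) and angulation $= \operatorname{atan2}(v_y, v_z)$
   (projection on YZ against Z).
6. **Deltas.**  $\Delta = \text{final} - \text{initial}$ per tooth and
   movement; $\Delta$rotation is wrapped to $(-180^\circ, 180^\circ]$,
   the other two are plain differences since their magnitudes stay below
   $90^\circ$.

The fitting surface is `measure_movement(initial, final, planned, config)`,
returning a `tooth_movement` object with `coef()` (the delta matrix),
`summary()` (per-group statistics and, when a planned table is attached,
Bland-Altman agreement), `residuals()` (planned minus measured) and
`plot()`.

## Sign conventions

No universal sign conventions exist for these angles, so the package fixes
and documents one set; deltas are convention-independent up to a global
sign.  Axes are right-handed with X to the patient's right, Y anterior and
Z occlusal.  Rotation is read clockwise-positive from +Y towards +X (the
`atan2` formula above); `rotation_about_z()` itself is the usual
right-handed (counter-clockwise) rotation, so rotating a tooth by
`rotation_about_z(-theta)` increases its measured rotation by `theta`.  The
mesiodistal line is the distal-to-mesial vector and the crown line the
vestibular-gingival-to-occlusal vector.  Clinical readings ("mesial tip
positive") depend on arch side and are deliberately not encoded.

## The median plane: an open design choice

The occlusal plane fixes only the Z axis; the lateral axis needs a median
plane.  The simplest construction — perpendicular to Plane 1 and to the
scanner's native XZ plane — inherits the arbitrary scanner orientation,
so it is not reproducible across exports.  The
default (`median_plane = "incisor_midpoint"`) is intrinsic to the
dentition: Plane 2 contains the Plane-1 projections of (a) the midpoint of
the central incisors' mesial landmarks and (b) the lingual gingival
centroid, with its normal the in-plane direction perpendicular to the line
a-b.  The literal construction remains available as
`median_plane = "native_xz"`.  The equivariance tests (frame rebuilt after
an arbitrary rigid motion of all landmarks equals the moved frame) only
hold for the intrinsic default, which is why it is the default.

## Agreement and reliability statistics

Validation of such a method compares its deltas against an external
standard (an aligner manufacturer's planned-movement table) and against
repeated measurements:

* `bland_altman()` — bias of the paired differences with its t-based 95%
  CI, sample SD (n−1), limits of agreement mean ± 1.96 SD, a one-sample
  t test for systematic error, and the Dahlberg index
  $\sqrt{\sum d_i^2 / 2n}$ for random error.  The 1.96 multiplier (not a
  t quantile) and the t-based CI are fixed because they exactly reproduce
  the published validation tables shipped with the package
  (`validation_summary()`); `bland_altman_summary()` recomputes the same
  arithmetic from a reported (mean, SD, n) triple.
* `icc_single_absolute()` — ICC(A,1), the single-measurement
  absolute-agreement intraclass correlation from the two-way ANOVA mean
  squares, with the McGraw–Wong F-based confidence interval.  The point
  estimate is identical for the two-way random model (validity) and the
  two-way mixed model (intra-/inter-rater reliability); the model label is
  recorded for reporting.  Two algebraic variants of the CI's
  Satterthwaite degrees of freedom circulate in the literature; a 20,000
  run coverage simulation (n = 12, k = 3, true ICC 0.76) showed one
  hitting the nominal 2.5% miss rate per side and the other over-covering,
  and the package uses the calibrated form (they coincide at k = 2).

Rounding in report tables is two decimals (half-even); all internal
computation is full precision.

## The synthetic cohort generator

There is no public landmark dataset for this task, so the package
generates one with known ground truth.  `generate_arch()` places upright
crown templates on a parabolic arch form (defaults: 14 measured teeth per
arch — second molars included, third molars not; upper arch 60 mm wide,
45 mm deep; typical adult crown dimensions per tooth group), with the
gingival margin in a common plane and the occlusal landmark directly above
the vestibular gingival one, so a noise-free arch measures exactly zero
inclination and angulation.  `apply_movements()` moves each tooth about
its landmark centroid in frame coordinates, in the fixed order
inclination (about the distal-mesial axis), angulation (about the
buccolingual axis), rotation (about frame Z), then translation, using the
measurement sign conventions — making single-axis recovery exact by
construction, which pins down the sign conventions end to end.  Combined
three-axis movements are recovered only approximately because the three
measured quantities are projection angles, not Euler components of the
applied rotation; for movements up to ±15° the worst per-component error
stays below 1.5°, which is asserted as a fixed tolerance.

Digitisation noise is isotropic Gaussian per landmark coordinate with
SD 0.05 mm by default, a realistic point-picking error on scanned models.
`generate_paired_dataset()` emulates a cohort: per patient it builds a
noise-free arch, applies a movement table (by default Gaussian movements
with SD 5° rotation, 3° inclination/angulation, 0.3 mm translation,
the magnitude range of aligner-planned corrections), then adds independent
noise to both time points.

What the generator does *not* emulate — and what passing tests therefore
do not establish about clinical data — is reference-plane instability:
real initial and final set-up models differ by genuine gingival remodelling
and anterior extrusion, which tilt the fitted occlusal plane between time
points.  The clinical validation found exactly this to limit agreement for
anterior inclination and for angulation.  Synthetic pairs share one
coordinate system, so exactness tests run with `align = FALSE` in
`pipeline_config()`; the default `align = TRUE` performs the whole-arch
best fit of the clinical procedure and is exercised by the noise-ladder
simulation (72 patients × 14 teeth = 1008 teeth at 0.05 mm noise, rotation
ICC vs ground truth > 0.9) and by a scanner-space mismatch test.

## Numerical choices and degenerate inputs

* Collinearity in plane fitting: degenerate when the second singular value
  falls below 1e-9 of the largest; the same threshold flags rank-deficient
  cross-covariances in the Kabsch fit (reflections are excluded by
  sign-flipping the smallest singular direction).
* A mesiodistal line with occlusal-plane projection shorter than 1e-9 mm,
  or a vanishing crown line, is a per-tooth error naming the FDI code; a
  crown line with non-positive Z component only warns (the angles are
  still defined) since it indicates a digitisation mix-up rather than a
  numerical problem.
* Zero-variance difference vectors leave the Bland-Altman t statistic and
  p undefined (`NA`) while the other fields stay valid; constant rating
  matrices flag the ICC undefined rather than returning 0/0.
* IGES import supports the fixed 80-column form, Point entities (Type 116)
  only, honours the Global-section delimiter declarations and Hollerith
  strings, requires millimetre (or unspecified) units, and maps points to
  clinical identities through an explicit manifest, because point identity
  is not reliably encoded in mesh-software exports.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run entirely on generated data:
single-axis recovery over 336 tooth-movement combinations, 100 random
rigid transforms for the invariance properties, 1000-candidate oracle
bounds for the plane fit and the rigid fit, 100 random matrices against a
definitional ANOVA oracle for the ICC, and the 1008-tooth noise-ladder
cohort; the published-table arithmetic is reproduced from the reported
per-group summaries included in `inst/extdata/`.  A minority of published
cells are internally inconsistent with their own mean/SD (see
`?validation_summary` and the README) and are flagged out of the
reproduction checks.

## Limitations

* Landmark-based best fit stands in for surface-based best fit; with real
  scans the five landmarks are a sparser constraint than a mesh surface.
* Validity is only as good as the reference frame; the method is known to
  be reliable for all three movements but clinically valid mainly for
  rotation (maxillary canines excepted) and posterior inclination.
* The synthetic generator's parabolic arch and upright templates are
  idealisations; its parameters are configuration, not anatomical claims.
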