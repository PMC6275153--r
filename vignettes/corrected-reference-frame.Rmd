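---
title: "Descriptive 3D treatment evaluation in a corrected reference frame"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Descriptive 3D treatment evaluation in a corrected reference frame}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cephaloframe)
```

## The problem

Voxel-based superimposition of pre- and post-treatment cone-beam CT (CBCT)
records aligns two timepoints on structures that treatment does not change —
the anterior cranial base — with excellent accuracy, but by itself it only
supports qualitative, color-coded displays or direct point-to-point
distances, which carry no information about the *direction* of change.
Landmark-based reference systems give directional measurements but require
every reference landmark to be digitized twice (once per timepoint),
doubling the digitization error.

`cephaloframe` combines the two: one automated rigid superimposition on the
cranial base, one reference system digitized a single time on the
superimposed records, and all change values obtained by projecting
displacements and axes onto that reference. Because the reference is shared,
any error in locating it is made identically on both timepoints and cancels
out of every change value; this shared-reference invariance is tested
to 1e-9 mm in the suite.

## Pipeline and model

1. **Superimposition.** The post-treatment volume is registered to the
   pre-treatment volume by maximizing the Shannon mutual information
   $MI = H(F) + H(M) - H(F, M)$ of the joint intensity histogram over a
   binary cranial-base mask (anterior hypophyseal fossa, sphenoid wings,
   crista galli). The transform is rigid (6 parameters, mm and degrees).
   Masking matters: maxillary structures move with treatment, and including
   them would bias the alignment.
2. **Reference landmarks, once.** On the superimposed pre-treatment record:
   right and left Sella as the arc-length centroids of the manually traced
   hypophyseal-fossa borders; the constructed Sella `C-Sella` as their
   midpoint; the Porion axis through the two Porion points; the raw
   Orbitale points.
3. **Asymmetry correction.** Orbitale is the least reliable of these
   landmarks mediolaterally (natural craniofacial asymmetry), so the raw
   pair is replaced by constructed `C-Orbitale` points that keep only its
   reliable coordinate (the vertical level of mid-Orbitale) and take their
   mediolateral positions at equal distances from `C-Sella`, parallel to
   the Porion axis. The corrected Frankfort Horizontal (`C-FH`) is the
   total-least-squares plane through the two Porion and two `C-Orbitale`
   points; the corrected midline runs through `C-Sella`, in-plane,
   perpendicular to the Porion axis.
4. **Orientation.** A rigid transform maps the `C-FH` normal to +Z, the
   midline to +Y and the centre of `C-FH` (centroid of its four defining
   points projected onto the plane) to the origin. Both records are viewed
   in this frame from here on.
5. **Measurement by projection.** A coronal auxiliary plane (the
   mid-maxillary perpendicular plane) cuts the maxilla perpendicular to
   `C-FH` midway between ANS and PNS. On its contour the maxillary
   basal-bone point (`Max`, most concave point nearest the midline) and the
   alveolar-crest point (`Alveo`, most inferior point) are detected
   semi-automatically. Linear change is the change in absolute mediolateral
   offset from the corrected midline (positive = expansion); angular change
   is the signed angle between pre- and post axes projected on the
   auxiliary plane (positive = buccal tipping).

## Worked example

```{r example}
spec <- phantom_spec(
  motion = rigid_transform(rotation_about(c(0.4, 1, 0.6), 6), c(3, -2, 1.5)),
  noise_sd = 0)
ph <- generate_phantom(spec)

pre <- ph$pre; pre$frame <- "superimposed"
post <- transform_landmarks(ph$post, invert_transform(spec$motion),
                            new_frame = "superimposed")
frame <- build_reference_frame(pre)
report <- measure_all(apply_frame(pre, frame), apply_frame(post, frame), frame)
report[, c("parameter", "kind", "value", "units")]
```

On this noiseless phantom the report reproduces the generator's injected
changes (2.5 mm at Max, 3.0 mm at the crest, 6° premolar and 4° molar
tipping) to numerical precision.

## What the phantom emulates — and what it does not

The synthetic phantom is the package's test bed. Its landmark layout is
adult-scale (inter-Porion ≈ 110 mm, Sella near the origin, right side at
negative X), with closed elliptical Sella-border traces, maxillary contours
carrying a cosine notch (apex = the Max point) and a V-shaped crest
(apex = the Alveo point), per-side mediolateral expansion applied to
treatment-affected landmarks only, an arbitrary rigid inter-timepoint
motion, optional per-landmark anatomical asymmetry, and isotropic Gaussian
digitization noise (default conditions: 2.5 mm Max, 3.0 mm crest, 6°
premolar and 4° molar tipping; the premolar axis is ~20 mm long,
a realistic cusp-to-apex distance, which sets how digitization noise
propagates into projected angles). The voxel phantom renders anisotropic
Gaussian blobs, truncated at 3σ so that the treatment-affected blobs
contribute exactly nothing inside the cranial-base mask, on a 64³ grid at
2.2 mm spacing, with 2% intensity noise in the standard registration
condition.

What passing tests on this phantom show: the geometry, projection algebra,
error cancellation and registration machinery are correct, and landmark
noise propagates as theory predicts. What they do not show: performance on
real CBCT intensity distributions (beam hardening, scatter, metal
artifacts), real cortical-bone contour shapes, or observer behaviour;
cleft-specific anatomy is not modelled.

## Numerical and design choices

* **World convention.** Right-handed, X mediolateral (positive toward the
  patient's left), Y anterior, Z superior; millimetres everywhere, degrees
  for angles. NIfTI (RAS) and DICOM (LPS) geometry is converted on ingest.
* **Equivariance.** The `C-Orbitale` construction is expressed in an
  anatomy-derived basis — vertical = normal of the raw Porion/Orbitale
  plane signed toward Sella, mediolateral = horizontal projection of the
  Porion axis — rather than in raw world axes. For an aligned head the two
  formulations coincide; the intrinsic form additionally makes the entire
  frame exactly equivariant under a common rigid motion of the superimposed
  records, which is what makes the shared-reference invariance hold to
  machine precision rather than approximately.
* **C-Orbitale half-width.** The rule for "equal distances" from `C-Sella`
  is the mean of the two raw offsets (`half_width = "mean"`): the least
  perturbing choice, reducing to the raw points for symmetric anatomy.
  `"raw"` (no equalization) is selectable.
* **Plane fit.** `C-FH` is fitted by orthogonal least squares (SVD) rather
  than constructed from two parallel lines: identical on ideal input,
  graceful on digitized input, with the residual reported and logged.
* **Registration defaults.** 32 histogram bins, linear partial-volume bin
  weights for a smooth metric (hard binning for reported metric values),
  3-level multi-resolution schedule (Gaussian σ = 2, 1, 0 voxels),
  Nelder-Mead with one simplex restart at the finest level, intensity-
  centroid initialization. All masked voxels enter the metric — no
  stochastic sampling — so results are deterministic.
* **Concavity operator.** Contours are resampled at 0.1 mm arc length;
  candidate indentation apexes are strict local minima of midline distance
  (~2 mm neighbourhood) whose nearby smoothed discrete curvature clearly
  exceeds the contour's baseline (median) curvature — a smooth convex arc
  has uniform curvature and is rejected. Among candidates the one nearest
  the midline wins. A pure medial-extremum rule is selectable.
* **ICC model.** Two-way random effects, absolute agreement: ICC(2,1) for
  Single Measures, ICC(2,k) for Average Measures, computed from the two-way
  ANOVA mean squares; consistency ICC(3,·) selectable. Negative estimates
  are clamped to 0 and flagged, never silently. Intra-rater reliability
  treats one observer's repeated sessions as the repeat factor; inter-rater
  uses the observers at a fixed session (the first, by default).
  Coordinate SDs are per-subject sample SDs pooled by root mean square.
* **Tie-breaks and degeneracies.** The most-inferior search breaks Z ties
  toward the midline; coincident Porion points, collinear molar apices,
  axes perpendicular to the projection plane and empty registration masks
  raise classed errors rather than producing numbers.

## Problem sizes

The validation suite runs on one CPU: registration recovery uses twenty
seeded motions on the 64³ phantom; measurement recovery uses one hundred
noisy repeats of the landmark pipeline; ICC calibration uses two hundred
simulated 100 × 3 panels. These sizes keep every sampling-based check's
standard error well inside its tolerance while completing in minutes.

## Limitations

Registration is rigid by design — growth or deformation inside the masked
cranial base would violate its assumption. Cranial-base masks are supplied,
not segmented automatically. The semi-automated detectors assume the traced
contour actually contains the anatomical feature (a notch, a crest) and
lies in the auxiliary plane. Reported reliability of the constructed
landmarks is a property of the digitization process; the package can
quantify it (reliability module) but not remove it.
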