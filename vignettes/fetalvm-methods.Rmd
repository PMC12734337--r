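---
title: "Measuring fetal ventriculomegaly from tissue segmentations: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring fetal ventriculomegaly from tissue segmentations: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetalvm)
```

## The measurement problem

Fetal ventriculomegaly (VM) is diagnosed and graded from a single number:
the atrial width of the lateral ventricles, read on an axial plane through
the thalami and the cavum septi pellucidi. The clinical bands are Normal
below 10 mm, Mild from 10 mm, Moderate from 12.5 mm and Severe from 15 mm.
A one-millimeter difference can change the grade, so the geometry — which
plane, which structure, which direction — matters more than any model.

`fetalvm` automates that geometry for volumes that already carry a tissue
segmentation. Segmentation itself is deliberately an *input*, not a stage:
masks may come from manual annotation, from a phantom, or from any
segmentation backend (e.g. nnU-Net); the package consumes the mask and is
agnostic about its origin.

## Pipeline

**Mask simplification.** Multi-class fetal tissue masks (7 tissues in the
FeTA convention) are collapsed to three classes: 0 background, 1 lateral
ventricles, 2 deep gray matter. The default map follows the FeTA numeric
codes (ventricular system 4 → 1, deep gray matter 6 → 2, all else → 0) and
is overridable in configuration, since other datasets number tissues
differently. Remapping conserves voxel counts per class, and a mask already
in `{0, 1, 2}` is passed through untouched by the pipeline entry points.

**Intensity normalization.** For paired T2w volumes, intensities are clipped
at the 0.5th/99.5th percentiles and z-scored per volume. A zero-variance
volume maps to zeros rather than erroring — constant backgrounds are common
in phantoms. The result is invariant to positive affine rescaling of the
input. Resampling (nearest-neighbor for labels, trilinear for intensities)
is available but off by default: native spacing is preserved unless a target
spacing is configured.

**Measurement-plane selection.** The per-slice deep-gray-matter area
`A(k) = count(label 2 in slice k) × dx·dy` peaks where the thalami are
widest, which closely tracks the clinical measurement plane. The center
slice is `argmax A(k)`, ties broken to the smallest index so the choice is
deterministic. A window of ±12 slices (25 slices, configurable: ±10 and ±13
are also reasonable) provides the standardized 2D stack; at volume
boundaries the window is clipped, never padded or shifted, because invented
or re-centered slices would misrepresent the anatomy.

**Adaptive left/right splitting.** The ventricle mask is projected onto the
left–right axis (one occupancy sum per image column). A *discontinuity* — an
interior run of empty columns between occupied ones — indicates the natural
separation between the two ventricles; the mask is split at the midpoint of
the longest such run (ties: the run closest to the mask's horizontal
center). When no empty interior column exists (fused or touching masks), the
fallback splits the bounding box into two equal halves. The two parts always
partition the input exactly. The left–right axis defaults to the image
x-axis after canonical RAS reorientation and can be swapped in
configuration.

One degenerate case deserves note: a single lone ventricle with no gap is
bisected by the equal-halves fallback — the algorithm cannot know the other
side is absent. A side that receives no pixels reports 0 mm rather than
erroring, since unilateral enlargement is clinically real.

**Width via minimum bounding rectangle.** Each side is measured with a
minimum-area oriented bounding rectangle, computed in physical millimeters
(coordinates are scaled by the pixel spacing before fitting, so anisotropic
pixels do not bias the orientation). The atrial width is transverse to the
ventricle's long axis, so the *short* side of the rectangle is the default
width; a flag selects the long side instead. The final reported width is the
maximum of the left and right widths. Volume is the label-1 voxel count
times the voxel volume, in cm³, and is carried as a descriptive marker —
the severity decision is width-only.

**Severity labeling.** Half-open, lower-inclusive intervals: Normal
`[0, 10)`, Mild `[10, 12.5)`, Moderate `[12.5, 15)`, Severe `[15, ∞)` mm.
The lower-inclusive convention follows from the diagnostic definitions "≥ 10
mm" and "≥ 15 mm"; 12.5 mm is assigned to Moderate by the same rule. All
three cut points are configurable.

**Reporting.** Each case yields a fixed structured prompt —
`Slice: [Image]; Severity: <class> VM; Width: <w> mm; Volume: <v> cm^3`,
width and volume to one decimal — and an offline templated explanation that
cites only the measured values and the threshold crossed. Widths within
0.5 mm of any threshold are flagged as borderline, since interpretation is
least reliable near a class boundary; the window is configurable. An
external language-model explainer can be plugged in behind the same
interface, but the offline template is the default so nothing in the
package ever requires network access.

## The bounding-rectangle convention

Two decisions here are genuinely open and worth recording.

*What does the rectangle enclose?* A pixel is a physical dx × dy square, not
a point: a single-pixel blob must have nonzero extent. The rectangle's
**orientation** is chosen to minimize the bounding-box area of the pixel
*centers* (computed exactly with rotating calipers on the convex hull — the
optimum is flush with a hull edge). The **sides** are then padded by the
support of one pixel square along each rectangle axis
(`dx·|cos θ| + dy·|sin θ|` and `dx·|sin θ| + dy·|cos θ|`), so the reported
rectangle contains every foreground pixel's full square. For axis-aligned
blobs this reproduces the exact pixel-count extents (a 10 × 4 block at
0.5 mm measures 5.0 × 2.0 mm; one pixel at 1 mm measures 1 × 1 mm).

Why not minimize the area of the padded (corner-hull) rectangle directly?
Because the padding term is smallest at axis-aligned orientations, which
systematically tips the near-flat area objective toward the image axes for
slightly rotated structures — the fitted "width" then becomes a projection
extent rather than the transverse width. Fitting the orientation on centers
removes that bias while keeping the containment guarantee.

*How stable is the short side?* For mildly elongated, near-elliptic
cross-sections the rectangle area is an almost flat function of orientation,
so the minimizing angle — and with it the short side — can move by up to
about two in-plane voxels when the structure is rotated in-plane. This is a
property of the minimum-area-rectangle definition itself (any implementation
of it, including OpenCV's `minAreaRect`, shares it), not of this
implementation; the test suite asserts the honest two-voxel bound for
rotated phantoms and exact-to-the-voxel recovery for unrotated ones. More
elongated ventricles pin the orientation more firmly.

## The phantom generator: what it does and does not emulate

Every geometric claim in the package is validated against synthetic phantoms
with closed-form ground truth:

- two ellipsoidal ventricle blobs (label 1) whose maximal in-plane
  transverse extents equal the requested widths, separated by a configurable
  left–right background gap;
- one deep-gray-matter ellipsoid (label 2) whose cross-sectional area peaks
  at a requested slice. Voxelization can tie neighboring slice areas, so the
  generator trims the outermost label-2 voxels on non-peak slices until the
  peak is strictly unique — and verifies this before returning;
- a paired T2-like intensity volume (bright CSF-filled ventricles on darker
  parenchyma, mild anterior–posterior shading, additive Gaussian noise).

Defaults are chosen to resemble reconstructed fetal T2w MRI: 0.5 mm
isotropic spacing, a 96 × 128 × 64 grid, ventricle elongation 1.4–1.8,
separation gaps of 3–6 mm, noise sd 0.05 against tissue contrasts of order
0.1–1. Cohorts draw per-side widths uniformly (default 6–20 mm, spanning
all four grades), with the peak slice uniform over the interior so a ±12
window never reaches a boundary; all randomness is seed-derived and two
runs with one seed are bit-identical.

The phantoms are deliberately *not* anatomically realistic: no curved
ventricular horns, no partial-volume effects, no bias fields or motion
artifacts, no segmentation errors. Passing the recovery suite therefore
demonstrates that the geometry — plane selection, splitting, rectangle
width, volume, grading — is implemented correctly at clinical resolutions;
it does not demonstrate accuracy on real fetal MRI, which additionally
depends on segmentation quality and true ventricular shape.

## Problem sizes and numerical choices

The verification suite uses an 80-phantom cohort for the slice-window
arithmetic (80 interior ±12 windows → exactly 2000 slices), a 50-phantom
width sweep (6–20 mm) for parameter recovery — center slice exact, width
within one in-plane voxel in ≥ 95% of cases, grade equal to truth whenever
the true width is at least one voxel from a cut point — 100 random digitized
ellipses for the rectangle-vs-exhaustive-0.1°-sweep oracle, and 200 random
two-blob masks for the split-vs-connected-components oracle. These sizes
keep the full suite around a minute on one CPU while leaving the estimates
stable.

Other conventions, for completeness: slice indices are 1-based (R
convention) with the axial axis as array axis 3 after RAS reorientation;
label values are validated against the permitted set on construction and
after every I/O round trip (non-integer values beyond 1e-3 are an error,
not silently rounded); Dice and IoU of two empty masks are 1 by convention
so sweeps over absent structures do not crash; undefined precision or recall
(a class never predicted, or with no support) is reported as 0 with an
explicit flag rather than NaN, keeping macro averages finite on small
cohorts; PNG slices carry no physical units, so in-plane spacing is a
required argument with a 0.5 mm isotropic default in the CLI configuration.

## Known limitations

- The equal-halves fallback bisects fused or unilateral ventricle masks; a
  shape prior would be needed to do better, and none is attempted.
- The short-side width convention assumes the ventricle cross-section is
  longer anterior–posteriorly than transversely (elongation > 1); for nearly
  circular cross-sections the short/long distinction is unstable by nature.
- Width is measured on the single maximal-deep-gray-matter slice, not
  aggregated over the window; that matches the clinical single-plane
  protocol but makes the measurement sensitive to the plane choice when the
  ventricle tapers quickly.
- Volume is reported only for 3D input; a single 2D slice has no defined
  slab thickness, so its volume is `NA`.
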