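---
title: "Marker-based 3D2D registration of vertebrae: models and methods"
author: "fluororeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-based 3D2D registration of vertebrae: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Navigated spine surgery needs the 3D pose of each vertebra in the
intraoperative scene. A preoperative CT supplies the 3D anatomy; two
angulated fluoroscopic images acquired with a mobile C-arm supply the
intraoperative information. `fluororeg` registers each vertebra of the CT
rigidly to the pair of 2D views, using radiopaque skin-marker spheres to
recover the unknown relative pose between the two views, so that neither
the C-arm's absolute angulation has to be calibrated nor its position
tracked. Per-vertebra (rather than whole-spine) rigid registration
absorbs changes in spinal curvature and inter-vertebral shifts between
the CT and the acquisition.

Throughout, patient axes are x = left-right (+x left), y = caudo-cranial
(+y cranial), z = fronto-dorsal (+z dorsal); lengths in mm, angles in
degrees. Rigid poses `q = (tx, ty, tz, wx, wy, wz)` rotate extrinsically
in the order x, y, z about a stated center: per-vertebra poses about the
vertebral body center, coarse poses about the volume center, which keeps
translation magnitudes comparable across vertebrae.

## DRR formation

Candidate poses are scored by comparing digitally reconstructed
radiographs (DRRs) with the fluoroscopic images. The projector
(`forwardProject()`) casts one ray per detector pixel from the point
source through the attenuation volume, samples trilinearly at a fixed
step (default half the smallest voxel), and sums. Poses are applied by
inverse-transforming the rays, so the volume is never resampled. The
projector is exactly linear in the volume; splitting a volume over
disjoint masks and summing the masked DRRs reproduces the full DRR to
machine precision. Marker spheres are rendered analytically: a ray at
distance `d < r` from a sphere of radius `r` and attenuation `mu`
contributes `2 mu sqrt(r^2 - d^2)`.

Images live in the line-integral (log-transformed) domain on both sides
of the comparison. Whether fluoroscopy should be compared raw or
log-transformed is not fixed by the clinical protocol; the log-like
domain was chosen because the similarity's explicit intensity scale `s`
(below) then models an affine detector response, which the simulator
deliberately applies.

## The gradient-difference similarity

For a fluoroscopic image and a DRR the similarity is

$$S = \sum_{i,j} \frac{A_v}{A_v + I_{\mathrm{diffV}}(i,j)^2}
    + \sum_{i,j} \frac{A_h}{A_h + I_{\mathrm{diffH}}(i,j)^2},$$

with vertical and horizontal difference images

$$I_{\mathrm{diffV}} = \frac{dI_{\mathrm{fl}}}{di} - s\,\frac{dI_{\mathrm{DRR}}}{di},
\qquad
I_{\mathrm{diffH}} = \frac{dI_{\mathrm{fl}}}{dj} - s\,\frac{dI_{\mathrm{DRR}}}{dj}.$$

Derivatives are central differences with replicated borders. Each
per-pixel term lies in (0, 1], so `0 < S <= 2N` over `N` pixels with the
bound attained exactly when both difference images vanish.

Two constants are not fixed by the formulation and are package
decisions:

* `Av`, `Ah` default to the squared median absolute fluoro gradient over
  the region of interest (ROI). Tying the half-saturation constant to
  the image's own gradient scale keeps the per-pixel normalization
  meaningful across noise levels and detector scalings.
* `s` is re-estimated at every evaluation by the least-squares closed
  form `s = <grad fl, grad drr> / |grad drr|^2` (both directions
  pooled). An all-zero DRR gradient is degenerate; `s = 1` is returned
  with a flag.

Per-vertebra matching restricts `S` to a rectangular ROI: the projected
bounding box of the vertebra's mask under the initial pose, inflated by
the search bounds (mapped through the geometric magnification) plus a
5-pixel dilation. The ROI, the fluoro gradients and `Av`/`Ah` are frozen
per optimization stage so that all candidate poses are scored on the
same support.

## CMA-ES pose search

The 6-DOF similarity landscape is multimodal, so the search uses the
covariance matrix adaptation evolution strategy (the standard
(mu/mu_w, lambda) scheme with rank-one and rank-mu updates and the
default population rule `lambda = 4 + floor(3 log n)`), implemented in
`cmaesMinimize()` and fully reproducible given a seed. Defaults chosen
for the registration stages:

* initial step sizes `sigma0` = 3 mm / 3 deg for stage 2. Smaller steps
  (2 mm) left a fifth of runs with 5 mm / 5 deg start errors in distant
  local optima; 3 mm trades a little final-precision polish for capture
  range.
* evaluation budget 1500 per stage, stopping early when the best value
  improves by less than 1e-3 of the total improvement over 15
  consecutive generations ("stagnation"); a run that stops this way is
  flagged converged, as is a run whose sampling distribution has
  contracted to under a tenth of its initial scale by the time the
  budget ends (the TolX-style criterion of reference implementations).
  Runs that stagnate with more than 40% of their budget unspent are
  restarted from the start point with a fresh seed (independent
  restarts, the standard remedy for multimodal CMA-ES landscapes) and
  the best result kept.
* search bounds +/-10 mm / +/-10 deg around the stage-1 pose for stage
  2 - the per-vertebra changes the method is expected to absorb (up to
  5 deg about x, 2 mm along z) sit well inside - and +/-15 mm /
  +/-10 deg for stage 1. Bounds are enforced by clamping plus a
  quadratic penalty.

## Two-stage registration

**Stage 1** registers the centered vertebra and its cranial neighbor
simultaneously with one shared pose against view 1 only, at half
detector resolution. Its purpose is to shrink the search space for the
per-vertebra stage. Because in-plane translation is the axis along which
the single-view similarity is most multimodal, the CMA-ES search is
seeded by an exhaustive in-plane translation grid (3 mm steps across the
search range) evaluated at quarter resolution; the grid costs well under
a percent of the stage budget. A single view cannot constrain depth
along the ray, so stage-1 accuracy is assessed in-plane; the residual
depth error is handed to stage 2, whose bounds cover it.

**Stage 2** registers each captured vertebra separately by maximizing
the unweighted sum `S1 + S2` over both views, where the view-2 geometry
is the view-1 geometry composed with the (estimated or true) relative
pose. The combination rule is not dictated by the formulation; the
unweighted sum is the simplest symmetric choice and the ROI sizes of the
two views are similar. Stage 2 runs at half and then full resolution,
the second phase starting from the first's optimum with halved step
sizes. Vertebrae whose projected mask bounding box leaves either
detector are skipped with a recorded reason, never silently dropped, and
vertebrae flagged non-registrable (e.g. sacral levels) are skipped the
same way.

## Relative pose from skin markers

The relative angulation (RAD) between the two views is estimated from
5-9 radiopaque spheres stuck to the skin:

1. **Detection** (`detectMarkers2d()`): difference-of-Gaussian blob
   responses over a small scale range, 8-neighborhood maxima above a
   robust (MAD-based) threshold, quadratic subpixel refinement, and
   non-maximum suppression at one marker diameter. Because the markers
   are identical manufactured spheres their responses are nearly equal;
   detections weaker than 0.6 times the median of the five strongest
   are discarded as anatomy clutter.
2. **Correspondence** (`matchMarkers()`): every cross-view pair is
   scored by its two-ray triangulation residual under the nominal
   geometries and the global assignment minimizing total residual is
   found exactly by dynamic programming over subsets, with a fixed skip
   penalty absorbing spurious or missing detections. The nominal
   angulation only needs to be correct to roughly 15 degrees.
3. **Refinement** (`estimateRelativePose()`): matched rays are
   triangulated under the current relative pose, each 3D point is
   dropped onto its nominal view-2 ray, and the rigid correction of
   view 2 is re-estimated by Umeyama least-squares alignment; iterated
   to convergence and then polished by direct least squares on the
   ray-ray residuals.

Two structural facts shape this step. First, with *unknown* marker
positions, two calibrated views leave the baseline length unobservable,
and - because skin markers are nearly coplanar and the field of view is
narrow - the orbit angle itself trades almost perfectly against the
marker depths. An unconstrained 6-DOF fit therefore wanders by several
degrees under realistic detection noise. The package resolves this by
constraining the refined pose to rotations about the isocenter: exactly
the family a (possibly imprecisely read-off) isocentric C-arm can
realize between two exposures of a static patient. Second, a
correspondence search under a coarse nominal angulation can occasionally
lock onto a self-consistent but wrong assignment; `markerRelativePose()`
therefore re-matches under the refined geometry until stable and falls
back to the nominal geometry whenever the estimate leaves the +/-15 deg
trust band of the declared angulation.

## Accuracy evaluation

The target registration error (TRE) of a vertebra is the Euclidean
distance between a landmark mapped by the estimated and by the true
pose, evaluated at the vertebral body center, with the left pedicle
center as a second landmark; the signed difference
`TRE(pedicle) - TRE(body)` indicates rotational error (zero under pure
translation errors). Signed per-axis components use the patient axes
with +z dorsal. Cohorts are summarized by median and interquartile range
with linear-interpolation quantiles, and outliers are the values outside
the Tukey fences `Q1 - 1.5 IQR` and `Q3 + 1.5 IQR`; the quantile
estimator is a package choice, the fence rule is standard.
`radSweep()` runs the full simulate-register-evaluate loop over a set of
rotation angle differences and emits per-vertebra tables plus per-RAD
medians; results whose optimizer did not converge are excluded from
summaries but retained in the tables.

## The synthetic phantom: what it emulates, and what not

`makeSpinePhantom()` builds a soft-tissue torso (elliptical cylinder
with low-frequency texture) containing stacked stylized vertebrae:
an ellipsoidal body with a denser cortical shell, a posterior ring, two
pedicle struts and a spinous process. Stylized shapes are a deliberate
choice: the registration mathematics only needs structured gradients,
and analytic shapes give exact landmark ground truth (the body-center
landmark is the ellipsoid center; the left pedicle center is the +x
strut's midpoint). Attenuations are plausible diagnostic-energy values
(soft tissue 0.018/mm, trabecular 0.032, cortical 0.065, posterior
elements 0.055; marker spheres 1.2/mm at 2 mm radius).

Ground-truth intraoperative motion has two parts: a shared
patient-repositioning pose (default uniform within +/-5 mm, +/-3 deg
about the volume center) and independent per-vertebra perturbations,
uniform within +/-5 deg about x and +/-2 mm along z by default - the
positional-change bounds the registration is expected to absorb; the
other four components default to zero but are configurable.
Perturbations are applied at projection time (each vertebra's pose is
passed to the projector), not by warping the volume, which avoids
resampling artifacts and matches the rigid per-vertebra model. Markers
are placed randomly on the dorsal skin surface within a 150 x 150 mm
frame centered over the centered vertebra, with a minimum separation.
Fluoroscopy simulation composites the background DRR, the per-vertebra
DRRs under their true poses and the analytic markers, then applies
Poisson-like quantum noise (default 20000 photons per unattenuated
pixel), Gaussian electronic noise (sd 0.01) and an affine intensity
change (scale 1.3, offset 0.1) that forces the similarity's `s` factor
to matter. The C-arm angulations are jittered uniformly by +/-3 deg per
view around their declared values, emulating a manually rotated C-arm -
this is what makes the marker-based pose estimation consequential.
The "detector-skin distance" factor is modeled by shifting the
source-object distance, its only geometric effect in this model;
tissue-attenuation effects of waist circumference are reduced to the
soft-tissue level plus noise gain, a proxy and labeled as such.

The phantom does **not** emulate anatomical shape variation, pathology
(fractures, lytic or sclerotic lesions), scatter, beam hardening, or
detector blur beyond Gaussian noise. Passing tests therefore demonstrate
the correctness and internal consistency of the algorithmic chain and
its qualitative behavior (angulation dependence, depth-error dominance,
capture handling) - not clinical-grade accuracy on real anatomy, whose
headline numbers depend on cadaver-specific image quality that no
simulation reproduces.

## Study sizes and defaults used by the test and acceptance runs

C-arm defaults are SDD 1000 mm, SOD 600 mm, 0.3 mm pixels on a 768^2
detector - typical flat-panel values; the clinical protocol states no
intrinsics, so these are configuration, not claims. The marker-geometry
analyses use these defaults. The registration test cases run at desk
scale: 96^3-voxel phantoms at 1.5 mm spacing, 256^2 detectors at 1.2 mm
pitch, five vertebrae (T11-L3, centered on L1), eight markers, and a
full registration takes a few seconds per vertebra. The slice-thickness
study generates its baseline at 0.67 mm slice spacing (96 x 192 x 96
voxels) and degrades it by slab-averaging to 2.0 mm on the registration
side only, since the intraoperative scene is not degraded. Recovery
experiments use 20 seeds with initial offsets up to 5 mm / 5 deg; sweep
experiments use 20 replicates per RAD and register the three central
vertebrae of each case. These sizes are the package's chosen study
conditions; the generator accepts larger grids unchanged.

## Degenerate inputs and tie-breaks

* Collinear or coincident point sets make the Umeyama covariance rank
  deficient and raise an error rather than returning a spurious pose.
* Points at or behind the source plane cannot be projected; capture
  checking treats them as "not captured".
* A source inside the volume is rejected as degenerate geometry.
* An all-zero DRR gradient yields `s = 1` with a degeneracy flag.
* Marker detection on a blank image returns an empty table; matching
  requires at least five detections per view (the documented minimum
  marker count) and errors otherwise.
* Identical detections with identical geometries yield the identity
  relative pose; near-parallel rays triangulate to a fallback depth at
  the source-object distance instead of dividing by ~0.
* Equal-valued similarity maxima are resolved by CMA-ES sampling order,
  which is fixed by the seed; reruns are bit-stable.

## Known limitations

* Stage 1 is single-view: depth along the view axis is structurally
  unconstrained and is only resolved by stage 2.
* The isocentric constraint on relative-pose refinement assumes the
  patient does not move between the two exposures; free-form two-view
  geometry is available (`isocentric = FALSE`) but is ill-conditioned
  for coplanar markers.
* Registration accuracy at RAD 40 deg carries a heavier depth-error
  tail than at 90 deg; occasional distant local optima (about 5% of
  runs at desk scale) are flagged by their lower final similarity and
  surface as outliers in cohort summaries.
* The NIfTI header stores spacings as 32-bit floats; spacings that are
  not exactly representable (e.g. 0.67 mm) round-trip to header
  precision (~1e-7), not bit-exactly.
* DICOM series input is not supported; convert to NIfTI first.
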