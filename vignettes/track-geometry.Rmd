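---
title: "Scene geometry from a single vanishing point: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scene geometry from a single vanishing point}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(trackcal)
```

## The model

A home-stretch broadcast frame is modelled as a pinhole view of a ground
plane ruled with parallel lane lines 1.22 m apart. The world frame is
right-handed: `x` along the lanes toward the finish, `y` lateral, `z` up;
lane line `k` is `{y = k * 1.22, z = 0}`. A camera is five numbers plus a
position: azimuth (pan about the vertical; 0 = looking down the lanes,
positive toward the track), elevation (tilt below horizontal), roll
(fixed at 0 in the calibration path — the horizon of broadcast footage is
horizontal), horizontal field of view, and the centre `C` in metres.

The intrinsics assume square pixels, zero skew and a principal point at
the exact image centre, so the focal length in pixels is
`f = (W/2) / tan(fov/2)` and only the field of view is free. The
world-to-camera rotation is composed as

```
R = R_roll(optical axis) %*% R_elev(camera x) %*% R_align %*% R_azim(world z)
```

where `R_align` maps world `x` to the optical axis, world `-y` to image
right and world `-z` to image down. This composition is a design choice:
with roll = 0 it makes the ground-plane horizon exactly horizontal by
construction, which is the assumption the whole search rests on. (A
rotation written abstractly as a product of three elementary rotations
does not fix the order; ours is documented here rather than assumed
known.) The projection follows the standard column convention
`p ~ K [R | t] (X, Y, Z, 1)^T` with `t = -R C`.

Two consequences carry the method:

* the image of the lane direction — the main vanishing point — is
  `v0 = c + f (tan az / cos el, -tan el)`, independent of `C`;
* the *direction* from the principal point to `v0` is independent of `f`.

## From one vanishing point to a camera family

Given a detected `v0`, each candidate azimuth determines the rest:

1. **Elevation**: solved so the model direction matches the observed
   direction of `v0`. The signed angular mismatch is monotone in
   elevation (checked at runtime); bisection to 1e-6° is used even though
   a closed form (`sin el = -tan az * dy/dx`) exists — the closed form
   serves as the independent oracle in the tests.
2. **Field of view**: `f = |v0 - c| / |(tan az / cos el, -tan el)|` in
   closed form; candidates with fov outside (0.1°, 179°) are rejected.
3. **Position**: the detected lane lines are ray-traced to the ground
   from a reference camera at unit height. Ground-plane lane offsets are
   affine in the camera's lateral offset and height, so matching the
   1.22 m spacing and aligning the lane grid is a 2-parameter weighted
   least squares (weights damp near-horizon evidence, whose ray-traced
   positions blow up). Two components are unidentifiable from parallel
   lines alone and are fixed by convention: the position **along** the
   lanes (`x = 0`: the world origin sits at the camera's station) and the
   integer lane index (the first detected lane is lane 0). Round-trip
   comparisons against synthetic ground truth canonicalise the true
   camera by that integer lane offset before measuring position error.

The azimuth is swept over 1°–89° in 0.5° steps (mirrored for cameras
panned the other way); the result is a dense one-parameter family of
cameras, every one of which reprojects the lane grid onto the detected
lanes. The family is genuinely ambiguous — selection needs one extra
constraint (second vanishing point, camera height, or lateral offset),
resolved with linear interpolation between the bracketing azimuth
samples. A grid sweep is preferred over gradient descent deliberately: it
finds *all* solutions, not one.

## Lane detection

Detection is classical by design: Sobel gradient magnitude thresholded
into an edge map, a Hough line transform over (rho, theta) with 1 px /
0.5° resolution, iterative peak extraction with non-maximum suppression,
and contiguous runs of supporting edge pixels as segments. Each segment
is then refined to sub-pixel accuracy by a weighted total-least-squares
fit, preferring bright-ridge pixels (the painted line centre) over edge
pixels; fits whose lateral RMS exceeds `max_line_rms` mix several
converging lines and are discarded, and near-duplicate refits of one
physical line are deduplicated. Segments are filtered to the dominant
direction family (2° histogram, ±10° window) and merged into lanes.

The vanishing point is a majority vote: pairwise lane intersections,
grid-hashed at 10 px, modal cell, geometric median within 25 px — then
refined to the support-weighted least-squares concurrency point of the
vote-consistent lanes. The refinement matters because intersections of
near-parallel lanes scatter enormously *along* the lines while the
lateral line evidence stays tight. Pairs closer than 0.5° contribute no
vote; if that excludes every pair (long-lens frames whose vanishing point
lies tens of thousands of pixels out), the vote falls back to any
measurably converging pair and relies on the concurrency refinement — a
family parallel within angular noise still reports "at infinity". All
thresholds live in `detect_config()`.

## Pose auditing

Each frame's predicted 3D skeleton is placed by ray-tracing the reference
2D skeleton's lowest ankle onto the plane `z = ankle_height_m` (default
0.08 m — the ankle joint sits above the sole; placement is exact at
touch-down frames, which is where a running skeleton is actually
anchored), scaled so its projected height matches the reference, then
projected, aligned by closed-form least-squares scale + translation, and
measured: mean per-joint offset in px; the same scaled by
`athlete_height_mm / reference pixel height` (default 1800 mm — a
config, since the athlete's true height is not knowable from the image)
as an approximate mm figure; the 2D knee angle error; and an approximate
3D knee error obtained by rotating the lower leg ±1° about the knee
flexion axis (the hip–knee–ankle plane normal, central differencing),
recording the 2D angle sensitivity `s`, and rescaling the 2D error by
`1/s`. Side-on (sagittal) cameras give `s ≈ 1`; frontal views give small
`s` and amplify the implied 3D error, floored at `s_floor = 0.05` with a
warning to avoid division blow-up for degenerate viewing.

Touch-down detection marks frames where an ankle is at a local image-`y`
maximum with pelvis-relative displacement under a height-relative
threshold; consecutive qualifying frames collapse to midpoints.

Two correction strategies mirror domain knowledge: **movement** fits a
total-least-squares line to the ground anchors and translates each
skeleton onto it; **rotation** additionally yaws each skeleton about its
anchor to face the finish line. A limitation worth stating plainly:
because the audited metrics are computed after 2D similarity alignment,
a translation-only straightening is nearly invisible in them on synthetic
cases whose anchors are already straight — its benefit on real footage
comes from metre-scale placement errors that desk-scale fixtures do not
produce. The rotation strategy's improvement, by contrast, reproduces
cleanly under injected yaw drift.

## The synthetic generator

The renderer draws anti-aliased 3 px lane lines over a noisy, gently
graded background (so edge detection faces non-trivial input) and records
the exact analytic image lines and vanishing point as ground truth.
Radial distortion (`k1`, `k2`, radii normalised by half-width) exists
only as a render-time robustness knob; the calibration path is strictly
pinhole, and recovery degrades smoothly to ~0.2% position error at
`k1 = 0.02` (13 px displacement at the frame edge).

The runner is a parametric 17-joint gait, not a biomechanical model:
pelvis advancing at 8.5 m/s with cadence 10/3 steps/s (step length
2.55 m), sinusoidal fore–aft ankle motion with two-link leg inverse
kinematics (thigh/shank 0.48 m, knee angle cycling ≈ 73°–150°), arms in
counter-phase. Touch-downs are scripted: the phase is snapped so contact
events land exactly on frame times, where the ankle is at its lowest
point and momentarily stationary relative to the pelvis. Ground-truth
camera sampling couples viewing distance to zoom (8–16 m ground
footprint) and aims at the first lanes, emulating a stands-mounted
broadcast camera; azimuth 15°–75°, elevation 3°–30°, fov 5°–40°.

What passing on this generator does and does not show: it validates the
geometry and the estimators against exact ground truth, including under
2D jitter, knee bias, yaw drift, outlier lanes and mild lens distortion.
It does not exercise curved track sections, occlusion, motion blur,
compression artefacts, non-white lane paint, or real lens models — on
real broadcast footage the detection thresholds in `detect_config()` are
the knobs to revisit first, and per-frame vanishing points should be
stabilised with `smooth_vanishing_points()` before enumeration.

## Numerical choices and degenerate inputs

* Elevation bisection tolerance 1e-6°; fov closed-form; translation via
  weighted normal equations (the design matrix is 2-column, conditioning
  is unproblematic after horizon clipping at 10 px below the horizon).
* Projected-height scaling solves a 1D root by log-scale bisection to
  0.25 px with bracket expansion; non-convergence is an error, not a
  silent pass-through.
* `v0` at the principal point, directions flipped 180°, all-parallel lane
  families, skeletons with coincident hips or leg joints, rays at or
  above the horizon: all raise classed errors
  (`trackcal_error_*`) rather than returning garbage.
* Equidistant selection candidates resolve to the lower azimuth; a
  non-unimodal constraint residual warns and returns the global minimum.
* Problem sizes in the shipped tests — 50-camera recovery at 1280×720,
  1000-draw property loops, 30-frame evaluation sequences — were chosen
  as the smallest sizes at which the statistical checks (e.g. the
  Rayleigh-mean comparison at 5%) are stable.

## Known limitations

Single straight-section scenes only; no bend geometry, no multi-frame
bundle adjustment beyond median smoothing of `v0`; lens distortion is
rendered but never modelled in calibration; the mm-scaled reprojection
error is an image-scale approximation, not a true 3D distance; absolute
position along the lanes and the absolute lane index are unidentifiable
from lane lines and fixed by convention.
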