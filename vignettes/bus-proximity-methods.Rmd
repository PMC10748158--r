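---
title: "Measuring social distancing from a ceiling-mounted depth camera: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring social distancing from a ceiling-mounted depth camera}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BusProximity)
```

## The measurement model

A single stereo depth camera on the ceiling of a single-decker bus observes
up to 25 seating positions. Each capture yields a 16-bit depth matrix
(Z-depth in raw units, metres = raw × *S*) registered to a colour image on
which a pose-estimation model has produced, per passenger, 17 keypoints in
COCO order. All measurement anchors on the **nose keypoint** (index 0):
for airborne transmission the nose-to-nose separation is the natural
exposure distance, and the nose is the body part most reliably visible
from a ceiling viewpoint.

The distance between passengers 0 and 1 is computed in four steps:

1. read raw depth *d*ᵢ at the nose pixel (*u*ᵢ, *v*ᵢ);
2. scale to metres, *D*ᵢ = *d*ᵢ·*S*;
3. deproject through the intrinsic model to
   *P*ᵢ(X, Y, Z) — for an undistorted pinhole,
   X = (*u*−*c*ₓ)/*f*ₓ·Z, Y = (*v*−*c*ᵧ)/*f*ᵧ·Z, Z = *D*;
   Brown–Conrady distortion, when present, is inverted iteratively
   (25 fixed-point iterations, round-trip accurate to 10⁻⁶ m over the
   working depth range);
4. take the Euclidean norm *m* = ‖*P*₀ − *P*₁‖, for **every unordered
   pair** in the frame.

Assumptions worth making explicit: raw depth is *Z-depth* (distance along
the optical axis), the convention consumed by intrinsic deprojection, not
Euclidean range; the depth value at the single nose pixel represents the
nose (an optional 3×3 median fallback exists for invalid centre pixels but
defaults off, since the protocol is a direct lookup); float keypoints are
rounded half-up for the depth lookup but used unrounded in deprojection.
Raw value 0 encodes invalid depth and is signalled, never treated as 0 m;
measurements with an invalid depth, or a depth outside a plausibility
range (default 0.3–10 m, the interior working range of the device), are
skipped and tallied rather than fabricated.

## Risk bands and exposure statistics

Distances fall into three epidemiological bands: **< 1 m** (increased
risk), **1–2 m** (moderate), **> 2 m** (lower). The boundary values 1 m
and 2 m are assigned to the middle band, keeping the outer bands strictly
"less than" and "greater than" as their labels read.

Occupancy is expressed as detections over the 25-position visible
capacity, rounded to an integer percent — exact at every reachable count,
since one passenger is 4 %. Per occupancy level the package reports:

* the number of analysed images (those with ≥ 2 detections);
* per band, the total instance count and the mean instances per image;
* the **individual likelihood**: within one image, an individual belongs
  to a band if at least one other passenger is at a band distance (one
  occurrence suffices, and an individual may belong to several bands
  simultaneously); the likelihood is the mean over images of the fraction
  of individuals in the band.

Averaging per-image proportions (images weighted equally) is the default;
a pooled-ratio alternative (`weighting = "pooled"`) is provided because
the two differ when image counts are unequal across time. Individuals
with no valid measurement to anyone are excluded from that image's
denominator (they cannot qualify for any band, so including them would
deflate likelihoods by a measurement artefact, not a behaviour).

Per frame the three band counts always sum to the number of measured
pairs, and measured + skipped = C(n, 2) — an accounting invariant enforced
in code and asserted in the tests. A useful geometric sanity check on the
bands themselves: the planar area of the 1–2 m annulus is exactly three
times that of the < 1 m disc, which is why moderate-band counts dominate
as occupancy grows.

## Preprocessing

The capture device is mounted upside-down, so frames are first rotated
180° (depth[i, j] → depth[h−1−i, w−1−j]; keypoints (u, v) →
(w−1−u, h−1−v)); a provenance flag guards against double rotation.
Storage errors occasionally emit a frame twice, so byte-identical
duplicates (MD5 over the raw depth buffer) are removed, keeping first
occurrences — only exact duplicates, never perceptual near-duplicates.
The stereo pair's field-of-view mismatch leaves an invalid band around
the depth map, so detections whose nose lies within a 30-pixel margin of
any edge are excluded (Chebyshev margin, boundary-exclusive: a nose at
exactly 30 px survives). Finally, detections whose nose falls inside
user-drawn mask polygons (boundary-inclusive) are excluded; masks cover
handrails and reflective regions that produce false depth readings.

Two conventions here were genuinely open and are our choices: the
anchor for border/mask tests is the nose keypoint (any other anchor
would discard passengers whose nose is perfectly measurable), and a
nose-confidence floor (default 0.05) removes detections whose anchor the
pose model itself distrusts, counted separately in the run log. The
pipeline order is fixed — rotate → de-duplicate → confidence → border →
mask — and the pipeline is idempotent on its own output.

## Seat mapping

Reference features with known positions both in the image and on the bus
plan (seat backs, handrail fittings; 15 by default) are reduced to a
**horizontal distance plane**: the deprojected point's vertical component
is dropped (r = √(X² + Z²)) and the bearing taken as θ = *u*·HFOV/*w*
degrees, converted to Cartesian (r·sin(θ−HFOV/2), r·cos(θ−HFOV/2)).
The centring is a free gauge; any constant offset, and residual camera
tilt, are absorbed by the perspective transform. This reduction is exact
for a level camera; for a pitched camera it introduces a smooth
field-dependent distortion that the projective fit largely absorbs —
which is why reference points are best placed at passenger (nose) height
across the seating area, where the fit then interpolates.

The 3×3 transform *H* from distance plane to plan is estimated by **least
median of squares**: minimal 4-point samples (exhaustive when C(n, 4) is
small, otherwise 1000 random samples under a fixed seed), each solved by
a Hartley-normalised DLT, scored by the median squared plan-space
residual over all correspondences; the best model defines a robust scale
1.4826·(1 + 5/(n−4))·√med, inliers at 2.5 scales, and an ordinary
least-squares refit on the inliers is returned. LMedS needs no error
threshold and tolerates up to half the correspondences being grossly
wrong — the property exercised directly in the tests with 3/15 and 7/15
corrupted points.

Passenger points mapped through *H* are allocated by point-in-polygon
tests against the plan: seats A–F (front to back) × 1–4 (offside to
nearside) plus FM, the middle seat of the back row; the aisle is an
explicit polygon, not a fallback, because aisle dwell time is itself a
reportable quantity. Nine positions (A1, D2, D3, E2, E3, F1–F4) are
excluded from allocation by default — visibility there is too poor for
reliable detections — and are never returned. Plan polygons must be
interior-disjoint (validated at load time); boundary points go to the
first polygon in label order, deterministically. Occupancy event series
tolerate single-frame dropouts (one missing frame inside a run does not
split the event; configurable), and percent-of-time uses all recorded
frames as the denominator (a frames-with-detections denominator is a flag
away, but would overstate occupancy on empty days).

## The synthetic scene generator

Real footage of identifiable passengers cannot be published, so the
package ships a ground-truthed generator that stands in for it. It
emulates the capture conditions: a VGA (640×480) camera with 74°×62°
fields of view and a 1 mm depth unit, ceiling-mounted (2.2 m) above the
front of the seating area and pitched 25° towards the back so all 25
positions project inside the usable image; one frame every 5 s; 16-bit
depth with 2 % fractional Gaussian noise (the device's accuracy class at
2 m), truncated at ±3σ to reflect a bounded error specification;
duplicate-frame injection; and per-frame detection dropout.

Passenger behaviour is deliberately the simplest process with a tunable
stationary occupancy, because no behaviour model is available from data:
Poisson arrivals (default 0.3/min) with exponential dwell (default
10 min), blocked when every choosable seat is taken — an Erlang-loss
process whose stationary occupancy is truncated-Poisson with offered
load = rate × dwell (the closed form the tests check against; the initial
state is drawn from it, so a simulated day is stationary from the first
frame). Seat choice is categorical over free seats proportional to
preference weights, defaulting to window > middle > aisle to reflect
observed seat popularity qualitatively. Noses sit 1.2 m above the floor
at the seat centroid with isotropic 3 cm jitter per frame, avoiding
degenerate exact-grid placements. The static background is rendered
coarsely (room box plus seat cushion/backrest boxes) — sufficient because
the analysis only reads depth at keypoint pixels — and each head is a
small disc (~2 cm physical radius) carrying the noisy nose Z-depth into
the depth image, z-buffered against the scene.

What the generator does **not** emulate, and what passing tests therefore
do not show about real data: pose-model failure modes (false positives,
swapped keypoints, occlusion-induced keypoint drift), standing passengers
and limb articulation, specular and window-glass depth artefacts,
non-stationary demand (rush hours), and group boarding correlations.
Results on synthetic days validate the *measurement chain*, not the
detector.

## Numerical choices and degenerate inputs

* Depth quantisation: stored depth is 16-bit at *S* = 1 mm, so even
  noiseless distances recovered through stored frames carry ~1 mm
  quantisation; exactness checks on the geometry chain therefore use
  exact (u, v, depth) floats, and frame-path checks use a
  quantisation-scale tolerance.
* Pixel convention: 0-based coordinates, origin top-left, u = column;
  integer coordinates address pixel centres; half-up rounding for depth
  lookup.
* Homography degeneracies: minimal samples with any three collinear
  points are skipped; if no valid sample exists the estimation errors out
  rather than returning a silent fit; points mapping to infinity
  (homogeneous w ≈ 0) raise an error.
* Over-capacity frames, negative distances, unordered timestamps and
  inconsistent accounting all raise immediate errors — these indicate
  upstream bugs, not data conditions to be smoothed over.
* Determinism: every stochastic routine runs under a private RNG stream
  derived from an explicit seed and restores the caller's RNG state;
  identical configuration and seed byte-reproduce the entire artifact
  set.

## Problem sizes

The bundled analyses are sized to run comfortably on one CPU: the demo
service hour is 720 VGA frames (≈30 s end to end), unit tests use a
reduced 160×120 camera with identical fields of view where full
resolution adds nothing (the geometry is resolution-independent; only
pixel-margin parameters scale), and the stationarity check simulates
1800 frames at the small resolution with a shortened dwell so that the
effective sample size — computed from the birth–death relaxation time,
since frames 5 s apart are strongly autocorrelated — supports 3σ bounds.

## Known limitations

Contact *duration* is not accumulated across frames — identities are not
tracked, so statistics are per-image snapshots; exposure over a journey
is strictly worse than any single-frame figure suggests. The individual
likelihood treats bands independently; a passenger can (and at higher
occupancy usually does) qualify for several at once. Allocation accuracy
degrades for seats far from the camera — the motivation for the default
exclusion list — and the linear-in-*u* bearing used for the distance
plane is an approximation to the true ray angle whose residual the
homography absorbs only where reference points constrain it.
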