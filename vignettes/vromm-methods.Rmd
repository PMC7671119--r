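---
title: "Methods: videogrammetric kinematics and external-marker muscle strain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: videogrammetric kinematics and external-marker muscle strain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vromm)
```

## The problem

Suction-feeding fishes expand the buccal cavity in a few tens of
milliseconds by elevating the neurocranium, retracting the pectoral girdle
and depressing the hyoid apparatus. Quantifying this requires (i) 3D
skeletal kinematics from multi-camera high-speed video of skin-mounted
markers, and (ii) estimates of muscle strain and shortening velocity from
marker pairs spanning a muscle — for example the sternohyoideus (SH),
tracked between a urohyal marker and a marker at the muscle's caudal end.
Because skin markers ride on skin, not muscle, the package also implements
the statistics used to validate skin-marker strain against an implanted
-marker reference method (accuracy as a regression slope, precision as a
residual RMSE).

Every stage is testable without video data: a synthetic strike generator
produces ground-truth poses, marker trajectories, muscle-length series and
noisy multi-camera 2D observations.

## Camera model and triangulation

Each camera is an 11-parameter direct linear transformation (DLT) mapping
world coordinates (mm) to image coordinates (px):

$$u = \frac{L_1X + L_2Y + L_3Z + L_4}{L_9X + L_{10}Y + L_{11}Z + 1},
\qquad
v = \frac{L_5X + L_6Y + L_7Z + L_8}{L_9X + L_{10}Y + L_{11}Z + 1}.$$

Calibration solves the 11 coefficients by linear least squares from at
least six non-coplanar control points (a calibration object with 26
machined circles is the typical source). Triangulation inverts the same
equations: each camera contributes two linear constraints and the 3D point
is the least-squares intersection, with the RMS reprojection error as a
per-frame residual. Refraction through water and lens distortion are not
modelled explicitly; in practice the 11-parameter DLT absorbs them
approximately, and the synthetic cameras are ideal pinholes, so the
machine-precision closure tests are meaningful. Triangulation is purely
linear — no iterative refinement — which is sufficient at sub-pixel noise
levels; near-parallel ray geometries are flagged via the condition number
rather than "fixed". Frames seen by fewer than two cameras become missing
3D frames; gap handling is a separate, explicit step.

## Rigid bodies, the body plane, and precision

Per-frame poses are fitted by SVD-based orthogonal Procrustes (Kabsch)
with a reflection guard, minimising
$\sum_m \lVert R\,p_m + t - q_m \rVert^2$ over the markers visible that
frame (at least three, non-collinear). All markers are weighted equally.
The reported residual is the per-point RMS misfit, so with $M$ markers and
isotropic coordinate noise $\sigma$ its expectation is
$\sigma\sqrt{3}\sqrt{1 - 6/(3M)}$ — six pose degrees of freedom absorbed
out of $3M$ coordinates.

The *body plane* is a reference frame carried by five or more flank
markers. Its reference configuration is first re-expressed in a canonical
anatomical frame — X along the rostro-caudal principal axis of the
markers, Z the orthogonalised dorsal axis, Y (left-lateral) completing a
right-handed set, origin at the marker centroid — and then fitted exactly
like any rigid body. The fitted pose therefore *is* the anatomical
coordinate system (ACS) pose, and parenting to it removes whole-body
swimming motion from all downstream quantities.

Tracking precision is the standard deviation over time of each pairwise
marker-to-marker distance within one rigid structure (constant in life, so
any spread is measurement error), averaged over pairs. Two static markers
with iid coordinate noise $\sigma$ give a distance SD of
$\sigma\sqrt{2}$, which the tests verify by simulation. Gap-filled frames
are excluded from precision: interpolated coordinates would deflate the SD
artificially.

Interior gaps up to a configurable length (default 5 frames) are filled by
natural cubic splines per coordinate and flagged; longer gaps and gaps
touching the trial ends stay missing.

## Kinematic conventions

* **Excursions.** Marker world positions are expressed in the per-frame
  ACS; retraction is $-(X - \bar X_{\text{base}})$ and depression
  $-(Z - \bar Z_{\text{base}})$, so both are magnitude-positive, zeroed on
  a pre-strike baseline window.
* **Elevation.** The relative rotation
  $R_{rel} = R_{\text{body}}^{-1}R_{\text{neuro}}$ is decomposed in Z-Y-X
  Euler order; elevation is the Y-axis angle in degrees, baseline-zeroed,
  dorsal rotation positive. The Euler order is a documented choice — a
  joint coordinate system convention names the axes but not the order —
  and for near-planar pitching the Y angle is insensitive to it; frames
  within a degree of gimbal lock are flagged. The generator applies its
  elevation pulse as a rotation about the ACS Y axis, so the convention is
  self-consistent end to end.
* **Peak gape.** Detected as the global maximum of the jaw-marker distance
  after an optional 5-frame moving-average smooth, ties resolved to the
  earliest frame. Real trials may instead supply `t_peak_gape` in the
  events CSV; both paths are supported. (Which markers define gape is an
  operationalisation of this package: the generator carries an explicit
  jaw-marker pair whose distance peaks exactly at peak gape.)
* **Baseline.** One shared window (default: first 20 frames) zeroes
  excursions and elevation *and* defines initial muscle length, so all
  "pre-strike" references mean the same epoch.

## Muscle strain and shortening velocity

With $L_i$ the mean pre-strike length of a marker pair, strain is
$s(t) = 100\,(L_i - L(t))/L_i$ (shortening positive) and velocity is the
negated derivative of normalized length in units of $L_i\,s^{-1}$
(shortening positive). The normalized length is optionally smoothed by a
zero-phase 4th-order Butterworth low-pass (forward-backward over a
mirror-padded copy, so no phase lag biases latencies and no start-up
transient leaks into the trial), then differentiated by central
differences, one-sided at the ends. The same filtered series feeds strain
and velocity, so their peaks share one smoothing.

The default cutoff is 25 Hz at 500 fps — strike events last tens of
milliseconds — and is configurable (0 disables filtering). Two numerical
consequences are worth knowing and are exercised by the tests: a 60 ms
raised-cosine pulse loses about 0.3 percentage points of peak strain
through this filter (its fundamental sits near 17 Hz), and the velocity
peak is attenuated more, since differentiation weights the higher
harmonics. With filtering off, the pipeline reproduces generator strain to
1e-6 and peak velocity to within discretisation error (<1 %). Velocity
peaks are searched over interior frames only, because one-sided endpoint
differences carry twice the noise variance.

Event-relative reporting returns peak strain and velocity with latencies
relative to peak gape (ms), plus velocity *at* the peak-gape frame, the
quantity used to compare species' shortening speeds at the moment of peak
suction power.

## Method validation statistics

External (skin-marker) strain is regressed on the simultaneously measured
internal reference strain, frame by frame, per trial. The slope against an
ideal slope of 1 is the method's accuracy; the residual RMSE (% strain)
its precision; $100\,(1 - \overline{\text{slope}})$ the underestimation
margin. The regression includes a free intercept by default (robust to
baseline offsets between methods; configurable), pairs are compared at
identical frames with no lag estimation, and pooling averages per-trial
slopes rather than refitting one pooled regression — each strike is one
experiment. Group summaries use means of per-individual means with SEM
across individuals when individuals differ (one-way fixed-effects ANOVA,
`stats::oneway.test` with equal variances, decides); the pooled-across-
trials summary is also returned for the homogeneous case. Correlations of
peak excursions with peak elevation are Pearson tests per variable.

## The synthetic strike generator

The generator is the package's ground truth, not a fixture. Its defaults
describe one idealised strike: 500 fps, 0.2 s trial, peak gape at 0.1 s;
raised-cosine kinematic pulses (width 60 ms) peaking at peak gape with
amplitudes 8° elevation, urohyal retraction/depression 2/3 mm, cleithrum
1.2/0.8 mm (urohyal depresses more than it retracts, the cleithrum the
reverse, and urohyal excursions exceed cleithrum excursions); a
raised-cosine strain pulse (width 60 ms) peaking 15 ms after peak gape
with SH strain 7.2 % of $L_i$ (epaxial 3.9 %). With the lag equal to a
quarter pulse width, peak shortening velocity falls exactly at peak gape.
The raised-cosine shape is an analytic convenience: smooth, bounded,
unimodal, with a closed-form derivative for velocity oracles.

Skin slip — the imperfect coupling of skin to muscle — is modelled as a
pure multiplicative attenuation: the external marker pair is placed so
that its distance is exactly $L_i(1 - \alpha\,s_{\text{int}}(t)/100)$,
with $\alpha \in (0,1]$ (default 1). This is a phenomenological link, not
a mechanics model: it reproduces the observed *effect* (a regression slope
$\alpha < 1$) without claiming anything about collagen-fibre behaviour.

Cameras are ideal 1024×1024 pinholes at 0.7 m, two oblique views ±35°
plus an optional perpendicular third, expressed as DLT models. Rendering
projects every marker and adds iid Gaussian pixel noise; the default of
0.75 px is chosen so that the synthetic neurocranium tracking precision
(mean pairwise-distance SD) lands near 0.17 mm, the precision typical of
careful real marker tracking; dropout can be injected as missing values,
and points behind a camera are flagged missing rather than projected.
Whole-body drift (30 mm/s) and a slow 1.5° yaw exercise the body-plane
parenting. The five body-plane markers are laid out exactly coplanar with
principal axes aligned to the body frame — an idealisation that makes the
zero-noise closure tests exact to machine precision.

What the generator does *not* emulate: refraction and lens distortion,
occlusion geometry, auto-tracking failures, asymmetric or multi-peaked
strikes, skin-slip dynamics beyond a constant multiplier, and deformation
of the "rigid" marker sets. Passing tests therefore demonstrate that the
*computational* pipeline is correct and well-conditioned at realistic
noise levels — not that skin markers track muscle in any particular
species.

## Problem sizes and seeds

Test and demonstration runs use one 101-frame strike (0.2 s at 500 fps)
with 14 markers and 2–3 cameras; Monte-Carlo checks use 300–2000
replicates of small statistical kernels and 20 replicate strikes for
parameter recovery; the bundled study simulation uses 22 strikes from 4
simulated individuals, mirroring a realistic strike count. All stochastic
steps take explicit integer seeds and are bit-reproducible; the RNG state
of the calling session is saved and restored around every seeded
operation.

## Known limitations

* The linear DLT has no distortion terms; heavily distorted optics would
  need undistortion upstream.
* Euler-angle elevation degenerates near ±90° pitch (flagged, not fixed);
  suction strikes stay far from gimbal lock.
* The 25 Hz default filter measurably attenuates sharp peaks (see above);
  choose the cutoff to fit the event bandwidth, or disable filtering for
  noiseless data.
* Precision excludes gap-filled frames but not low-confidence
  triangulations; inspect the QC section of the trial report.
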