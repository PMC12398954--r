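---
title: "Tracking respiratory motion with an RGB-D camera: methods and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking respiratory motion with an RGB-D camera: methods and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgbdtrack)
```

## The problem

External-beam radiotherapy of thoracic and abdominal tumors must account
for respiratory motion: the treated anatomy moves by up to a few
centimetres with breathing. Surface-guided radiation therapy (SGRT)
systems monitor an external surrogate — here, a small triangular sticker
on a relatively rigid region of the chest or upper abdomen — and report
its displacement in room coordinates in real time, so that gating or
breath-hold techniques can be applied. Commercial SGRT systems are
accurate but expensive; a consumer RGB-D (color + depth) camera can fill
the same monitoring role at a fraction of the cost, provided its accuracy
is demonstrated.

`rgbdtrack` implements such a monitoring pipeline end to end, *plus* the
validation framework used to qualify it, *plus* a synthetic RGB-D phantom
simulator that stands in for the camera and motion phantom hardware. Every
stage is therefore testable on a desk: simulated frames with exact ground
truth flow through the same preprocessing, detection, and
pixel-to-millimetre conversion code that real frames would.

## The pipeline

Each frame carries a color image and a per-pixel depth map in mm
(0 marks invalid depth), both 848 x 480 at 30 fps in the nominal setup.
Per emitted frame the tracker:

1. **Enhances contrast** in the region of interest (ROI) with CLAHE
   (contrast-limited adaptive histogram equalization), applied to the
   luminance channel with chroma preserved, to stabilise marker appearance
   under ambient-light changes.
2. **Detects the triangular marker** inside the ROI. The reference
   detector is classical: pixels are scored by their color distance to a
   robust planar background model (absorbing uniform backgrounds and
   smooth illumination gradients), thresholded by Otsu's method, and
   grouped into connected components. Each component's contour is
   simplified with Douglas–Peucker at 2 % of its perimeter (floored at
   1.5 px, the scale of rasterization staircases, with a vertex-decimation
   pass that removes corner-cut artifacts); a candidate survives only if
   it is a 3-gon with area >= 50 px, solidity >= 0.9, and a triangle-fit
   residual below 25 %. The stage is a contract — `detect_marker()`
   returns masks, vertices, sub-pixel centroids and scores — so a learned
   instance-segmentation backend can be swapped in without touching
   downstream code.
3. **Reads depth at the centroid** through a five-frame temporal median
   (rejecting single-frame depth anomalies of any magnitude) averaged over
   a small patch, excluding invalid pixels.
4. **Deprojects to room coordinates** with the pinhole model:
   `x = (u - cx) z / fx`, `y = (cy - v) z / fy`. The camera principal axis
   is aligned with the couch longitudinal axis (IEC 61217), so depth
   change is longitudinal motion while centroid motion scaled by depth
   gives the vertical and lateral components.
5. **Reports displacements** relative to a baseline pose, the mean of the
   first five tracked frames. If the marker leaves the ROI, tracking
   suspends (status `SUSPENDED`) until the user resets the ROI
   (`reset_roi()`); the baseline is preserved across the gap. Frames with
   no valid depth in the patch are emitted as `MISSING_DEPTH` and excluded
   from metrics rather than interpolated.

Sign conventions are fixed as: `z_long` positive away from the camera,
`y_vert` up-positive, `x_lat` right-positive facing the image; image rows
grow downward, hence `v = cy - fy y / z`. No lens distortion is modelled
(rectified streams assumed).

## The simulator

`render_sequence()` produces ground-truthed frame sequences emulating the
physical validation setups:

* **Flat surface** perpendicular to the camera axis at 400–1500 mm,
  carrying the marker — the 1D motion experiments.
* **Torso surface**: a parabolic-cylinder section (apex toward the camera,
  configurable half-width and bulge) — enough curvature to exercise
  curved-surface tracking without a mesh asset. The marker patch rides the
  surface rigidly (vertex distances constant), matching placement on a
  rigid chest-wall region.
* **Waveforms**: sinusoids of 5–30 mm amplitude at 0.1–0.33 Hz
  (6–20 cycles/min), and a breath-hold trace — regular breathing
  interrupted by two constant plateaus over 110 s, with raised-cosine
  transitions (width 1.5 s) keeping the trace continuous. The published
  volunteer recording behind the irregular-motion test is not public, so
  the simulator substitutes this parameterised waveform with the same
  structure (two deep-inspiration holds, 110 s). An optional `delay_s`
  pre-roll keeps the surface static while the tracker acquires its
  baseline, as an operator would before starting the motion program.
* **Depth noise**: i.i.d. Gaussian per pixel per frame, with bias and SD
  linearly interpolated between measured anchors — 0.03 ± 0.13 mm at
  560 mm and 0.65 ± 0.61 mm at 1120 mm, the static precision of the
  target camera. Only per-distance bias/SD are published, so no spatial or
  temporal noise correlation is modelled, and the static anchors are
  reused for dynamic scenes; both are deliberate simplifications.
  Consequently, passing tests demonstrate correctness of the geometry,
  detection and statistics under this noise model — not robustness to
  correlated depth artifacts, specularities, or occlusions of real
  cameras.
* **Ambient light**: optional per-frame global gain/offset jitter on the
  color image, which is what the CLAHE stage exists to absorb. The static
  background texture derives from the scene alone, so changing the seed
  changes only the noise realization, never the ground truth.

Rendering is anti-aliased (4 x 4 supersampling), which makes the
sub-pixel centroid meaningful: boundary pixels blend marker and
background in proportion to coverage, and the detector's
contrast-weighted centroid recovers the continuous triangle centroid to
a few hundredths of a pixel.

## Detector scoring

Detection quality is quantified with single-class mean average precision
(mAP): predictions are matched to ground-truth masks greedily by score at
an IoU threshold (0.5 by default; the threshold used for the published
figure is not stated), and AP integrates the right-continuous precision
envelope over recall. `render_detection_dataset()` builds the benchmark:
triangles of random size (20–80 px), shape jitter, rotation and color on
skin-tone-like or gray backgrounds with gradients and pixel noise. The
reference detector reaches mAP = 1.0 on 60 such images, the same figure
reported for the trained instance-segmentation network it stands in for;
re-training that network is out of scope here.

## Validation statistics

All statistics operate on paired measured/nominal series in mm:

* **TSR** (tracking success rate): percentage of frames deviating
  *strictly less than* 2, 1.5 and 1 mm from nominal.
* **MAE**: mean absolute error at paired points.
* **Pearson r**, with constant series rejected as undefined.
* **Bland–Altman**: differences are camera − reference; bias is their
  mean, limits of agreement are bias ± 1.96 SD with the n−1 sample SD.
  The 1.96 multiplier (not 2.0, not t-based) is fixed because the
  published limits are consistent with it (e.g. −0.01 − 1.96·0.35 =
  −0.696 → −0.70). The agreement plot's x-axis uses the mean of each
  pair.
* **Trace alignment**: the measured trace is linearly interpolated onto
  the reference timestamps restricted to the overlap, after a
  cross-correlation search (1 ms grid, ± 500 ms default window) for the
  small systematic time offset between unsynchronised systems.
* **Latency**: the phase shift of the fundamental periodic component,
  found as the cross-correlation peak on a 1 ms grid with parabolic
  refinement; the uncertainty follows from the residual scatter and
  curvature of the parabolic fit. The search window must stay below the
  test signal's half-period — a peak on the window boundary is rejected
  as ambiguous rather than silently aliased.
* **Drift**: SD of the tracked coordinate overall and per time window;
  windows with fewer than two samples are dropped.
* **Fitted nominal**: for longitudinal experiments the nominal series may
  be a least-squares sinusoid fitted to the measurement
  (`fit_sinusoid()`), mirroring difference panels computed against fitted
  motion; both raw-program and fitted modes are supported.

## Numerical choices and degenerate inputs

* Invalid depth sentinel is 0 mm; invalid pixels are excluded from the
  patch median, and an all-invalid patch yields `MISSING_DEPTH`.
* Median warm-up: the first four frames use the median of the available
  window rather than being dropped, so the trace has one sample per
  frame.
* Decimation (default 3 at 30 fps, i.e. ~10 Hz output) changes sampling
  only: a decimated trace is a subsequence of the undecimated one. The
  rate mirrors the effective throughput of the acquisition pipeline after
  ROI selection and filtering, rather than modelling compute load.
* Multiple surviving detections: highest score wins, ties broken by
  larger area (a single marker is assumed).
* mAP edge conventions: no ground truths and no predictions is 1.0;
  predictions without ground truths, or ground truths without
  predictions, is 0.0.
* ROI re-centering on the tracked centroid is available
  (`recenter_roi = TRUE`) but off by default: the fixed-ROI
  suspend-on-exit behaviour is the documented safety mechanism.
* The exact intrinsics of the original deprojection reference are not
  published; the functional pinhole form is implemented with
  configurable parameters (default 848 x 480, fx = fy = 600 px).

## Problem sizes used in the tests

The test suite and acceptance script run at desk scale by choice: a
240 x 160 px sensor with the marker at 560 mm for end-to-end scenes
(geometry unchanged, rendering cheap), 60-image detection benchmarks,
600-frame error-model simulations and 10^5-sample Monte-Carlo checks of
the analytic statistics. The end-to-end noiseless sinusoid recovery
(MAE < 0.1 mm, r > 0.999) uses 270 frames at 30 fps.

## On-disk formats

Traces are CSV (`t_s,x_lat_mm,y_vert_mm,z_long_mm,status`, 17 significant
digits, lossless round-trip). Sequences are directories of 8-bit RGB PNG
color frames plus depth PNGs storing 16-bit 0.1 mm-unit integers packed
losslessly into the red (high byte) and green (low byte) channels, with a
CSV manifest and JSON metadata. Reports serialize to JSON; figures
(trace overlay, Bland–Altman scatter with bias/limits lines) are ggplot2.

## Known limitations

* The simulator's noise model is uncorrelated Gaussian; real depth
  cameras show spatially correlated noise, flying pixels and
  material-dependent artifacts.
* The classical detector assumes the marker is the dominant
  color-contrast object within the ROI; cluttered ROIs may need the
  pluggable learned backend.
* Hardware-bound quantities (true sensor latency, thermal drift,
  co-acquisition against a clinical system) cannot be reproduced in
  simulation; the package validates the corresponding *estimators* on
  constructed inputs instead.
* Lateral displacement is computed and stored but not evaluated by
  default, as external-surrogate monitoring conventionally tracks the
  vertical and longitudinal components.
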