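# rgbdtrack

Respiratory motion monitoring for radiotherapy with a consumer RGB-D
(color + depth) camera — implemented as a fully testable, desk-scale R
package.

## What this is for

Thoracic and abdominal radiotherapy must manage breathing motion.
Surface-guided systems track an external surrogate — here a triangular
sticker on a rigid region of the chest — and report its displacement in
room coordinates in real time. `rgbdtrack` implements the full low-cost
pipeline around an RGB-D camera, and everything needed to qualify it:

* **Camera geometry** — pinhole projection/deprojection tying pixels and
  depth to millimetres: `x = (u - cx) z / fx`, `y = (cy - v) z / fy`,
  with the camera axis aligned to the couch longitudinal axis (IEC
  61217). Depth change gives longitudinal motion; optical centroid
  motion scaled by depth gives the vertical/lateral components.
* **Preprocessing** — CLAHE contrast enhancement of the color stream and
  a five-frame temporal median on depth (kills single-frame anomalies of
  any magnitude).
* **Detection** — a classical triangle detector (robust planar
  background model → Otsu threshold → contours → Douglas–Peucker
  3-gon fitting with solidity and fit-residual gates) behind a pluggable
  contract, scored by single-class mean average precision (mAP).
* **Tracking** — per-frame orchestration with ROI management, sub-pixel
  centroids, baseline referencing, decimation to the ~10 Hz effective
  rate, and suspend-on-ROI-exit / `reset_roi()` semantics.
* **Validation statistics** — tracking success rate (TSR at <2/1.5/1 mm,
  strict), MAE, Pearson r, Bland–Altman agreement (bias ± 1.96 SD limits),
  trace alignment with phase-shift correction, cross-correlation latency
  estimation, and drift statistics.
* **Synthetic phantom** — a ground-truthed RGB-D simulator (flat surface
  or curved torso, sinusoidal and breath-hold waveforms, Gaussian depth
  noise anchored at 0.03 ± 0.13 mm @ 560 mm and 0.65 ± 0.61 mm @
  1120 mm) replaces the camera hardware so every stage runs on a desk.

See the vignette (`vignettes/respiratory-motion-tracking.Rmd`) for the
model, parameter and design details.

## Worked example

Simulate a 20 mm, 0.2 Hz vertical sinusoid on a flat surface at 560 mm
(1 s static pre-roll for the baseline), track it through the full
pipeline, and validate against the simulator's ground truth:

```r
library(rgbdtrack)

intr  <- camera_intrinsics(fx = 600, fy = 600, cx = 120, cy = 80,
                           width = 240, height = 160)
wf    <- waveform_sinusoid(amplitude_mm = 20, frequency_hz = 0.2,
                           duration_s = 9, sample_rate_hz = 30, delay_s = 1)
scene <- scene_spec("flat", base_depth_mm = 560,
                    marker = marker_spec(side_mm = 25),
                    motion = list(vertical = wf), fps = 30, duration_s = 9)
seq   <- render_sequence(scene, intr, noise = depth_noise_model(), seed = 1)
seq
#> frame_sequence: 270 frames @ 30 fps, 240x160 px, surface=flat

trace <- track_sequence(seq, tracker_config(roi = c(70, 15, 100, 130),
                                            decimation = 3))
gt <- seq$ground_truth$y_vert_mm[seq(1, 270, by = 3)]
eval_report(trace$y_vert_mm, gt, axis = "vertical")
#> eval_report (vertical axis, n = 90)
#>   TSR(<1 mm): 100.00%
#>   TSR(<1.5 mm): 100.00%
#>   TSR(<2 mm): 100.00%
#>   MAE: 0.041 mm
#>   Pearson r: 1.0000

bland_altman(trace$y_vert_mm, gt)
#> Bland-Altman (n = 90): bias 0.010 mm, SD 0.048 mm, LoA [-0.083, 0.103] mm
```

Every frame stays within 1 mm of the programmed motion (TSR 100 %), the
mean absolute error is 0.04 mm, and the Bland–Altman limits of agreement
against ground truth are about ±0.1 mm — the tracker recovers the
programmed waveform essentially to the depth-noise floor at this
stand-off.

A command-line wrapper covering `simulate` / `track` / `evaluate` /
`report` is installed at
`system.file("cli", "rgbdtrack", package = "rgbdtrack")`; scenes and
tracker settings come from a single YAML config.

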