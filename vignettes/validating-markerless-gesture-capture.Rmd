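---
title: "Validating markerless 3D gesture capture against optical motion capture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating markerless 3D gesture capture against optical motion capture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Gesture researchers want the 3D positions of a speaker's hands, arms and face
without the cost and intrusiveness of optical motion capture (MoCap).
Deep-learning human pose estimation (HPE) promises exactly that from ordinary
video: each video frame yields per-keypoint pixel positions with a confidence
value, and either a second calibrated camera (stereo triangulation) or a
monocular lifting model turns those into 3D coordinates. The question this
package operationalises is: *how far are those 3D keypoints from what a MoCap
system would have measured, and is the spatial region swept by the hands — the
gesture space — reproduced faithfully?*

`hpeval` implements the full evaluation pipeline as reusable, tested
components:

1. **Stereo triangulation** of per-camera 2D keypoint streams through a
   calibrated pinhole model (`triangulate_streams()`), with the fused
   confidence set to the *minimum* of the two per-camera confidences — a
   keypoint seen poorly by either camera yields an unreliable 3D point.
2. **Temporal alignment**: clapperboard trimming, exclusion of a margin at
   each end (the experimenter is visible near the claps), and uniform
   downsampling of the 100 fps MoCap stream to the 30 fps video grid
   (`trim_to_claps()`, `downsample_uniform()`).
3. **Spatial alignment**: a confidence-gated validity mask, tape-measure
   scaling for monocular streams, and a least-squares rigid (Kabsch)
   registration onto the MoCap frame (`build_validity_mask()`,
   `estimate_scale()`, `fit_alignment()`). A rigid map — not affine — is
   used deliberately: shearing a skeleton deforms it and flatters the error.
4. **Metrics and statistics**: per-keypoint Euclidean error tables,
   per-group one-way repeated-measures ANOVAs with Bonferroni post-hoc
   paired comparisons, and voxelized gesture-space occupancy compared with
   the Dice coefficient (`euclid_errors()`, `rm_anova()`,
   `pairwise_bonferroni()`, `voxelize()`, `dice_curve()`).
5. A **synthetic session generator** (`sim_config()`, `generate_study()`)
   that emulates the whole recording setup, so every stage can be exercised
   end to end with known ground truth.

## The statistical model

Thirteen upper-body keypoints are analysed: thumb and middle-finger tips,
wrists, elbows, shoulders, cheeks and chin, each side where applicable. For
analysis they are folded into **10 groups**: the two shoulders together, and
the three face points together; all others individually per side.

For each group, the dependent variable is the mean Euclidean distance
$e = \lVert \hat{x} - x_{\text{mocap}} \rVert$ over valid frames, one value
per participant per method. With $n$ participants and $k$ methods the
classical within-subject decomposition gives

$$F = \frac{SS_{\text{method}} / (k-1)}{SS_{\text{error}} / ((n-1)(k-1))},
\qquad
\eta_p^2 = \frac{SS_{\text{method}}}{SS_{\text{method}} + SS_{\text{error}}},$$

so the default $10 \times 4$ design has $df_1 = 3$, $df_2 = 27$. No
sphericity correction is applied by default (the reference analysis reports
uncorrected dfs); Greenhouse–Geisser is available via
`rm_anova(gg_correction = TRUE)`. Post-hoc comparisons are paired t-tests
with p-values multiplied by the number of pairs (6 for four methods, capped
at 1) and 95% CIs from the t distribution with $n-1$ df.

A (frame, keypoint) cell enters the analysis only when it is **valid**: the
MoCap marker was tracked *and* every method reports confidence at or above
the threshold $\tau$ (default 0.3; a tie at exactly $\tau$ counts as valid).
The same joint intersection is used both for fitting the alignment and for
the error analysis — the strictest consistent reading, so every method is
compared on identical frames.

Gesture space is quantified from the pooled left + right wrist positions
over all frames and sequences (handedness and time are not distinguished):
space is divided into half-open cubic voxels $[iv, (i+1)v)$ anchored at the
aligned-frame origin, a voxel is occupied if any wrist position falls in it,
and agreement between two occupancy sets is
$\mathrm{Dice} = 2|A \cap B| / (|A| + |B|)$. The grid anchor and floor
indexing are package conventions — the boundary convention is otherwise
arbitrary, and half-open cells make indices unambiguous (negative
coordinates floor downward).

## What the synthetic generator emulates

No recordings are distributed with the evaluation design, so the generator
reproduces the *statistical structure* the analysis assumes, with defaults
fixed to the study conditions:

* 10 participants × 8 sequences; 60 s of gesturing between two clapperboard
  strikes, padded by 2 s on each side; 5 s margins excluded from analysis.
* Three 1920×1080 @ 30 fps cameras 3 m away — one frontal, two diagonal at
  ±35° — with focal length 1500 px and mild radial–tangential distortion;
  extrinsics expressed relative to camera 1 (identity rotation, zero
  translation). A 100 fps MoCap reference in its own, rotated + translated
  coordinate frame that the alignment stage must recover.
* Motion: a kinematic chain (shoulder → elbow → wrist → fingertips) driven
  by sums of 2–5 random harmonics in 0.2–2 Hz on the joint angles, with
  per-participant bone lengths drawn from U(260, 320) mm, whole-body sway,
  head bob and slow head yaw. Segment lengths are exact by construction, so
  the elbow–shoulder distance equals the participant's "tape-measured"
  length to machine precision.
* Observation noise: Gaussian pixel noise (default sd 2 px) on 2D
  detections; confidence values that drop when a keypoint is geometrically
  hidden — behind the torso capsule, a fingertip pointing away from the
  camera behind its own hand, or a cheek on the far side of the head — so
  low-confidence events correlate with pose as in real HPE rather than
  being drawn independently. Shoulders are never occluded (they lie on the
  torso outline), so, as in the emulated recordings, shoulder keypoints are
  detected in every frame.
* A fixed outward per-keypoint **anatomical marker offset** (default 10 mm)
  between MoCap markers (skin-mounted, bone-referenced) and HPE keypoints
  (inside the body). This is a systematic bias, not noise: a single rigid
  transform cannot remove differently-oriented per-keypoint offsets, which
  puts a floor under the achievable error exactly as the anatomical
  mismatch does in real validations.
* MoCap marker loss as a per-frame hazard with *persistent* dropout: a lost
  label never recovers within a sequence, mirroring tracking failures that
  are excluded rather than relabelled.
* Two monocular 3D streams in the frontal-camera frame, each scaled by a
  hidden per-participant factor from U(0.8, 1.25) and corrupted by a
  *shared per-frame depth wobble* (default sd 150 mm) plus small
  per-keypoint jitter (default 20 mm). Correlated depth error is the key
  realism choice: real monocular lifting misplaces the whole body in depth
  far more than it distorts limb proportions, which keeps the tape-measure
  scale estimate identifiable while still degrading 3D accuracy severely.
  The depth-wobble magnitude is a modelling choice (the reference analysis
  reports monocular depth error only qualitatively) and is exposed in
  `sim_config()`.

Four methods result: `tri_13` (diagonal stereo pair, the primary method),
`tri_12` (frontal–diagonal pair), and `mono_a` / `mono_b`. Two stereo and
two monocular methods give the four stereo-vs-mono post-hoc contrasts of
interest.

What the generator does **not** model: photorealistic appearance, detector
biases that correlate across cameras, hand articulation beyond two
fingertip points, rolling shutter, calibration error, or time-varying
camera sync drift. Tests passing on this simulation therefore validate the
*pipeline* — geometry, alignment, masking, statistics — not any specific
HPE model's accuracy on real video.

## Numerical choices and degenerate inputs

* Triangulation solves the two-view DLT system on undistorted normalized
  coordinates by least squares in the $w = 1$ gauge, via closed-form 3×3
  normal equations; this vectorises over whole streams. A midpoint-method
  triangulator is provided as an independent cross-check. Near-parallel
  rays (normal-matrix determinant below `1e-10` relative) are flagged
  missing rather than returned.
* Undistortion is fixed-point iteration: 20 iterations or change < 1e-12.
* `rigid_fit()` is the SVD (Kabsch) solution with reflection correction
  (`det(R) = +1` always, even for near-planar inputs); configurations with
  fewer than 3 pairs or near-collinear geometry are errors, not results.
* Clap convention: the clap frames themselves are excluded (content lies
  strictly between claps). The source convention is unstated; this one is
  fixed and documented.
* Downsampling is nearest-index selection `round(i(N-1)/(T-1))` with both
  endpoints preserved — no interpolation is invented. Because the 30 fps
  grid does not subdivide the 100 fps grid, selected MoCap frames are up to
  5 ms off the video timestamps; with wrists moving ~1 m/s this contributes
  a few mm that no spatial alignment can remove. Recovery of hidden
  transforms is therefore exact (sub-µm, sub-µdeg) on a static pose and
  accurate to a few mm on a moving one; an interpolating variant exists
  behind `method = "linear"` for sensitivity checks.
* Sums of squares that vanish to rounding (identical method columns) are
  clamped to zero so that `F = 0`, `p = 1` rather than a 0/0 artifact.
* Empty aggregation cells are *absent*, never zero; a zero-variance paired
  contrast reports `p = 0` with a `degenerate` flag.
* All randomness derives from one base seed through named substreams
  (participant / sequence / camera / method), so adding a camera or method
  never perturbs other draws, and every export is byte-identical under the
  same seed.

## Problem sizes used in the shipped checks

The package's own test-suite and acceptance script run the full default
design (10 × 8 sequences, 60 s at 30 fps, 100 fps reference — about 5.5
million valid error records) for the study-level claims, and smaller
configurations (2 × 2 sequences, 14–16 s) for file-pipeline and
reproducibility checks, which exercise identical code paths at lower cost.

## Known limitations

* The evaluation validates geometry and statistics against a simulated
  ground truth; absolute error magnitudes on real recordings depend on the
  HPE models and calibration quality and are not predicted by the defaults.
* One rigid transform per (participant, method) assumes the rig and MoCap
  frames do not drift within a participant's session.
* The monocular error model is a two-component Gaussian; real monocular
  lifting errors are heavier-tailed and pose-dependent.
* Only two-camera triangulation is implemented; with more cameras a
  multi-view least squares would be the natural extension.
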