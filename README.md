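# hpeval

Validation of markerless 3D human pose estimation (HPE) against optical
motion capture (MoCap) for gesture research.

## The problem

Gesture researchers need 3D positions for a speaker's wrists, elbows,
fingertips and face, but optical MoCap is expensive, space-hungry and its
retroreflective markers can inhibit natural gesturing. Deep-learning pose
estimators recover per-frame 2D keypoints with confidence values from plain
video; two calibrated cameras plus triangulation — or a monocular lifting
model — turn those into 3D. Before replacing MoCap with video, one has to
quantify how far the HPE keypoints land from the MoCap reference and whether
the *gesture space* (the region the hands sweep) is reproduced.

`hpeval` implements that evaluation end to end, for 13 upper-body keypoints
(thumb and middle-finger tips, wrists, elbows, shoulders, cheeks, chin):

* **Geometry** — pinhole projection with radial–tangential distortion,
  confidence-gated two-view DLT triangulation (fused confidence =
  min of the pair), re-projection RMS QC, and SVD (Kabsch) rigid
  registration.
* **Alignment** — clapperboard trimming with margin exclusion, uniform
  nearest-index downsampling of the 100 fps MoCap stream to the video
  grid, a joint validity mask (MoCap tracked *and* every method's
  confidence ≥ τ = 0.3), tape-measure scaling for monocular streams, and
  one rigid transform per participant × method fitted from all sequences.
* **Metrics & statistics** — per-keypoint Euclidean-error tables folded
  into 10 analysis groups; per-group one-way repeated-measures ANOVA
  (`F = MS_method / MS_error`, partial η² = SS_method / (SS_method +
  SS_error); df1 = 3, df2 = 27 for the 10 × 4 default design) with
  Bonferroni-corrected paired post-hocs; voxel-occupancy gesture spaces
  compared by Dice = 2|A∩B| / (|A|+|B|) across a 10–100 mm voxel sweep.
* **Synthetic study generator** — 10 participants × 8 sequences × 3
  cameras (1920×1080 @ 30 fps) + 100 fps MoCap, with harmonic-driven
  skeletal motion, pose-correlated occlusion and confidence, anatomical
  marker offsets, persistent MoCap marker loss, and depth-degraded
  monocular streams, all byte-reproducible from one seed.

Everything is tibble-first: streams, masks, error tables and test results
are tidy data frames that pipe into dplyr and ggplot2 (`autoplot()`,
`tidy()`, `glance()` methods included).

## Worked example

```r
library(hpeval)

cfg <- sim_config(n_participants = 3, n_sequences = 2, duration_s = 20,
                  margin_s = 2, seed = 7)
res <- run_validation_study(cfg)
res
#> <hpe_study> 3 participants x 2 sequences, 138008 error records
#> Overall mean error (mm) by method:
#>   mono_a     126.58
#>   mono_b     124.89
#>   tri_12      15.51
#>   tri_13      14.14
#> Dice at 50 mm voxels: 90.5%
```

Both stereo methods land ~15 mm from the MoCap reference — the residual is
dominated by the 10 mm anatomical marker offset and the 100→30 fps
resampling mismatch, neither of which a rigid alignment can remove — while
the monocular methods sit two orders of magnitude worse in depth. The
stereo-vs-mono post-hoc contrasts for, say, the right wrist:

```r
dplyr::filter(res$pairwise, group == "wrist_R",
              xor(grepl("^tri", method_a), grepl("^tri", method_b)))
#>   method_a method_b mean_diff_mm ci_low ci_high p_bonferroni direction
#> 1 mono_a   tri_12           109.   69.3    150.       0.0431 mono_a > tri_12
#> 2 mono_a   tri_13           111.   70.7    150.       0.0416 mono_a > tri_13
#> 3 mono_b   tri_12           108.   75.8    139.       0.0281 mono_b > tri_12
#> 4 mono_b   tri_13           109.   76.7    141.       0.0279 mono_b > tri_13
```

Each row is a paired t-test across participants with its 95% CI of the mean
difference and Bonferroni-corrected p (×6 pairs): every stereo method beats
every monocular method. `autoplot(res$errors)` draws the per-group error
box plots, `autoplot(res$dice_curve)` the Dice-vs-voxel-size curve, and
`res$breakdown` tabulates where each stereo variant's confidence drops
below threshold.

The same analysis runs as a file-based pipeline whose stages communicate
only via inspectable artifacts (study export → triangulation → alignment →
evaluation → report, each with a checksum manifest):

```r
pipeline_all(cfg, "my_study")   # or stage by stage: pipeline_simulate(), ...
```

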