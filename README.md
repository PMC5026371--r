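# pawtrackr

Automated video tracking of individual mouse forepaws during spontaneous
grooming, with trajectory analytics for bilateral coordination and
grooming/walking discrimination.

## The problem

Grooming in mice is a stereotyped innate behavior whose duration, stroke
speed and bilateral coordination report on basal-ganglia circuit function
and stress state. Scoring grooming by eye is slow and coarse, and generic
whole-animal trackers cannot follow individual forepaws: both paws share
the same natural color and change shape continuously. The practical
work-around is to label each forepaw with a distinct neon marker (neon
green, hue H = 120°, and neon magenta, H = 300°) and film the arena from
below. Those hues are far from the skin (H ≈ 10°) and from black or white
fur (achromatic, H = 0°), so each paw becomes a uniquely-hued blob that can
be followed frame by frame.

`pawtrackr` is a headless R implementation of this color-based tracking
engine plus the downstream trajectory analytics, aimed at behavioral
neuroscientists who want scriptable, reproducible forepaw kinematics from
video, and at method developers who need a tracker they can validate
against exact synthetic ground truth.

## The method

For every frame of a video the engine:

1. converts the frame from RGB to **HSV**; hue is the tracking signal
   because it is invariant to the lighting changes that move saturation
   and value;
2. builds binary **color masks** from user-set HSV ranges — one for the fur
   (body), one per paw — which doubles as background subtraction without a
   reference frame; masks can be dilated;
3. detects each mouse's **body** as the largest group of connected mask
   components merged by collision detection (expanded bounding boxes),
   giving a bounding box scaled to the mask extent, the mask center of
   mass, and the principal-axis orientation from second-order image
   moments;
4. tracks each paw by **hue-histogram back projection**: a reference hue
   histogram (max-normalized frequency counts, hue only) is taken once
   from a user ROI on frame 0, and every masked pixel of the current frame
   is replaced by its hue bin's weight, yielding a probability map;
5. runs **mean shift** from the previous window — iterative re-centering on
   the probability-weighted centroid — to find the densest cluster, with
   CAM-shift-style window scaling (side ∝ √mass). Detections are accepted
   only if the cluster mass reaches *min box size* and the centroid falls
   inside a **search region** 10 % larger than the body box (which also
   attributes paws to mice in multi-enclosure arenas);
6. on a lost paw (occlusion behind the body, out of view) grows the window
   progressively up to the body box until the paw reappears, and records
   the frame as lost rather than dropping it.

Trajectory analytics compute displacement/speed series, path length,
convex-hull covered area, occupancy maps, inter-paw distance, the bilateral
time lag (cross-correlation peak of the displacement series), Pearson
displacement correlation, grooming/walking bout classification by majority
vote over area, inter-paw distance and lag, and grooming-episode detection
with a sliding covered-area window.

A deterministic synthetic renderer (elliptical body, anti-aliased neon paw
disks, grooming and walking motion motifs, occlusions, brightness
modulation) provides scenes with exact ground truth; it is how the package
tests itself and a useful benchmark substrate in its own right.

## Worked example

Render a 10 s grooming bout (60 fps, 0.75 mm/px), track it, and summarize:

```r
library(pawtrackr)

motif    <- grooming_motif(600, seed = 8)
scene    <- synthetic_scene(list(motif), seed = 8)
rendered <- render_scene(scene)
cfg      <- scene_tracker_config(scene, rendered$truth)

records <- track_video(rendered$frames, cfg)
records
#> # A tibble: 600 × 11
#>   frame mouse body_x body_y orientation left_x left_y left_tracked ...
#> 1     0     0   120.   91.9        90.0   116.   62.5 TRUE
#> 2     1     0   120.   91.9        88.7   119.   64.0 TRUE

left  <- as_trajectory(records, mouse = 0, "left")
right <- as_trajectory(records, mouse = 0, "right")
metrics <- bout_metrics(left, right)
tidy(metrics)
#> # A tibble: 6 × 2
#>   metric              value
#> 1 covered_area_cm2    1.17
#> 2 path_length_mm   1456.
#> 3 mean_speed_mm_s   146.
#> 4 mean_interpaw_mm    6.08
#> 5 lag_s               0
#> 6 displacement_r      0.929
classify_bout(metrics)
#> [1] "GROOMING"
```

The paws stay within 1.17 cm², sit ~6 mm apart, move in synchrony (zero
lag, displacement correlation 0.93) — the kinematic signature of grooming;
a walking bout shows tens of cm², ~16 mm separation and a ~0.4 s gait lag.
`plot_trajectory(left)` draws the speed-coded path and
`plot_occupancy(left)` the visit-count raster. A thin CLI
(`inst/cli/pawtrackr.R`) exposes `track`, `analyze` and `synth` verbs over
the same functions.

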