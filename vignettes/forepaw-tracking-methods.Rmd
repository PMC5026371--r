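---
title: "Forepaw tracking by hue back projection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forepaw tracking by hue back projection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pawtrackr)
```

This vignette documents the model behind `pawtrackr`, the parameters that
matter, the reasoning behind the numerical and design choices that were
genuinely open, and what validation on synthetic scenes does and does not
demonstrate.

## The tracking model and its assumptions

The engine tracks color, not shape. Each forepaw is assumed to carry a
marker whose *hue* is unique in the scene: distinct from the other paw,
from the fur, and from everything in the background. Hue is the angular
coordinate of HSV space, and it is the right invariant for this problem:
dimming the lights, lifting a paw off the floor, or uneven illumination
across enclosures move *value* and *saturation* but leave hue essentially
fixed. Black and white fur are both achromatic (saturation 0) and share hue
0 by convention, which is why the same method works for dark- and
light-furred strains.

Per frame the pipeline is: HSV conversion → binary HSV-range masks (body,
left paw, right paw; dilation optional) → body detection → per-paw back
projection → mean shift → accept/lose decision. The key modeling
commitments are:

* **Masks are the background subtraction.** A pixel participates only if
  its H, S and V all fall within user-set bounds; no empty-arena reference
  frame is needed. Hue bounds may wrap around 0° (needed for magenta/red).
* **The body is a merged component set.** Tight fur masks fragment, so
  components whose bounding boxes — each expanded by `merge_gap` — touch are
  merged transitively ("collision detection"), and the largest merged group
  in each enclosure is the body. Centroid is the mask center of mass;
  orientation is the principal-axis angle from second-order central
  moments, reported in [0°, 180°) because a silhouette cannot distinguish
  head from tail.
* **The paw model is a hue histogram, frozen at frame 0.** Frequency
  counts of hue (only), max-normalized, from a user ROI drawn *inside* the
  colored paw on the first frame. Back projection replaces each masked
  pixel with its bin weight; everything else is 0.
* **Mean shift finds the cluster; the window follows the cluster.** The
  window is re-centered on the probability-weighted centroid of its
  contents until the shift is below `eps` or `max_iter` is reached. On
  acceptance the window is rescaled with side ∝ √mass (continuously
  adaptive, CAM-shift style); on loss it grows geometrically toward the
  body box so a reappearing paw is re-acquired quickly.
* **Attribution is spatial.** A detection counts only if its centroid lies
  in the search region — the body box enlarged by `expansion` — which both
  tolerates stretched forelimbs and prevents claiming a neighbour mouse's
  paw in divided arenas. Multi-enclosure arenas use one set of HSV limits
  for all enclosures.

Losses are first-class: a lost frame keeps its output row with empty paw
coordinates and a 0 flag, so record count always equals frame count and
drop statistics are computable downstream.

## Parameters

| parameter | units | default | notes |
|---|---|---|---|
| HSV limits (×3 masks) | deg / fraction | user-set | the main accuracy lever; hue bounds may wrap 0° |
| `dilation` | px | 0 | square element, side 2r+1 |
| `body_min_area` | px | 50 | rejects specks before merging |
| `merge_gap` | px | 5 | collision-detection box expansion |
| `min_box_size` | probability mass | 25 | cluster mass below this = loss; applied after mean shift |
| `expansion` | fraction | 0.10 | search region 10 % larger than the body box |
| `n_bins` | bins | 36 | 10° hue bins |
| `max_iter`, `eps` | — / px | 10, 1 | mean-shift stopping rule (window-center shift) |
| `window_scale` | — | 2 | side = scale·√mass |
| `min_window_side` | px | 4 | lower clamp on the adaptive window |
| `loss_growth_rate` | fraction/frame | 0.10 | geometric growth toward the body box while lost |
| `pixel_size_mm` | mm/px | 0.21 | set by the user's optics |
| `fps` | 1/s | 60 | slow-motion acquisition |

Choices that were open and how they were fixed:

* **Hue scale.** Degrees in [0, 360) are the public contract everywhere
  (the marker hues are quoted as 120 and 300); any half-range internal
  encoding of other imaging stacks is deliberately not exposed.
* **"10 % larger".** Read as *linear* dimensions ×1.10 (the simpler, more
  permissive contract), exposed as `expansion`.
* **Histogram binning and normalization.** 36 bins of 10° and
  max-normalization, the classic back-projection convention; the bin width
  comfortably separates the 120°/300° markers from fur and skin hues.
* **Window scaling law.** "Bigger cluster, bigger window" is made concrete
  as side = 2·√mass, clamped to [`min_window_side`, body box]. The square
  root makes window *area* proportional to cluster mass, and the absolute
  law has no hidden reference state: equal mass always gives an equal-sized
  window.
* **`min_box_size` semantics.** Compared against summed probability mass
  (a weighted pixel count) of the cluster *after* mean shift, so the
  threshold and the accepted cluster refer to the same window.
* **Re-seeding.** If the previous window contains zero probability mass
  (long occlusion while the mouse moved), the window is re-seeded at the
  highest-mass cluster inside the search region; ties break toward smaller
  y, then smaller x, keeping the tracker fully deterministic.
* **Divider geometry.** Dividers are classified vertical/horizontal after
  rotation correction; enclosure ids run row-major from the top-left and
  boundary points go to the lower id (deterministic ties). The fourth
  arena corner is completed as a parallelogram from the three given.

## Trajectory analytics

Displacement series use consecutive tracked-tracked frame pairs only;
pairs spanning a lost frame are excluded and counted. Covered area is the
convex hull of the tracked points (the occupancy map is the complementary
raster view). The bilateral time lag is the peak of the normalized
cross-correlation between the *mean-subtracted displacement vectors* (dx
and dy jointly) of the two paws over a bounded window (default ±1 s).
Vector displacements — rather than unsigned step lengths — are used because
unsigned series are blind to anti-phase motion: a perfect left-right gait
alternation produces *identical* step-length series and a spurious zero
lag, whereas the vector cross-correlation recovers the half-period offset.
The Pearson displacement correlation, by contrast, is computed on step
magnitudes, which is how bilateral stroke coordination is conventionally
summarized.

Bout classification is a majority vote of three criteria (covered area <
10 cm², inter-paw distance < 8 mm, |lag| < 0.2 s votes grooming; strictly
above votes walking; exactly at threshold abstains). The defaults sit
midway between typical grooming and walking group values; they are
calibration constants to be adjusted per rig, not biological claims.

Episode detection slides a 1 s window over both paws' points, computes the
joint hull area per frame, and marks frames below `area_thresh_cm2` with
both paws tracked as candidates; runs shorter than 2 s are dropped, then
runs separated by less than 0.5 s are merged. The per-window threshold
defaults to 2.5 cm² — necessarily smaller than the whole-bout 10 cm²
classification threshold, because a 1 s window sees only a fraction of a
walking traversal. 2.5 cm² is the geometric midpoint between the largest
1 s grooming window (~1.6 cm²) and the smallest 1 s walking window
(~3.1 cm²) produced by the generator's study conditions.

## What the synthetic scenes emulate — and what they do not

The generator renders, deterministically for a given seed: a white (or
dark) arena floor, an elliptical fur-colored body, and two anti-aliased
neon paw disks (hues 120° and 300°) at sub-pixel positions, with exact
ground truth. Scene defaults are chosen as a desk-scale version of a
typical rig: 240×160 px at 0.75 mm/px (one enclosure seen from below),
60 fps, body semi-axes 40×20 px (~60×30 mm mouse), paw radius 5 px
(~7.5 mm), 600-frame (10 s) bouts.

* The **grooming motif** holds the body still and drives both paws through
  the same small Lissajous stroke pattern (amplitudes 10×6 px ≈ 7.5×4.5 mm,
  3 Hz, paw separation 7 px ≈ 5 mm) plus small independent jitter — giving
  confined area (~1.2 cm²), high displacement correlation (~0.95) and zero
  lag.
* The **walking motif** translates the body (40 px/s ≈ 30 mm/s, ping-pong
  across the enclosure with a slow lateral sway) with paws striding along
  the movement axis at 1.25 Hz; the right stride is the left delayed by
  half a period (24 frames = 0.4 s) — the gait alternation that produces
  walking's bilateral lag and a much larger covered area (~17 cm²).
* **Occlusions** simply do not draw a paw for the configured frames,
  mimicking a paw disappearing behind the head/body; **brightness
  profiles** multiply the V channel of the whole frame with hue untouched,
  mimicking illumination changes.

These scenes validate the geometry and logic of the tracker: mask
correctness, localization to sub-pixel RMS, loss flagging and recovery,
hue invariance, and the qualitative grooming/walking ordering of all three
discriminating metrics. They deliberately do *not* contain: articulated or
deforming paws, fur texture, specular reflections from the arena floor,
motion blur, sensor noise or compression artifacts, paw-over-paw depth
ordering beyond simple painter's order, or imperfectly constrained HSV
limits. Passing on synthetic scenes therefore demonstrates algorithmic
correctness under the stated color assumptions, not performance on any
particular laboratory's videos — real deployments still need the HSV
limits, `min_box_size` and the classification thresholds tuned on their
own footage.

## Numerical notes and degenerate inputs

* Windows are kept inside the frame at every mean-shift step; integer
  pixel windows are half-open [x, x+w)×[y, y+h) in 0-based coordinates.
* A zero-mass window leaves mean shift immediately (mass 0, centroid NA);
  the caller treats it as a loss.
* Achromatic pixels (s = 0) carry hue 0; a hue interval with lo > hi wraps
  through 0°.
* Convex hulls of fewer than 3 non-collinear points have area 0;
  zero-variance displacement series yield lag 0 with a degenerate flag and
  an error for the Pearson correlation.
* Coordinates are written to output files with 2 decimals; lost paws write
  empty fields plus a 0/1 tracked flag, and all four output formats
  (CSV/TXT/XML/HTML) round-trip the same schema.
* Connected components are 8-connected; the labelling merges
  diagonally-adjacent 4-connected labels with a union-find pass.

## Problem sizes used in the test suite

The suite renders and tracks 600-frame scenes (240×160 px) for the
end-to-end checks, 360 frames for occlusion recovery, 20 motif bouts of
600 frames for discrimination, and a 3000-frame composite for episode
detection; oracle-equivalence checks use 100 random 50×50 images and 50
seeded unimodal maps. These sizes give sub-2-minute full-suite runs while
keeping every check statistically unambiguous.

## Known limitations

* Color is the only cue: two markers of similar hue, colored bedding, or
  strong hue-shifting illumination defeat the method by design.
* Video containers are not decoded; frames come from an image sequence or
  memory.
* Orientation is axial (no head/tail disambiguation).
* The episode-boundary estimate inherits half-window (~0.5 s) edge bias,
  consistent with duration estimates slightly below human scoring.
* One body per enclosure is assumed; two mice in one enclosure merge into
  a single largest group.
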