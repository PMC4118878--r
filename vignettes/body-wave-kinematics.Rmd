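---
title: "Quantifying body-wave swimming kinematics of adult zebrafish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying body-wave swimming kinematics of adult zebrafish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zebrakin)
```

## The measurement problem

Commercial fish-tracking systems reduce the animal to a point and report
distance and velocity, which misses how the body itself moves. For muscle
phenotypes -- the motivating application is transgenic zebrafish carrying
human *CLCN1* mutations that cause myotonia congenita, a chloride-channel
disorder with delayed muscle relaxation and stiffness -- the informative
signal is the *body wave*: how strongly the fish bends while it swims.
`zebrakin` quantifies that signal from top-view high-speed video (nominally
250 frames/s, 480x640 px, one adult fish per tank) with three per-cycle
measurements:

* **Body curvature** `K(i)`: the fish midline is modelled by 20 control
  points, uniformly spaced in arc length from head to tail. At each
  interior point, curvature is the unsigned angular change (degrees)
  between the directions of the two adjacent midline segments. Larger
  values mean stronger bending. The two endpoint locations copy their
  nearest interior neighbour so every posture yields a length-20 vector.
* **Tail offset** `T/L`: the distance from the tail point to the
  silhouette centroid, divided by body length. A straight fish scores
  about 0.5; bending moves the tail toward the centroid, so smaller
  values mean stronger bending. Because it is a ratio of body-frame
  distances it does not depend on where or in which direction the fish
  swims.
* **Travel distance**: the path length of the centroid trajectory over
  one body-waving cycle (a config switch selects net displacement
  instead).

The unit of analysis is the **body-waving cycle**: a video segment in
which the fish goes from straight to bent and back to straight. Cycles
can be supplied as manual annotations (the reference workflow) or
detected automatically from maxima of the smoothed tail-offset series.

## Pipeline

1. **Background model.** The background is the per-pixel temporal median
   of all frames; for an even number of frames the lower median is used so
   the model keeps an actually observed intensity and integer type. The
   model is permutation-invariant in the frame order. A median background
   assumes every pixel shows the tank in more than half the frames --
   true for recordings in which the fish swims around, and a condition the
   synthetic generator enforces explicitly (see below).
2. **Segmentation.** Each frame is subtracted from the background; the
   absolute difference is thresholded (default 25/255 -- the recording
   protocol does not fix a value, so it is config-exposed), cleaned with
   one 3x3 binary opening and closing, and labelled with 8-connectivity
   so thin diagonal tail segments stay connected. The largest component
   of at least `min_area` pixels is the fish; ties break to the earliest
   component in row-major order, deterministically.
3. **Posture.** The mask is thinned to a topology-preserving skeleton
   (Zhang-Suen). The centerline is the longest end-to-end path through
   the 8-connected skeleton pixel graph with Euclidean step costs, which
   drops fin spurs without a pruning parameter. The path is smoothed with
   a 5-point moving average (staircase suppression) and then *extended*
   from each endpoint to the mask boundary, marching in 1 px steps and
   re-centering every step on the midpoint of the local mask
   cross-section. Thinning retracts a skeleton by roughly the local
   half-width at each end; without the extension the tail tip -- where
   curvature peaks -- is systematically lost. The extension budget per
   end is the distance-transform value at the endpoint plus 3 px, so the
   march cannot round the end cap. Head and tail are disambiguated by
   local body width (mean distance-transform value over the 10% of arc
   length nearest each endpoint; adult zebrafish heads are wider than the
   caudal peduncle), by temporal consistency on subsequent frames, and by
   a deterministic smaller-x fallback for pathological symmetric shapes.
   Finally the centerline is resampled to 20 arc-length-uniform control
   points by linear interpolation.
4. **Cycle profiles.** Every cycle is normalized to 30 frames: longer
   spans are subsampled uniformly (round-half-away-from-zero indexing, so
   the selected frames are then not contiguous), shorter spans are
   extended with contiguous frames split evenly before/after (extra frame
   after on an odd deficit, slack pushed to the available side at video
   bounds). Per-frame curvature vectors form the 20x30 matrix `C`, which
   is smoothed along each column (spatial) and each row (temporal) with a
   4th-order Butterworth filter applied forward-backward (zero phase,
   unity DC gain); the tail-offset series is smoothed the same way.
5. **Metrics and statistics.** From each cycle: the largest smoothed
   curvature, the smallest smoothed tail offset, and the travel distance
   over the cycle span (runs of at most 2 undetected frames are bridged
   by linear interpolation; longer gaps reject the cycle). Profiles and
   metrics are averaged over all cycles of all fish within a group;
   group means are divided by the wild-type mean (wild-type = 1 by
   construction) and each group is compared with wild-type by a
   two-sided pooled-variance Student t test at alpha = 0.05, one metric
   at a time with no multiple-testing correction -- replicating the
   reference analysis; Welch and per-fish averaging variants are config
   switches that do not claim to match it.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `threshold` | 25 | 8-bit intensity | dark fish on a light tank; config-exposed because the protocol states none |
| `min_area` | 100 | px | well below an adult silhouette (~2000 px), above speckle |
| `spatial_cutoff` | 0.20 | cycles/sample | curvature signal along the body ends by ~0.15; inspected via `cmd_inspect_spectrum()` |
| `temporal_cutoff` | 0.15 | cycles/sample | passes the cycle fundamental (~0.03) and the peak's harmonics; a 0.10 cutoff measurably clips genuine peak sharpness |
| `cycle_length` | 30 | frames | the reference cycle normalization |
| `n_points` | 20 | points | the reference posture model |
| `alpha` | 0.05 | -- | the reference significance level |
| `auto_prominence` | 0.005 | T/L | ~1/4 of a moderate swimmer's straight-to-bent tail-offset excursion (~0.018), ~5x the post-smoothing noise ripple |

The cutoffs follow the method's own calibration procedure -- visual
inspection of the Fourier magnitude of the curvature and tail-offset
series, available as `cmd_inspect_spectrum()` -- performed once on
synthetic cycles and fixed.

## The synthetic swimmer

Real recordings of this protocol are not redistributable, so validation
uses a parametric swimmer with exact ground truth. Its midline is a
traveling wave in the body frame,

```
y(u, t) = stiffness * amplitude * (u / L) * sin(2 * pi * (u / (lambda * L) - f * t)),
```

with `u` the body-axis coordinate from head (0) to tail (`L`). The
amplitude envelope grows linearly toward the tail (carangiform-like,
producing the head-to-tail curvature gradient seen in real profiles); the
body is rigidly transformed by heading and forward speed, head leading,
and rendered as a union of disks along the midline with a snout- and
tail-tapered width profile, darker than the background, with optional
seeded Gaussian noise. Ground truth per frame -- 20 arc-uniform midline
points, analytic curvature (converted to degrees per control-point step,
with the same endpoint-padding convention as the measurement so the two
are commensurable), width-weighted strip centroid, tail offset -- comes
from the same curve that is rendered.

Defaults are chosen to be realistic for the emulated recording geometry
and fixed: body length 150 px (an adult spanning about a quarter of the
640 px field of view), tail-beat half-amplitude 19 px (~0.13 body
lengths), wavelength 0.95 body lengths, beat frequency 4 Hz -- one
straight-bent-straight tail-offset cycle is then 1/(2f) = 31.25 frames at
250 frames/s, matching the ~30-frame cycles of the reference analysis --
and forward speed 300 px/s (~2 body lengths/s cruising). The amplitude
keeps midline slopes small at the curvature peaks, so ground-truth peak
curvature scales nearly linearly with the stiffness factor (ratio 2.0
within a few percent for stiffness 0.5). Because tail offset is unsigned,
a "cycle" is one period of the tail-offset signal, i.e. half a left/right
beat period; the generator places cycle boundaries analytically at tail
zero crossings.

Two conditions are enforced by construction rather than hoped for:

* **Median validity.** Every generated video is long enough for the fish
  to traverse at least 2.75 body lengths, bounding per-pixel fish
  occupancy near 40% so the temporal median really is background. A short
  clip of a slow fish violates this silently -- worth remembering with
  real recordings too.
* **Stiff phenotype.** The stiffness factor scales both the wave
  amplitude and the forward speed. Undulation is what propels the fish,
  so a stiffer (lower-amplitude) swimmer is also slower; modelling
  stiffness as amplitude-only would leave travel distance unchanged,
  which contradicts the phenotype the metric set is designed to detect.

What the generator does *not* emulate: hydrodynamics (speed is imposed,
not emergent), fins, shadows and refraction, illumination drift,
occlusions, multi-fish scenes, and 3-D body roll. Passing the synthetic
validation therefore shows the *measurement chain* is correct at
realistic scale and noise, not that segmentation will survive arbitrary
tank conditions.

## Numerical choices and degenerate inputs

* Even-length medians take the lower median, preserving integer rasters.
* Zero-phase filtering uses odd-reflection end padding and steady-state
  initial conditions; constant series pass through exactly. Series
  shorter than the padding reduce the pad length rather than fail.
* Uniform cycle subsampling rounds half away from zero and resolves
  duplicate indices by shifting forward, deterministically.
* A mask with elongation (major/minor axis ratio) below 1.5 fails posture
  extraction for that frame -- the medial-axis assumption is unreliable --
  and the cycle is rejected with a reason rather than contaminating the
  profile. Ring-topology skeletons (no endpoints) are likewise an error.
* Ties in the largest-component choice, in head/tail fallback, and in
  peak selection are all broken deterministically, so identical inputs
  and seeds give byte-identical outputs.
* Zero-variance group comparisons: equal means give t = 0, p = 1;
  unequal means report p at the smallest positive double and are flagged
  significant.

## Validation summary

The test suite builds every expected value from analytic oracles (dense
finite-difference curvature, closed-form geometry, strip centroids on
sub-pixel grids) or from the generator's ground truth, at these problem
sizes: single-fish checks on 3-cycle videos (~345 frames at 480x640);
recovery on a zero-noise 2-fish x 3-cycle cohort; the stiffness contrast
on 2 fish x 5 cycles per group (10 cycles per group, seeded); t-test
calibration on 10,000 null replicates. On the zero-noise cohort the
pipeline recovers ground-truth peak curvature within a few percent
(tolerance 15%), minimum tail offset within well under 0.01 absolute
(tolerance 0.03), and travel distance within ~1% of speed x duration
(tolerance 10%). `scripts/acceptance.R` recomputes all of these from
scratch.

## Known limitations

* Peak curvature is the hardest quantity: it lives in the last two
  control points of a thin, curling tail, at the rasterization limit.
  The tip extension recovers most of it; residual error is a few percent
  low on average and varies with beat phase.
* The skeleton-based midline assumes a single, simply connected, fish-
  shaped silhouette; self-occluding postures (fish curled onto itself)
  will be rejected by the elongation guard or produce a shortened
  centerline.
* Averaging pools cycles across fish, as in the reference analysis;
  fish-level clustering is ignored there and here (a per-fish averaging
  switch exists but makes no claims of equivalence).
* Group comparisons are per-metric Student t tests without multiple-
  testing correction, again replicating the reference analysis; the
  comparison CSV notes this.
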