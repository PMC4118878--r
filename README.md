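# zebrakin

Body-wave swimming kinematics of adult zebrafish from top-view high-speed
video (nominally 250 frames/s, 480x640 px, one fish per tank).

Point-tracking systems report where a fish goes; they cannot say how the
body moves while it swims. For muscle phenotypes -- the motivating case is
transgenic zebrafish expressing human *CLCN1* mutations that cause
myotonia congenita, i.e. muscle stiffness -- the signal of interest is the
body wave. `zebrakin` segments the fish against a per-pixel temporal
median background, models its posture as 20 midline control points
uniformly spaced in arc length from head to tail, and quantifies each
body-waving cycle (straight - bent - straight, normalized to 30 frames)
with three measurements:

* **body curvature** `K(i)` -- the unsigned angular change, in degrees,
  between the directions of the two midline segments meeting at control
  point `i` (larger = more bending);
* **tail offset** `T/L` -- tail-to-centroid distance over body length
  (about 0.5 when straight; smaller = more bending; invariant to the swim
  trajectory);
* **travel distance** -- path length of the body-centroid trajectory over
  the cycle.

Per-cycle curvature matrices (20 body locations x 30 frames) and
tail-offset series are low-pass smoothed (zero-phase 4th-order
Butterworth), averaged within genotype groups into spatio-temporal
profiles, normalized to the wild-type mean, and compared against
wild-type with two-sided pooled-variance Student t tests at p < 0.05.

A parametric undulatory-swimmer simulator with analytic ground truth
(midline, curvature, centroid, tail offset per frame) makes the whole
chain testable without recordings; a `stiffness` factor scales wave
amplitude and forward speed to emulate a stiff-muscle phenotype.

## Worked example

Simulate one wild-type-like swimmer (three annotated body-waving cycles)
and analyze it:

```r
library(zebrakin)

sw  <- generate_swimmer(swimmer_params(seed = 11), n_cycles = 3,
                        fish_id = "demo")
res <- analyze_video(sw$video, sw$cycles, run_config(),
                     fish_id = "demo", group = "wildtype")
res$cycles
```

```
  fish_id    group cycle_index max_curvature_deg min_tail_offset travel_distance_px
1    demo wildtype           0          15.34664       0.4988218           38.86317
2    demo wildtype           1          15.08359       0.4985760           37.53568
3    demo wildtype           2          16.78101       0.4989597           37.38586
```

Each row is one body-waving cycle: this fish bends up to ~15-17 degrees
per control-point step at the peak of a beat, its tail approaches the
body centroid to ~0.50 body lengths when maximally bent, and the centroid
covers ~38 px per cycle. The analytic ground truth for the same cycles
has peak curvature ~17.2 degrees, minimum tail offset ~0.51, and travel
speed x duration ~38 px, so the video pipeline recovers the kinematics to
within a few percent.

A two-group experiment (wild-type vs a stiffness-0.5 cohort, 2 fish and 5
cycles per group) and the group statistics:

```r
coh <- generate_cohort(n_fish = 2, cycles_per_fish = 5,
                       normal_params = swimmer_params(),
                       stiff_params  = swimmer_params(stiffness = 0.5),
                       seed = 42, render = FALSE)
res <- analyze_cohort(cohort_video_loader(coh), coh$annotations,
                      coh$manifest, run_config(), wildtype = "wildtype")
res$summary
```

```
     group          metric  n     mean         sd relative_mean       t          p significant
1 wildtype   max_curvature 10 16.09521 1.14867749       1.00000      NA         NA          NA
2 wildtype min_tail_offset 10  0.49866 0.00031730       1.00000      NA         NA          NA
3 wildtype travel_distance 10 38.05092 0.70309733       1.00000      NA         NA          NA
4    stiff   max_curvature 10  8.49902 0.61254560       0.52805 -18.452 3.8501e-13        TRUE
5    stiff min_tail_offset 10  0.52484 0.00015172       1.05251 235.448 7.4201e-33        TRUE
6    stiff travel_distance 10 19.04459 0.36274616       0.50050 -75.969 5.0435e-24        TRUE
```

The stiff cohort bends less (relative max curvature < 1), keeps its tail
farther from the centroid (relative min tail offset > 1), and travels a
shorter distance per cycle -- the direction expected of a stiff-muscle
phenotype -- and every contrast is significant under the Student t test.

Batch use from a shell (`analyze`, `simulate`, `inspect-spectrum`):

```sh
Rscript inst/scripts/zebrakin.R simulate --out sim --n-fish 2 --cycles 3 --seed 1
Rscript inst/scripts/zebrakin.R analyze --videos sim --manifest sim/manifest.csv \
    --annotations sim/annotations.csv --out results
```

`analyze` writes per-cycle metrics, group-comparison and mean-profile
CSVs, profile heatmaps, and a JSON run manifest with the config snapshot
and per-stage counts.

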