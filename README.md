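# ShoalTrack

Detection and tracking of many visually similar fish swimming in shallow
water, from top-view grayscale video, under frequent mutual occlusion — the
measurement problem at the bottom of quantitative collective-behavior work:
before schooling can be analyzed, every individual's trajectory has to be
extracted from footage in which fish constantly cross, touch and hide each
other.

ShoalTrack implements a three-stage pipeline:

1. **Head detection.** The fish head is rigid, dark and blob-like, so each
   frame is searched for scale-space determinant-of-Hessian (DoH) extrema,
   $\mathrm{DoH}(x,y,s) = (s^2L_{xx})(s^2L_{yy}) - (s^2L_{xy})^2$,
   restricted to dark-blob polarity and refined to sub-pixel/sub-scale
   accuracy. Each extremum's Hessian eigenstructure yields a head ellipse
   (center, length, width, orientation); candidates are filtered by a width
   band ($w \in [16, 24]$ px by default), a local-contrast threshold
   ($k = 0.03$) and an angle constraint (30°) that removes duplicate
   detections inside one Otsu-segmented fish region while keeping genuinely
   crossing fish.
2. **Tracking.** A constant-velocity Kalman filter per track gates the
   detections; a quarter-circle *compensation window* (radius = head
   length, ±45° about the heading) takes over when prediction fails, e.g.
   at burst starts. Association is decided by *cascade feature matching* on
   an active-contour head region: width (≤ 5 px), aligned symmetric
   difference area (≤ 50 px²), gray-histogram distance (≤ 0.15), with
   greedy one-to-one conflict resolution.
3. **Trajectory linking.** Tracks missing detections for $T_1 = 10$
   consecutive frames close as incomplete fragments; fragment pairs whose
   gap is under $T_2 = 30$ frames and whose endpoints are within
   $D = 80$ px are re-joined when their endpoint regions pass the same
   feature cascade, with linear interpolation across the gap.

The package also ships a seeded synthetic fish-school video generator with
per-frame ground truth (head centers, headings, occlusion flags) and the
standard evaluation metrics: precision, recall, occlusion ratio (OR),
occlusion detection ratio (ODR), trajectory completeness factor (TCF),
trajectory fragmentation factor (TFF) and identity-switch counts.

## Worked example

Simulate a small school, run the full pipeline, and evaluate against the
generator's ground truth:

```r
library(ShoalTrack)

scene  <- simulateSchool(nFish = 5, nFrames = 60,
                         motion = motionParams(arena = 400, separation = 90),
                         seed = 7)
frames <- renderFrames(scene)

res <- runPipeline(frames)
res$counts
#> $frames
#> [1] 60
#> $detections
#> [1] 302
#> $rawTracks
#> [1] 11
#> $trajectories
#> [1] 5

tally <- detectionTally(res$detections, sceneTruth(scene))
detectionMetrics(tally)
#> $precision
#> [1] 0.9900662
#> $recall
#> [1] 0.9966667

ev <- evaluateTracking(res$trajectories,
                       sceneTruth(scene)[, c("frame", "id", "x", "y")])
c(tcf = ev$tcf, tff = ev$tff, switches = ev$idSwitches)
#>      tcf      tff switches
#>        1        1        0
```

Five fish produce 302 detections over 60 frames (three false positives
and one miss at brief crossings, hence precision 0.990 and recall 0.997);
the tracker's 11 raw tracks collapse to exactly 5 trajectories after
linking and pruning, fully covering the true trajectories (TCF = 1) with
no fragmentation (TFF = 1) and no identity switches.

A command-line front end is installed with the package
(`exec/fishtrack`): `fishtrack simulate | detect | track | link | eval |
run`, each a thin wrapper over the functions above, reading and writing
the CSV formats documented in `?writeDetections` and
`?writeTrajectories`.

## Documentation

The methods vignette (`vignettes/shoaltrack-methods.Rmd`) describes the
detection, tracking, linking and evaluation models in detail, the meaning
and defaults of every tunable parameter, what the synthetic generator does
and does not emulate, and the package's numerical choices.
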