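---
title: "Detecting and tracking schooling fish with ShoalTrack: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and tracking schooling fish with ShoalTrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

ShoalTrack reconstructs the trajectories of many visually similar fish
swimming in shallow water, filmed from above, under frequent mutual
occlusion. This vignette explains the models behind each stage, the
parameters that matter, what the synthetic scene generator does and does not
emulate, and the numerical choices made where the design was genuinely open.

## The imaging model

A top-view shallow-water scene is a light background (tank bottom) with
dark fish. A fish consists of a **rigid elliptical head** — whose shape and
gray distribution barely change as the fish swims — and a deformable
posterior that swings for propulsion. The head is darker than both the
background and the body midline, wider than the tail, and partially
elliptical: it behaves like a dark blob of predictable size. All of
ShoalTrack's stages exploit exactly this structure.

Coordinates are 0-based with `x` along columns, `y` along rows (y grows
downward), pixel centers at integers; angles are degrees counter-clockwise
from +x, reduced modulo 180 for orientations. Frames are numbered from 1 in
all tables.

## Head detection

**Scale-space blob detection.** For scale $s$, the frame is convolved with
Gaussian second-derivative kernels giving $L_{xx}, L_{yy}, L_{xy}$, and the
determinant of the scale-normalized Hessian
$$\mathrm{DoH}(x, y, s) = (s^2 L_{xx})(s^2 L_{yy}) - (s^2 L_{xy})^2$$
is evaluated over a geometric scale grid $s_i = s_{\min} \cdot 1.26^i$
spanning $[w_{\min}/4,\; w_{\max}/1.5]$. For the default width band 16-24 px
that grid is 7 scales in $[4, 16]$ px; a dark blob of radius $r$ peaks near
$s = r/\sqrt2$, so the grid brackets every admissible head. Because the
determinant is sign-ambiguous, candidates are restricted to **dark-blob
polarity**: positive determinant *and* positive Laplacian (an intensity
minimum). The negated, polarity-masked response is searched for strict
minima over the full 26-neighborhood in $(x, y, s)$; each discrete minimum
is refined by a quadratic fit to its $3{\times}3{\times}3$ lattice
neighborhood, with offsets clamped to half a grid step (the scale offset is
applied in log-scale). Extrema closer than $2s$ to the border are discarded;
convolution uses reflective padding.

**Ellipse fitting.** The $2{\times}2$ Hessian at the refined extremum is
eigen-decomposed; with $|\lambda_1| \ge |\lambda_2|$ and curvature ratio
$r = |\lambda_1| / |\lambda_2|$, the orientation is the eigenvector of the
*smaller*-magnitude eigenvalue (curvature is weakest along the elongation)
and the axes are
$$\mathrm{length} = \kappa\, 2\sqrt2\, s\, r^{1/4}, \qquad
  \mathrm{width} = \kappa\, 2\sqrt2\, s\, r^{-1/4},$$
which preserve the geometric-mean blob radius $\sqrt2 s$ — the radius a
Gaussian blob of standard deviation $s$ is detected at — while letting the
curvature anisotropy set the aspect. The calibration factor $\kappa = 0.959$
was measured once on isolated rendered heads across the 16-24 px width band
(the raw Gaussian-blob relation overestimates the width of a solid,
anti-aliased head with an attached body by 4.2% ± 0.6%); with it the width
estimate is unbiased, so the width band constraint refers to nominal head
widths rather than to an estimator-inflated scale. Without this calibration,
fish near the upper band edge are systematically rejected by their own
configured band.

**Candidate constraints.** Three filters remove non-head candidates:

* *Width*: the fitted minor axis must lie in $[w_{\min}, w_{\max}]$
  (default 16-24 px). This removes small noise blobs and tail segments.
* *Contrast*: the mean gray of the elliptical annulus between 1x and 2x the
  fitted axes minus the mean gray inside, normalized by 255, must be at
  least $k$ (default 0.03). Tail candidates sit inside the body's dark
  surround and fail this.
* *Angle*: within one Otsu-segmented region, candidates closer than 30
  degrees in orientation are duplicate detections of the same head; only
  the maximum-contrast one is kept. Two *crossing* fish meet at a large
  angle — usually above 30 degrees — so genuinely occluding pairs survive.

Segmentation uses Otsu's threshold (exhaustive maximization of the
between-class variance over the 256 gray levels, smallest maximizer on
ties — a deterministic tie-break) with foreground = dark pixels, 8-connected
component labeling, and a minimum region area of $\pi w_{\min}^2 / 8$ px²
(half a minimal head), which deletes speckle without dropping a lone head.

Finally, each surviving center is repositioned at the **darkness centroid**
inside its fitted ellipse (centroid of background-minus-pixel gray deficit).
The scale-space extremum sits a little ahead of the head center when the
body merges into the rear of the head blob; the centroid correction reduces
the localization error on rendered scenes from about 1.5 px to under 1 px.

## Tracking

**Motion model.** Each track carries a constant-velocity Kalman filter with
state $(x, y, v_x, v_y)$, $F$ advancing position by velocity, $H$ observing
position, $Q = q\,\mathrm{diag}(\tfrac14, \tfrac14, 1, 1)$ with
$q = 1$ px², $R = I$ px², $P_0 = 10 I$ — standard near-constant-velocity
defaults at 30 frames/s. Candidates for association are detections within
the gate $3\sqrt{\mathrm{tr}\,P_{\mathrm{pos}}} + \bar\ell$ of the
prediction ($\bar\ell$ = mean head length). When the gate is empty — burst
starts, sharp turns — the **compensation window** takes over: a quarter
circle centered on the last effective detection, radius equal to the head
ellipse's major axis, spanning ±45° about the heading, reflecting the
observation that per-frame heading changes almost always stay within ±45°.

**Matching region.** Appearance is compared not on the raw ellipse but on a
contour-derived region: a two-phase piecewise-constant active contour
(Chan-Vese-type, without the length penalty's full machinery — an
8-neighbor majority smoothing term with weight 0.1, iterated to a mask
fixed point with a cap of 100 iterations) is grown from the ellipse mask;
the farthest contour point within ±15° of the body direction is the *outer
endpoint*; the *alignment line* is the directed body axis through the
center (the center-to-outer direction lies in the same ±15° cone but
wobbles with the tail bend, so the rigid axis anchors the alignment); the
*cutting line* through the center perpendicular to it bounds the
**head-side matching region**. The contour mask is clipped to a disc of
radius 1.25x the head length around the center — the head is the rigid,
stable part, and without the clip a crossing neighbor merged into the same
dark region inflates the features exactly at the frames where matching
matters most. Features: the cutting-line width, the region area, and its
gray histogram.

**Cascade matching.** Two regions match if they pass, in order: width
difference ≤ 5 px; area of the symmetric difference of the masks after
rigidly aligning the alignment lines ≤ 50 px² (the moved mask is resampled
bilinearly so rasterization jitter stays sub-pixel); histogram distance
(1 − intersection) ≤ 0.15. Failing any stage aborts the cascade. The match
score is the mean of the three threshold-normalized statistics, so a region
matched against itself scores exactly 0. Histograms use **32 bins of 8 gray
levels**: with matching regions of only a few hundred pixels, 256-bin
histograms are so sparse that pixel noise alone pushes the intersection
distance above threshold for the *same* fish (≈0.17 measured), while 32
bins give ≈0.07 same-fish vs ≈0.36 different-fish distances — still
individually discriminative through head/body intensity differences.
Conflicts (several tracks passing on one detection) are resolved globally,
greedily by ascending score, one detection per track per frame.

**Template management.** The matching region cached as a track's
appearance template is only replaced when the new region's area lies
within 30% of the track's running area level (an exponential moving
average that itself always updates); regions extracted while two fish
merge or separate describe the merged blob, and refusing them keeps the
template clean exactly at the frames where matching decides identities.
Each track also snapshots a stabilized start-side template at its fifth
associated frame — tracks born from a fish re-emerging out of an occlusion
start with a contaminated region, and fragment linking matches against the
stabilized snapshot instead.

**Lifecycle.** An associated frame updates the filter and marks the state
effective. A missed frame associates a virtual observation: the state
coasts on the prediction, marked ineffective. At $T_1 = 10$ consecutive
misses the track is closed as *incomplete*, its trailing virtual states are
dropped, and the time/position of the last effective state become its **end
tag**. Unmatched detections spawn new tracks whose birth time/position is
the **start tag**.

## Trajectory linking

Fragment pairs (end-tagged A, start-tagged B) are linkable when
$0 < st_B - et_A < T_2$ (strict, $T_2 = 30$ frames) and
$\lVert ep_A - sp_B \rVert < D$ (strict, $D = 80$ px), and when the stored
endpoint matching regions pass the same cascade. Passing pairs link
greedily by ascending score, one-to-one per side, iterating until no link
forms; incomplete fragments stay eligible for the whole video (an occluded
fish may reappear much later, while the $T_2$ bound still applies to the
gap itself). Linked gaps are filled by linear interpolation of position,
flagged `interpolated` in the output. After linking, tracks shorter than 5
frames are removed as spurious. With $T_1 = 10$, note that a detection
dropout shorter than $T_1$ never fragments a track at all — the filter
coasts through it — so linking only ever sees gaps of at least $T_1$
frames.

## Evaluation metrics

Detection: a detection is a true positive iff it lies within half the mean
ground-truth head length of an unmatched truth head (greedy one-to-one by
distance); precision = TP/(TP+FP), recall = TP/(TP+FN). Occlusion ratio
OR = occlusion events / (fish x frames) and occlusion detection ratio
ODR = detected-while-occluded / occlusions; with printed group sizes of 10,
20 and 40 fish over 500 frames and 125, 640 and 3040 occlusions these give
0.025, 0.064 and 0.152 exactly, which pins down the denominator convention.
Detection time is logged but never asserted — it is hardware-dependent.

Tracking: the distance between an obtained and a truth trajectory is the
mean Euclidean distance over their overlapping frames (infinite if they
never overlap). Each obtained trajectory is associated with at most one
truth trajectory while several obtained may share one truth; minimizing the
summed distance under these rules decouples per obtained trajectory, so the
optimum assigns each obtained trajectory with any overlap to its
minimum-distance truth — the exhaustive-search tests confirm the
equivalence. TCF (completeness) is the mean fraction of each truth
trajectory's frames covered by its associated obtained trajectories; TFF
(fragmentation) is the mean number of obtained trajectories per matched
truth. Identity switches count changes of the nearest-truth identity along
each obtained trajectory.

## The synthetic scene generator

The generator emulates the laboratory conditions the method targets: a
light tank bottom (gray 220) with Gaussian pixel noise (sd 4), static dark
speckle, and slowly drifting suspended particles (radius 1.5-3 px — below
the head-width band, so they are rejected by the width constraint); fish
with head widths uniform on [16, 24] px, head length 1.5x width, body 4.5x
width, rendered as an anti-aliased dark head ellipse (intensity ≈ 60 ± 6)
plus a chain of tapering body discs (≈ 95 ± 6) whose bend follows a
sinusoidal tail phase. Overlapping fish composite by the darkest pixel
(order-independent); scripted occlusion fixtures use painter's order so a
crossing body genuinely hides a head. Motion: a mean-reverting turn-rate
process (AR(1) coefficient 0.7, innovation sd 6°/frame) keeps per-frame
heading changes within ±45° for over 99% of frames; cruise speed is AR(1)
around 6 px/frame with burst surges (probability 0.02/frame, gain 1.5x),
emulating burst-glide; walls reflect specularly. An optional separation
steering (turn away from the nearest neighbor within a preferred distance)
emulates low-density, occlusion-free groups; it is off by default. All
randomness flows from one explicit seed, with per-frame sub-seeds, so
scenes and frames are bit-identical across runs.

Ground-truth occlusion flags are computed from the rendered body masks: a
fish is *occluded* when any other fish's mask overlaps its head mask, and
its head is *visible* when under 25% of head pixels are covered.

What the generator does **not** emulate: illumination gradients and
flicker, water-surface refraction, shadows, 3-D body roll (the real reason
head appearance varies), photorealistic texture, and behavioral interaction
beyond separation steering. Passing the synthetic benchmarks therefore
shows the pipeline's logic is sound under the stated imaging model, not
that the stated thresholds transfer to arbitrary footage — on real video
the width band `w`, contrast `k` and the cascade thresholds are the knobs
to recalibrate first.

## Numerical choices and degenerate inputs

* Gaussian kernels are truncated at 3 s and sampled analytically;
  second-derivative kernels are recentered to zero sum so constant images
  respond exactly 0.
* Otsu errors on constant frames (no valid threshold); the detector treats
  that as "no segmentation" and reports no detections for flat inputs.
* Ellipse fits with $|\lambda_2| < 10^{-8}$ are rejected as degenerate with
  a reason rather than producing unbounded ratios.
* The active contour falls back to the initial ellipse mask (with a
  warning) if the evolved mask collapses below 4 px².
* Cutting-line intersections use boundary pixels within 1 px of the line;
  if one side is empty the fitted minor axis is the fallback width.
* Greedy tie-breaks (association, linking, truth matching) scan in
  ascending score order with stable ordering, making every pass
  deterministic.

## Problem sizes used by the test suite

The packaged benchmarks run a 10-fish, 300-frame scene in a 560x560 px
arena with separation steering at 90 px — a low-density regime whose
occlusion rate (≈ 4% of fish-frames) matches a sparse laboratory group —
plus a stronger-separation variant (170 px, no head is ever covered) for
the identity-switch check, and
scripted two-fish fixtures for crossings, coverings and dropouts. These
sizes keep a full run to a few minutes while still exercising hundreds of
association decisions per track.
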