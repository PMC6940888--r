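---
title: "Measuring feeding kinematics of young broiler chicks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring feeding kinematics of young broiler chicks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feedkin)
```

## The measurement problem

A chick feeding at a trough handles each particle through a stereotyped
cycle of phases: fixation over the particle, approach, grasping, an upward
withdrawal of the head, then a series of *mandibulations* — single
open–close cycles of the beak — during stationing, transport and
swallowing. Two handling techniques matter for feed-form research:
*catch-and-throw*, where the particle is re-seated or thrown within the
beak with exaggerated head motion and gape, and *slide-and-glue*, where the
tongue transports the particle by adhesion (invisible to a silhouette
analysis and out of scope here).

Recorded laterally at high frame rate (250 fps here), the feeding scene
supports four kinematic variables per mandibulation:

* **maximum beak gape** (mm) — the largest distance between upper and lower
  beak tips within the cycle;
* **head displacement** (mm) — the total path length of the head (tracked
  at the eye) over the cycle;
* **duration** (ms) — the cycle's frame count times `1000 / fps`;
* **average head speed** (mm/s) — displacement over duration.

Mandibulations are numbered in temporal order within each feeding sequence:
1, 2, 3, and 4 for the fourth *and all later* cycles up to swallowing. Feed
types are compared nonparametrically (the variables are far from normal):
Spearman rank correlations across variables, Mood's median test between
feed types and orders, and a chi-square test on catch-and-throw
frequencies. Feed granulometry is summarised by the geometric mean diameter
(GMD) and geometric standard deviation (GSD) of a sieve stack.

No suitable public recordings of this scene exist, so the package pairs the
analysis pipeline with a synthetic scene generator that renders a
parametric lateral chick head with exhaustive ground truth. Every accuracy
claim in the test suite is a parameter-recovery statement against that
generator, not against real footage.

## The synthetic scene

`scene_config()` fixes the imaging model: a 384 x 256 px frame (a
quarter-scale stand-in for a 1536 x 1024 sensor), 250 fps, 0.1 mm/px, and
four pairwise-separated gray levels (background 200, head/beak 120, feed
particles 70, eye 30) with additive Gaussian noise (sd 5 by default) applied
*after* ground truth is recorded. A `kinematic_script()` fixes what the
head does: an approach-plus-withdrawal prefix, then mandibulation cycles
with scripted frame counts, peak gapes, per-frame head steps and
catch-and-throw flags.

Geometry choices that matter downstream:

* The beak is two lobes hinged at a vertex forward and below the eye; the
  gape is realised by rotating both lobes symmetrically about the hinge
  (half-angle `asin(g / 2L)` for tip separation `g` and lobe length `L`),
  a stand-in for coupled cranial kinesis. Both tips therefore share the
  same distal column, which the tip detector exploits.
* Each lobe is drawn as a triangle plus a *capsule* (a thick segment with
  rounded ends, radius 1.6 px) along its spine. A bare triangle thins below
  one pixel near the apex and breaks up under rasterisation and
  morphological opening; the capsule keeps the lobe at least kernel-wide
  out to the tip while leaving the scripted tip the most distal point.
* Within a cycle the gape follows `base + amp * sin(pi (t + 0.25) / n)`
  for frames `t = 1..n-1`, with frame 0 pinned exactly at the baseline
  (0.6 mm — the beak is never fully closed at cycle boundaries). The
  quarter-frame phase offset makes the maximum unique for odd and even `n`;
  pinning frame 0 makes every cycle boundary a unique single-frame minimum,
  so segmentation can recover scripted durations *exactly*. The withdrawal
  prefix ramps its gape down to the baseline and the closing tail starts
  slightly below it for the same reason.
* One "grasped" particle rides with the lower tip, rim-touching the lobe
  from below and poking past it distally: it corrupts tip detection unless
  its pixels are removed, while leaving the tip cap itself unoccluded.
  Remaining particles rest statically in the trough.

What the generator does **not** emulate: plumage texture, 3-D pose and
perspective, motion blur, the tongue, lighting gradients, occlusion by the
trough, and real particle shapes. Passing recovery tests therefore show the
pipeline is correct *given its geometric assumptions*, not that it would
meet the same tolerances on real footage.

## The vision pipeline

Per frame (`track_sequence()`):

1. **Eye detection** (`detect_eye()`): Otsu's threshold separates the
   animal from the background; a second Otsu pass over the foreground
   intensities isolates the darkest pixels. Connected components are
   filtered by area and circularity `4 pi A / P^2` and the most circular
   candidate wins (ties: larger area, then smaller y). The eye is the
   darkest *compact* blob in a lateral view, which is why circularity — not
   a Hough transform — suffices. With EBImage's boundary-pixel perimeter
   estimate, a disc scores noticeably higher than an equal-area square, so
   the published discriminations hold even though absolute circularity
   values are biased upward.
2. **Head ROI** (`extract_head_roi()`): a window anchored at the eye,
   6 eye-radii back/up/down and 14 toward the beak (the beak must fit
   whole; nothing in the recording geometry pins a window size, so this is
   a package default, configurable).
3. **Particle removal** (`remove_particle_pixels()`): Otsu threshold, keep
   only the 4-connected component containing the eye, excise pixels in the
   particle intensity band (70 +/- 25), then open with a 3 px diamond
   kernel. The ablation switch `removal_enabled = FALSE` skips *only* the
   band excision so enabled/disabled comparisons isolate exactly that step.
4. **Tip detection** (`detect_beak_tips()`): among mask pixels at least
   `min_offset` beyond the eye toward the beak, take the most distal
   column; split the pixels within `tip_band` of it into upper/lower
   clusters by vertical gaps; each cluster's tip is its most distal column
   at the column's mean y (sub-pixel, robust to one-pixel cap jitter). One
   cluster means a (near-)closed beak and both tips coincide.

Frames where any step fails are flagged and filled by linear interpolation
between neighbouring detections — dropped frames would corrupt the
frame-count-based durations. The gape is recomputed from interpolated tips
so `gape_px = ||upper - lower||` holds on every row. A sequence with more
than `max_fail_fraction` (default 20 %) failures is rejected outright.

Calibration (`calibrate_from_ruler()`) estimates mm/px from a ruler image
as `tick_spacing_mm / median inter-tick spacing`, with tick centres taken
from runs of dark positions in the axis-mean intensity profile; fewer than
three ticks is a failure.

## Segmentation and kinematics

`segment_mandibulations()` smooths the gape series with a 3-frame moving
average, finds local maxima with topographic prominence >= 0.3 mm and
separation >= 4 frames, and bounds each cycle by the local minima around
its peak. Numerical conventions, chosen once and tested everywhere:

* peaks on the *smoothed* series; boundary minima and the reported peak
  frame on the *raw* series;
* within the minimal region between two peaks, the left cycle ends at the
  *earliest* minimal frame and the right cycle starts at the *latest* one,
  so a flat inter-cycle plateau belongs to neither;
* intervals are half-open `[start, end)`, 0-based, like all pixel
  coordinates (x right, y down).

The defaults (window 3, prominence 0.3 mm, separation 4) sit an order of
magnitude below the 2–4 mm gape peaks the study conditions produce; they
are configurable because real footage could need retuning.

`detect_withdrawals()` opens a feeding-sequence boundary at each upward eye
excursion of >= 3 mm completed within 50 frames and preceded by a downward
approach; the boundary rides the rise while it keeps the minimum sustained
withdrawal rate, so slow drift is not mistaken for withdrawal. Annotated
boundaries, when available, are passed to `assign_orders()` directly and
override the heuristic entirely. Orders restart at each boundary and cap at
4 ("fourth and further").

`compute_kinematics()` interprets "total displacement" as the cumulative
2-D path length of the eye over the interval — head jerks during
swallowing would vanish under a net start-to-end distance; the net
displacement is emitted as an auxiliary column anyway. Durations use the
frame count of the half-open interval, so `speed * duration = displacement`
holds to machine precision on every record. A consequence worth stating:
with displacements of ~1–3 mm and durations of ~60–110 ms, average speeds
are tens of mm/s; that is what the displacement/time definition yields, and
this package emits only that definition.

Catch-and-throw flagging is annotation-first. Without annotations a
clearly-labelled heuristic flags records whose max gape *and* displacement
both exceed their episode medians — a convenience consistent with
"augmented movements of the head and beak aperture", not a validated
classifier; a single-record episode is never flagged.

## Statistics

* `spearman_test()`: average ranks for ties; rho is the Pearson
  correlation of ranks; two-sided p from the t approximation with n - 2 df
  (appropriate at the hundreds-to-thousands of records the campaign
  yields). An exact full-enumeration permutation p-value is available for
  n <= 8.
* `moods_median_test()`: 2 x k table of counts above vs at-or-below the
  pooled grand median, Pearson chi-square with k - 1 df. Values tied with
  the grand median count as "at or below" by default (the common
  convention; `ties = "discard"` is available since the original
  software's behaviour is unknowable). Expected counts below 5 raise a
  flag, not an error.
* `chi_square_independence()`: Pearson chi-square without continuity
  correction, expected counts from margins; zero margins are an error.
* No multiple-testing correction is applied by default, matching the
  analysis style the pipeline mirrors; users can `p.adjust()` downstream.

The test suite pins these to independent oracles: explicit counting plus
`chisq.test(correct = FALSE)` for Mood's test, and the tie-corrected
sum-of-squared-rank-differences formula for Spearman, both to 1e-12, plus a
1000-replicate null simulation keeping the type-I error in [0.03, 0.07] at
alpha = 0.05.

## Granulometry

`gmd_gsd()` computes mass-weighted log10 statistics over sieve classes
whose mean diameter is the geometric mean of the bounding apertures:
`GMD = 10^(sum(W log10 d) / sum(W))`, `GSD = 10^sd_log10` (the feed-science
convention of exponentiating the log standard deviation; GMD itself is
base-invariant). The pan class is bounded below by a configurable floor
(default 38 um) and the coarsest class above by `top aperture * sqrt(2)`
(a root-2 sieve progression), both flagged in the output, since neither
bound is observable from the stack itself.

## Problem sizes and runtime choices

The simulated campaign mirrors the study design: 19 birds x 3 feed types =
57 sequences. Rendered recovery runs use 5 mandibulations per sequence
(orders 1, 2, 3, 4, 4) — enough to exercise every order class — while
script-level bookkeeping uses the full per-feed totals (576/602/551 = 1729
mandibulations), whose rendering would add nothing to the recovery
question. Rendered batches stream through `analyze_batch()` one sequence at
a time (a fully rendered 57-sequence batch of doubles would not fit in a
typical session's memory). Per-feed cycle frame counts, gapes,
displacements and catch-and-throw rates (26 % / 20 % / 33 % for F1/F2/F3)
are drawn around the per-order medians the study conditions imply.

## Known limitations

* The vision pipeline assumes a single bird, fixed lateral pose, known
  facing direction, and an eye that is the darkest compact blob; none of
  these are inferred.
* Tip localisation is only defined for a silhouette whose lobes share a
  distal column (symmetric-rotation gape); strongly asymmetric jaw motion
  would need a different tip model.
* The catch-and-throw heuristic is relative to episode medians and
  saturates on short episodes.
* Summary statistics measured on real footage cannot be reproduced without
  that footage; the package's numeric claims are recovery and
  self-consistency claims on synthetic scenes, plus the self-contained
  design counts (57 sequences; 576 + 602 + 551 = 1729 mandibulations).
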