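# feedkin

Marker-free feeding-kinematics analysis for young broiler chicks, from
lateral high-speed imagery.

When a 3–4-day-old chick feeds, it handles each particle through a series
of **mandibulations** — single open–close cycles of the beak — after an
upward withdrawal of the head. How wide the beak opens, how much and how
fast the head moves, and how often the bird resorts to exaggerated
**catch-and-throw** repositioning movements all depend on the feed's
particle size (granulometry). `feedkin` implements the full measurement
chain for a 250 fps lateral recording of such scenes:

* **vision** — eye detection (intensity threshold + circularity filter),
  head-region extraction, feed-particle pixel removal, beak-tip detection,
  and pixel-to-mm ruler calibration;
* **kinematics** — segmentation of the beak-gape series into mandibulation
  cycles (prominence-filtered peaks, minima boundaries), temporal ordering
  within feeding sequences (1, 2, 3, 4 = "fourth and further"), and the
  four per-cycle variables: maximum beak gape (mm), head displacement
  (total eye path length, mm), duration (frame count × 1000/fps, ms) and
  average head speed (displacement/time, mm/s), plus catch-and-throw
  flagging (annotation-first, labelled heuristic otherwise);
* **statistics** — Spearman rank correlation (average ranks, t
  approximation), Mood's median test (2 × k counts about the grand median,
  Pearson chi-square, k − 1 df), chi-square test of independence, and
  descriptive (mean, SE, median) and percentage summaries;
* **granulometry** — geometric mean diameter and geometric standard
  deviation from a sieve stack:
  `GMD = 10^(Σ Wᵢ log₁₀ d̄ᵢ / Σ Wᵢ)`,
  `GSD = 10^√(Σ Wᵢ (log₁₀ d̄ᵢ − log₁₀ GMD)² / Σ Wᵢ)`;
* **synthetic scenes** — because no recordings are publicly available, a
  generator renders a parametric lateral chick head (dark circular eye, two
  beak lobes hinged at a vertex, feed particles, calibration ruler,
  Gaussian noise) from kinematic scripts, with exact per-frame and
  per-mandibulation ground truth. All accuracy claims are
  parameter-recovery results against this generator.

## A worked example

```r
library(feedkin)

cfg <- scene_config()                       # 384x256 px, 250 fps, 0.1 mm/px
sc  <- make_feeding_script("F3", 5, cfg, seed = 2024)   # crumble feed
fs  <- render_sequence(cfg, sc)             # frames + ground truth

cal <- calibrate_from_ruler(render_ruler(cfg, 1.0), 1.0)
cal$mm_per_px
#> [1] 0.1

res <- analyze_sequence(fs, cal)
res$records[, c("order", "max_gape_mm", "displacement_mm",
                "duration_ms", "speed_mm_s", "catch_and_throw")]
#>   order max_gape_mm displacement_mm duration_ms speed_mm_s catch_and_throw
#> 1     1        4.10            2.98          60      49.71           FALSE
#> 2     2        5.20            3.12          84      37.15            TRUE
#> 3     3        3.70            3.32          80      41.46           FALSE
#> 4     4        3.55            2.66          80      33.19           FALSE
#> 5     4        3.40            2.72          88      30.89           FALSE
```

Five mandibulations are recovered, ordered 1, 2, 3, 4, 4. The first cycle
of this crumble-fed bird is wide (4.1 mm) and fast (~50 mm/s — a short
60 ms cycle right after withdrawal); the second is a catch-and-throw
(augmented gape and head motion); later cycles, the swallowing phase, get
narrower and slower. Each row satisfies
`speed × duration / 1000 = displacement` exactly, and durations are frame
counts times 4 ms.

The numbered drivers under `analysis/` run the same machinery at study
scale — `01_simulate.R` (the 19-bird × 3-feed campaign and its 1729
scripted mandibulations), `02_track_recover.R` (rendered tracking +
recovery rates), `03_campaign_stats.R` (the statistical battery and
figures), `04_granulometry.R` (synthetic sieve stacks for the three feeds)
— writing tables under `results/`.

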