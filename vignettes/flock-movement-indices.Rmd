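---
title: "Measuring broiler flock crowding and movement from top-view video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring broiler flock crowding and movement from top-view video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flockmetrics)
```

## The problem and the model

Heat stress changes how a broiler flock behaves long before it shows up in
production figures: birds move less and crowd more, often around drinkers
or enrichment objects. With a single ceiling camera over the pen, both
behaviours can be quantified without handling the animals. `flockmetrics`
implements two group-level indices computed frame by frame from 1 frame/s
grayscale video:

**Cluster (crowding) index.** After segmenting the birds into blobs, a
frame with $n_A$ blobs of mean area $\bar A$ (px²), mean perimeter
$\bar P$ (px) and mean pairwise inter-centroid distance $\bar D$ (px) in an
$h \times w$ frame scores

$$\mathrm{CI} = \frac{2\,\bar A\,\sqrt{h^2 + w^2}}{\bar P\,\bar D\,(n_A - 1)}.$$

Fewer, larger, closer blobs (birds merging into groups) raise the index.
Touching birds are deliberately *not* split: blob merging is the crowding
signal, so the number of blobs is the number of visible clusters, not of
birds.

**Unrest (movement) index.** Consecutive frames one second apart are
compared through the symmetric Hausdorff distance between their bird point
sets $F(i)$ and $F(i-1)$, converted to centimetres:

$$\mathrm{UI}(i, i-1) = k \cdot \max\{d_H(F(i), F(i-1)),\; d_H(F(i-1), F(i))\},$$

where $d_H(A,B) = \max_{a \in A} \min_{b \in B} \lVert a - b \rVert$. For a
rigidly translated shape this equals the translation length, so the index
reads as "how far did the flock configuration move this second". The scale
factor comes from the camera mounting:

$$k = \frac{2 H \tan(\alpha/2)}{w_s} \quad \text{cm/px},$$

with camera height $H$ (cm), lens opening angle $\alpha$, and sensor length
$w_s$ (px) along the longest frame dimension.

Per-frame values are averaged into 30-minute blocks (1800 frames each; a
7-h session gives 14 blocks and 25,200 frames per condition) and compared
across a temperature (comfort 23 °C vs heat stress 31 °C) × enrichment
(enriched vs nonenriched) design with a split-plot-in-time repeated-measures
ANOVA and Tukey mean separation.

## Pipeline assumptions

- The camera is fixed, mounted at the pen's geometric centre, and the scene
  is lit well enough that birds and litter separate in intensity. Birds are
  assumed darker than litter by default; a `polarity` flag inverts this,
  because plumage/litter contrast is a per-deployment property.
- Sampling at 1 frame/s is achieved by frame skipping, never temporal
  averaging, and timestamps derive from `index / sample_rate_fps` because
  surveillance-container timestamps are unreliable.
- The frame area equals the analysed pen area; if the camera sees more,
  supply a `crop_region`. Rectangles are 1-based and closed
  (`c(row0, col0, row1, col1)`), the R matrix convention, used identically
  everywhere in the package.

## Segmentation parameters

| parameter | default | meaning |
|---|---|---|
| `lowpass_sigma` | 1 px | Gaussian smoothing; suppresses litter specks and feather texture before thresholding |
| `background_method` | `median_of_sequence` | pixel-wise temporal median (≤ 25 evenly spaced frames); alternatives: `fixed_image`, `global_threshold` |
| `threshold_method` | `otsu` | between-class-variance threshold on a 256-bin histogram; `fixed` for controlled fixtures |
| `min_blob_area_px` | 25 px | blobs smaller than this are removed as residual noise |
| `fill_holes` | `TRUE` | enclosed background holes become foreground (4-connected complement) |
| `connectivity` | 8 | foreground connectivity; diagonal contact merges blobs, consistent with reading blobs as clusters |

The median background is robust wherever each pixel shows litter in more
than half the sampled frames. Under strong crowding birds can park near an
attractor long enough to violate that, so the synthetic-scene analyses in
this package threshold the raw frame globally with Otsu instead — synthetic
scenes are bimodal by construction and the global threshold is then exact.
On real footage the median background is the safer default.

The perimeter estimator is a Moore-neighbour contour traversal with
orthogonal steps counted 1 and diagonal steps $\sqrt 2$; a single-pixel blob
gets perimeter 1 by convention (the traversal takes no steps). The cluster
index only needs an internally consistent estimator, so the same function
serves the pipeline everywhere; sub-pixel accuracy is not claimed.

## Numerical choices and degenerate inputs

- **Hausdorff fast path.** For pixel point sets the directed distances are
  computed through an exact Euclidean distance transform
  (Felzenszwalb–Huttenlocher), which agrees *exactly* with the exhaustive
  double-loop definition on integer grids; the test suite enforces identity
  against an independent brute-force oracle. `point_mode = "centroids"`
  trades the literal pixel-set reading for speed.
- **Invalid frames.** A frame with fewer than two blobs has no defined
  $\bar D$: its cluster index is `NA` and flagged, under both denominator
  variants. A frame pair with an empty mask yields a flagged `NA` unrest
  value, never zero (zero means "measurably static", which an empty mask
  cannot claim). Block averages use valid entries only and report the valid
  counts.
- **Degenerate statistics.** If an ANOVA effect has zero sum of squares the
  table reports $F = 0$, $p = 1$ rather than 0/0. If the Tukey fit has zero
  residual variance, equal means share one letter and distinct means get
  distinct letters.
- **Otsu on a constant image** raises an error with guidance (use a fixed
  threshold) instead of returning an arbitrary bin.

## Design choices where the formulas are ambiguous

Two typesetting ambiguities in the source formulas are exposed as flags
rather than silently resolved:

- The cluster-index denominator reads `P̄·D̄·nA−1`; the default
  interpretation is $\bar P \bar D (n_A - 1)$ (`variant = "nA_minus_1"`),
  with $\bar P \bar D n_A$ selectable (`variant = "nA_inverse"`). Both
  preserve the qualitative behaviour (fewer clusters ⇒ higher index).
- The frame-size factor defaults to the diagonal $\sqrt{h^2+w^2}$
  (`use_diagonal = TRUE`), which makes the index scale linearly under
  spatial rescaling (area × $s^2$ in the numerator over three length
  factors in the denominator); `use_diagonal = FALSE` gives the $h^2+w^2$
  reading.
- Whether the original Hausdorff operands were pixels, contours or
  centroids is not recoverable; `point_mode` records the choice, defaulting
  to the most literal one (all foreground pixels).

## The synthetic flock generator

No study videos are available, so the package ships a ground-truthed
simulator: 10 dark ellipses (semi-axes 7.5 × 4.5 cm, a 21-day broiler) on
light litter (intensities 60 vs 200) in a 496 × 976 px arena seen by a
3-m, 60° ceiling camera (k ≈ 0.355 cm/px), with single-pixel speck noise
(density 10⁻⁴, well under `min_blob_area_px`). Birds follow a bounded
random walk: each second a bird moves with probability
`1 − sit_probability`, by a truncated-normal magnitude around
`step_cm_per_s`, in a direction blending a random unit vector with the
direction to its nearest attractor (weight `crowding_strength`). Initial
placement is non-overlapping; overlap during motion is allowed because
merged blobs are precisely the crowding signal.

The four regime presets encode only the *orderings* reported for real
flocks — comfort moves more than heat stress within each enrichment level,
enriched more than plain within each temperature, heat stress crowds at
least as much as comfort, and the plain heat-stress pen sits the most:

| preset | step (cm/s) | sit prob. | crowding | attractors |
|---|---|---|---|---|
| `comfort_enriched` | 12.0 | 0.10 | 0.15 | drinker, feeder, rings, sand box, perch |
| `comfort_plain`    | 9.0  | 0.15 | 0.15 | drinker, feeder |
| `stress_enriched`  | 5.0  | 0.45 | 0.55 | drinker, feeder, rings, sand box, perch |
| `stress_plain`     | 3.5  | 0.55 | 0.60 | drinker, feeder |

The magnitudes are realistic per-second displacements for 21-day broilers
but are *not* fitted to any reported index value: absolute index means
depend on unreleased footage, so the simulator is validated on orderings
and on ground-truth recovery (blob counts, step lengths), not absolutes.

What the generator does **not** emulate: feather texture, shadows and
lighting gradients, occlusion by equipment, birds at the pen wall seen at
an angle, infrared-mode imagery, and any real behavioural time structure
(feeding bouts, synchronous resting). Passing tests therefore demonstrate
that the *measurement chain* is correct and sensitive at realistic effect
sizes — not that segmentation will be this clean on farm video, where
threshold and background parameters need per-deployment tuning.

## Statistical model

Block means are analysed as a split plot in time:
`aov(y ~ temperature * enrichment + Error(block/temperature))`. The
temperature main effect is tested in the block × temperature stratum
(13 error df with 14 blocks), enrichment and the interaction in the within
stratum (26 df). Blocks with missing means drop listwise with a warning;
unbalanced designs are tolerated with a warning. Tukey all-pairs
comparisons on the four condition cells use `multcomp::glht` on
`aov(y ~ block + condition)` with compact letter display at α = 0.05
(configurable).

## Problem sizes used in the validation suites

The shipped validation studies run the complete pipeline —
simulate → render → segment → indices → blocks → ANOVA — on 20 replicate
experiments of four regimes, each a 14-block session of 30 s per block at
half camera resolution (248 × 488 px, k ≈ 0.710 cm/px from the same camera
model). These sizes keep a full replicate around 25 s while preserving the
design's block structure; the orderings and the temperature effect are
recovered in ≥ 95 % of replicates. Full-scale sessions (25,200 frames per
condition) use the identical code path — only `experiment_design()` and
`arena_px` change.

```{r example, eval = FALSE}
design <- experiment_design(block_duration_min = 0.5,
                            session_hours = 14 * 0.5 / 60)
run <- simulate_experiment(seed = 1, design = design,
                           arena_px = c(248, 488))
split_plot_anova(run$blocks, "unrest")
condition_report(run$blocks)
```

## Known limitations

- No video decoding: frames must be extracted to images first.
- No identity tracking, pose estimation or occlusion splitting — by design,
  the indices are group-level.
- The unrest index is a flock-configuration distance: one fast bird and ten
  moderately moving birds can score similarly, because the Hausdorff
  distance is an extremum, not a mean.
- Tukey letters on real data depend on the (unstated) original error
  structure; the package documents its own model rather than claiming to
  reproduce any published letters.
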