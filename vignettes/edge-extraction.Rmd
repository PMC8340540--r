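---
title: "From predicted boundaries to thin edges: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From predicted boundaries to thin edges: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thinedges)
```

## The problem

Boundary predictors — typically neural networks — emit *ramp edges*: a band
of pixels around the true object contour whose intensity encodes the
model's per-pixel confidence. Many downstream tasks need the opposite: a
*thin edge*, a one-pixel-wide, 8-connected binary curve at an exact
position. `thinedges` implements the post-processing function that performs
this reduction, its evaluation metrics, and the discrete parameter search
that adapts the reduction to a given predictor and data set.

All images are plain R matrices indexed `[row, col]`, origin top-left.
Grayscale images hold integers in 0–255; binary maps hold 0/1 (written to
disk as 0/255 PNGs). The 4-neighborhood is N/S/E/W, the 8-neighborhood adds
diagonals, and positions outside the image always count as background.

## The extraction pipeline

`extract_edges(g, param_set(alpha, beta, gamma))` applies three stages in
fixed order.

**Thresholding.** Pixels strictly below `alpha` are zeroed; pixels at or
above it keep their value. This is deliberately the only denoising in the
pipeline: the threshold is a tuned parameter, and anything more aggressive
would entangle the stages and blur what the search optimizes.

**Skeletonization.** Three interchangeable methods reduce the surviving
band to a thin edge:

* `'2D'` — Zhang–Suen two-subiteration thinning of the binarized band.
* `'3D'` — directional border thinning of the binarized band treated as a
  single-slice volume: the classic six-subiteration volumetric scheme, in
  which the two out-of-plane subiterations are vacuous and the remaining
  four (N, S, W, E) delete simple, non-endpoint border pixels with
  sequential re-verification. Both baselines discard the confidence values.
* `'GWPS'` — the gray-weighted path skeletonize, which uses them. It first
  computes the gray-weighted distance transform: for every foreground
  pixel, the minimal accumulated intensity over 4-connected paths ending at
  an in-image zero pixel (the start pixel and all intermediate pixels
  contribute their intensity; the terminal background pixel contributes 0).
  The transform is exact — multi-source lowest-cost-first propagation with
  integer-valued costs — not a two-pass raster approximation, because the
  thinning order below consumes the *exact* cost ranking. Viewing the
  transform as a surface, the true contour runs along its crest: interior
  band pixels accumulate cost from both sides, so the ridge is where the
  confidence mass concentrates.

  The ridge is then extracted by ordered homotopic thinning: foreground
  pixels enter a priority queue keyed by (cost, row-major index); a popped
  pixel is deleted iff its eight-way neighborhood number
  $N_c = \sum_{k \in \{1,3,5,7\}} \bar x_k - \bar x_k \bar x_{k+1} \bar x_{k+2}$
  (with $\bar x = 1 - x$, neighbors numbered counterclockwise from the
  east, $x_9 \equiv x_1$) equals 1 — i.e. it is a *simple* pixel whose
  removal preserves local connectivity — and it still has at least two
  foreground neighbors. Deletions re-enqueue the neighbors, and the pass
  runs to a fixed point. Low-cost flank pixels are eaten first; crest
  pixels, whose deletion would either disconnect the curve ($N_c \neq 1$)
  or shorten it (endpoint), survive.

  Two rules here were genuinely open design choices. Endpoints (one
  foreground neighbor) are never deleted, otherwise open curves would erode
  from their tips to nothing; the price is that noise-induced side branches
  also survive, which is exactly what the separate pruning stage is for.
  And ties in cost are broken by row-major position, making the output
  bit-reproducible regardless of queue internals.

**Pruning.** Small irregularities in the band leave short branches
(*spurs*) on the skeleton. The limit `l = (gamma/100) * sqrt(w^2 + h^2)`
scales with the image diagonal so that one `gamma` means the same relative
aggressiveness at any resolution. A spur is a branch from an endpoint to a
junction; branches of at most `l` pixels (junction excluded, `l`
real-valued) are removed, repeatedly, until none qualifies — removing one
spur can expose another. Components that are entire open curves or closed
loops are exempt: pruning targets artifacts hanging off an edge, not the
edge itself.

Branch topology is read off the *skeleton graph*: foreground 8-neighbors,
with a diagonal link suppressed whenever its two pixels share a foreground
4-neighbor. Without this standard convention the pixel where a spur meets a
straight line counts as a junction through the diagonal shortcuts, and
every spur measures one pixel short — a 2-pixel spur would survive a
2-pixel limit. Endpoints are processed in row-major order; when two
removable spurs share a junction the first one wins and the second may
become part of a longer (no longer removable) branch, so the scan order is
part of the definition.

## Metrics

`sde(pred, gt)` is the symmetric mean of the two directional mean Euclidean
distances between the two pixel sets — one direction penalizes predictions
far from any true edge (precision-like), the other penalizes missed true
pixels (recall-like). It is 0 iff the sets coincide. Because a directional
mean is undefined against an empty set, evaluation replaces an empty map by
a single pixel at `(floor(h/2), floor(w/2))` (0-based); the correction
lives inside the metrics and never mutates saved outputs. A prediction that
collapses to nothing is thus scored by how far the image center is from the
truth — a large but finite penalty.

`iou_box(pred, gt)` compares shapes and absolute positions coarsely: the
bounding boxes (inclusive pixel areas) of all 8-connected components are
matched greedily, one-to-one, in descending pairwise IoU, and the score is
the mean matched IoU over ground-truth components (unmatched → 0).
One-to-one matching stops a single sprawling prediction from scoring
against many components.

`evaluate_pairs()` aggregates both metrics with mean, median, and the
population standard deviation (the image set is treated as the whole
population being reported, not a sample from one).

## Parameter search

`grid_search()` walks the grid with `alpha` outermost, `beta` middle,
`gamma` innermost, each in declared order, and selects the combination with
the lowest mean SDE — IoU-box is reported but never drives selection, which
keeps the objective one-dimensional. Ties keep the first combination
encountered; the full table is returned so callers can detect them. The
threshold + skeletonize result is cached across `gamma` values, which
cannot change any number since only pruning depends on `gamma`. A
combination that fails on an image (e.g. `alpha = 0` leaves GWPS without
background) scores that image through the empty-map correction rather than
aborting the search.

`default_grid()` covers every tenth threshold (0, 10, …, 250 — 26 values;
255 is unreachable by the stepping), all three methods, and for `gamma`
every integer 0–10 plus every tenth value 20–100 (20 values): fine where
pruning is plausibly useful, coarse above, 1560 combinations in total.

## The synthetic generator

`generate_sample()` emulates what a boundary predictor hands the pipeline,
with a known answer attached. A ground-truth curve — an open smoothed
spline with one pixel per column, or a closed perturbed ellipse rasterized
to a taut loop — is drawn at least 2 pixels inside the border. The boundary
is rendered as a Gaussian cross-profile,
`round(A * exp(-d^2 / (2 sigma^2)))` with `d` the Euclidean distance to the
nearest curve pixel, zeroed below 1; then gaps (runs of curve pixels whose
perpendicular slab of the band is zeroed — modeling incomplete
predictions) and additive Gaussian noise, clipped to 0–255, are applied.

Defaults are 64×64 images, `sigma = 2` and peak `A = 200` (a clearly
resolvable band about 12 px wide with ample headroom under 255),
`noise_sd = 8` (visible speckle, yet well below the useful threshold range,
so parameter recovery is well-posed), `jitter = 2` px of smooth curve
irregularity, and no gaps. Per-sample seeds derive as `seed + k - 1`;
curve generation and rendering draw from separately offset streams, so the
same curve can be re-rendered under different degradations.

What passing tests on this generator do **not** show: real predictors make
structured errors — asymmetric profiles, confidence plateaus, hallucinated
or doubled boundaries — none of which the isotropic Gaussian band emulates.
Results here validate the post-processing machinery (exactness, topology
preservation, metric arithmetic, search correctness), not any claim about a
specific predictor or data set.

## Numerical conventions and degenerate inputs

* GWDT costs are integer-valued and exact (stored as doubles, which are
  exact for these sums); an image without any zero pixel is an error, not
  silently padded, because the path definition requires an in-image
  background terminal.
* RGB inputs to `read_gray()` are converted with the standard luma weights
  0.299/0.587/0.114 and rounded.
* `spur_length_limit()` returns a real length; branch pixel counts are
  compared with `<=`.
* All randomness flows through explicit integer seeds; no function touches
  the global RNG state without restoring it.

## Scale of the shipped checks

The test suite exercises the exactness and topology guarantees at sizes
chosen to make the properties sharp but the run short: 200 random 16×16
images against an independent value-iteration transform oracle, all 256
neighborhood configurations, 100 noisy 64×64 boundaries for topology
preservation and idempotence, 50 noiseless ramps for ridge recovery
(mean ridge-to-truth distance ≤ 1 px; end-to-end SDE ≤ 2 px), 100 spur
skeletons for the pruning postcondition, and an 18-combination search
checked against a cache-free exhaustive re-evaluation. The acceptance
script runs the same machinery end to end (8-image search, 20-image ridge
recovery) and writes its numbers as JSON.

## Known limitations

* Distance-to-set queries (SDE, rendering) use a brute-force kernel,
  O(pixels × set size); fine for thin edges on moderate images, slow for
  dense maps on megapixel images.
* Pruning outcomes at junctions shared by several removable spurs depend on
  the documented row-major scan order; any single fixed order has this
  property.
* The `'3D'` baseline is the single-slice specialization of volumetric
  border thinning; it is provided as a comparison method, not as a general
  3D skeletonizer.
* No non-maximum-suppression baselines, no sub-pixel ridge localization,
  and no tolerance-based boundary correspondence (F-measure-style
  benchmarking) — the metrics operate on exact pixel sets.
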