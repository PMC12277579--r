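---
title: "Counting touching grains by concave points and elliptical approximation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting touching grains by concave points and elliptical approximation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grainsplit)
```

## The problem

Grain number is a primary yield component in cereal breeding, and
photographing grains scattered on white paper is the cheapest way to
measure it at scale. When grains are carefully separated, thresholding
plus connected-component counting is exact. In practice grains are poured,
not placed, and a substantial fraction touch: a connected foreground
region (one *contour*) may then contain two, three, or more grains, and
naive counters under-count while distance-transform watershed tends to
over- or under-segment elongated grains unpredictably.

`grainsplit` implements a contour-based counter for this regime. The idea
has two stages:

1. **Concave-point detection.** Where two convex grains touch, the
   region's boundary makes a concave notch. Concavity is measured with a
   *corner response function* (CRF): at a boundary pixel $p$,
   $\mathrm{CRF}(p) = n_p / A$, where $A$ is the number of raster pixels
   within Euclidean distance $R$ of $p$ and $n_p$ is how many of them are
   foreground pixels of the region. On a straight stretch of boundary
   CRF $\approx 0.5$; at a convex corner it drops (a quarter-plane corner
   gives $\approx 0.25$); inside a concave notch it rises above $0.6$.
   Pixels with CRF above a threshold form runs, and the run maximum is
   taken as one corner point. Corners cut the contour into *segments*.

2. **Elliptical approximation (cpe).** Wheat grains are close to
   elliptical. Each candidate grouping of the segments into subsets is
   scored by fitting one ellipse per subset and summing fit errors; the
   grouping that minimizes the total error determines the count. This is
   what makes the counter robust to *spurious* corners from chips,
   dents and bumps: the two arcs of a chipped grain lie on one ellipse
   and are merged back together, while arcs of different grains cannot be
   approximated jointly.

A corner-count-only estimate (*cp*), $N = N_{\mathrm{corners}}/2 -
R_{\mathrm{closed}} + 1$, is retained as the comparison baseline, along
with a watershed counter (`countWatershed`) and the accuracy metric
$CR = 1 - |N^{*} - N| / N$ (`countAccuracy`).

## Preprocessing

`preprocessPipeline()` chains: bilinear $2\times$ downsampling (each
non-overlapping $2{\times}2$ window becomes one pixel holding the
per-channel window mean, rounded half-up) → Gaussian smoothing →
RGB-to-HSV conversion → mean-shift color smoothing → scalar channel
extraction → Otsu thresholding → small-component suppression.

Defaults, all overridable through `grainConfig()`:

* `gaussianKernel = 5` with sigma derived from the kernel width
  ($0.3((k-1)/2 - 1) + 0.8$, the common discrete-Gaussian convention) —
  a light denoising filter; the pipeline only needs speckle removed
  before thresholding.
* `meanshiftSpatialRadius = 10` px, `meanshiftColorRadius = 20` intensity
  units: typical flat-background values; mean-shift flattens color
  regions without blurring the grain/paper edge. Convergence is declared
  when the joint position+color shift falls below 1 (in pixel+intensity
  units) or after 5 iterations.
* `grayChannel = "saturation"`: on white paper the saturation channel is
  the most contrastive scalar — paper has saturation near 0 regardless
  of shading, grains saturate strongly — so Otsu's threshold lands in a
  wide empty valley. Grains are the *bright* class in this channel; the
  `"value"`/`"luma"` alternatives use dark-grain polarity instead.
* `minComponentArea = 30` px: dust and chip debris suppression,
  applied after downsampling.

Degenerate inputs fail loudly: a constant image has no Otsu threshold,
a 1-pixel-wide image cannot be downsampled.

## Corner detection choices

* `crfRadius = 7` (configurable over 3–10). The radius sets the scale of
  concavity the CRF can see: too small and raster noise dominates, too
  large and nearby contacts merge. With the pipeline working at half the
  capture resolution, grains are 30–100 px long and $R = 7$ resolves
  contact notches cleanly.
* `crfThreshold = 0.6`: straight boundary sits at $0.5 \pm 1/R$, so 0.6
  clears the discretization band while catching genuine notches, which
  score 0.7–0.9.
* One corner per above-threshold run (the run's CRF maximum, ties to the
  lowest index; runs wrap around the contour end). Single-point runs
  count; runs are never merged across sub-threshold gaps — the partition
  stage is designed to absorb spurious corners, so over-detection is the
  safe direction.
* Disk membership uses Euclidean distance on pixel centers; at the image
  border the disk is clipped and only in-bounds pixels are counted.

$R_{\mathrm{closed}}$ in the cp formula is implemented as the number of
degenerate closed segments — a segment whose two bounding corners are the
same corner, which happens only when a contour has exactly one detected
corner. The quantity is not defined operationally in the literature this
estimator descends from; this reading makes a one-corner contour (an
isolated chipped grain) count as one grain, and is zero for every other
configuration arising here. The cpe stage does not use it.

## Ellipse fitting

`fitConicLSQ()` fits $a_{11}x^2 + 2a_{12}xy + a_{22}y^2 + 2b_1x + 2b_2y
+ 1 = 0$ by linear least squares (SVD pseudoinverse). Two numerical
choices matter:

* **Conditioning.** Raw image coordinates (hundreds of pixels) make the
  quadratic design matrix ill-conditioned ($x^2 \sim 10^5$ against
  $2x \sim 10^2$). Points are centered on their mean and scaled by half
  their bounding-box extent before solving; the conic is mapped back
  afterwards. The reported residual $\lVert D\alpha + 1\rVert^2$ lives in
  the conditioned frame, which makes it translation- and
  rotation-invariant and comparable across subsets.
* **Degeneracy is data, not an error.** Rank-deficient systems (collinear
  points, parallel lines) yield `isValidEllipse = FALSE` via the
  discriminant $a_{11}a_{22} - a_{12}^2$ and axis-positivity tests;
  fewer than 5 distinct points is the only hard error.

## The partition search and its constraints

`bestPartition()` enumerates **all** set partitions of the $k$ segments
(Bell-number enumeration; subsets need not be contiguous arcs, since the
two opposite arcs of a middle grain in a chain belong together), scores
each candidate, and returns the argmin; ties break toward fewer subsets,
then enumeration order. Per-subset results are cached by subset, so the
cost is driven by the $2^k$ distinct subsets rather than the $B_k$
partitions. `maxSegments = 10` ($B_{10} = 115{,}975$) bounds the search;
beyond it the contour falls back, flagged, to the cp estimate.

The score of a partition is
$\sum_s \left[ \mathrm{res}_s / n_s + \lambda\, d_s / B_s \right]$:
the pooled algebraic residual normalized by the subset's pixel count,
plus a center-dispersion penalty — $d_s$ is the mean distance between the
subset's pooled-fit center and the centers of ellipses fitted to each
constituent segment alone (segments too short or too degenerate to fit
contribute nothing), and $B_s$ is the smallest semi-minor axis among the
subset's fits. $\lambda = 1$ by default. The penalty expresses that
alternative inscribed ellipses for arcs of one grain should agree on
where the grain's center is.

Least squares alone, however, cannot decide the *count*: splitting every
segment into its own subset always achieves a near-zero residual, because
almost any short arc lies on *some* conic. What makes the problem
well-posed is that grains are solid objects, and the package encodes that
as validity constraints rather than tuning weights:

* a subset must pool at least 5 distinct pixels and fit a real ellipse;
* the fitted ellipse must be at least `minGrainArea` (default 30 px²) —
  mirroring the component-level dust filter;
* the ellipse **center must be a foreground pixel of the region**: an
  inscribed grain's center is grain, not background. This rejects fits
  to chip-bite arcs (the bite removed the would-be center) and runaway
  fits on short arcs;
* no two subset ellipses may **interpenetrate** by more than 40% of the
  smaller one's area (measured on a deterministic area-uniform interior
  sample). Touching grains overlap by a sliver of a few percent; the
  near-identical ellipses produced by splitting one grain at a spurious
  corner overlap almost entirely, as do the phantom ellipses that short
  contact-zone arcs generate inside real grains. This single geometric
  rule is what merges chip-split arcs and is the package's resolution of
  an otherwise ill-posed minimization; 40% sits in the middle of a wide
  empty margin between the two populations and is not sensitive.

Partitions violating any constraint score $+\infty$. After the search,
corner pixels themselves (which belong to no segment) are attached to the
adjacent subset whose fitted conic passes closer, giving a complete
pixel-to-grain labeling for overlays.

## The synthetic scene generator

The paper-grade validation data for this method are photographs of wheat
grains poured on white paper; `generateScene()` emulates that setting
with full ground truth. Grains are ellipses with semi-minor axis
uniform in 28–40 px and aspect ratio in 1.6–2.4 at the default
1984×1488 px canvas (the pipeline's working resolution; grains are then
30–100 px long after the pipeline's own 2× downsampling, matching a
smartphone photo of wheat at ~4000×3000). Colors are tan/brown
(hue 25–40°, saturation 0.45–0.65) with per-pixel Gaussian noise
(sd 5 on grains, 2 on the near-white paper). A `touchFraction` share of
grains is placed tangent to an earlier grain along a random direction,
overlapping ~3 px so the contact survives downsampling, in clusters
capped at 4; `chipProbability` adds circular bites of radius 10–25% of
the semi-minor axis centered on a boundary point — exactly the defect
that creates spurious corners. Placement retries are bounded and failure
is an error, not a silent degradation. A single seeded RNG stream drives
every choice, so scenes are bit-reproducible, and the generator
saves/restores the caller's RNG state.

What the generator does **not** emulate: uneven illumination and shadows,
perspective distortion, non-elliptical grains (the elliptical shape model
is also the method's own assumption), glued clusters of 5+, and camera
noise correlated across pixels. Passing counts on these scenes therefore
demonstrate the algorithmic chain — binarization, concavity detection,
partition search — under the method's stated assumptions, not performance
on arbitrary field photographs.

## Problem sizes used in the shipped checks

The test suite exercises constructed rasters (touching disks, chains,
chipped ellipses, wedges of known interior angle) where expected values
come from independent brute-force oracles, plus seeded end-to-end scenes
of 20 grains at the default resolution — ten with `touchFraction = 0.4`
and `chipProbability = 0.2`, ten fully separated — on which the cpe
count is compared with the cp and watershed baselines via the CR metric.
Those sizes mirror the modal composition of the method's original test
imagery (20 grains per image, loosely placed with a significant number
of contacts).

```{r, eval = FALSE}
sc <- generateScene(20, touchFraction = 0.4, chipProbability = 0.2,
                    seed = 7)
res <- runPipeline(sc)
res
accuracyRow(res, trueCount(sc), "seed7")
```

## Known limitations

* Runtime of the exact partition search grows with the Bell number of
  the segment count; contours with more than `maxSegments` segments
  (dense many-grain clusters) fall back to the cp estimate. An optional
  area-based bound on the subset count could prune the search but is not
  enabled.
* The elliptical model fails for strongly non-elliptical seeds (beans);
  the partition constraints assume grain-like convexity.
* Polarity is fixed to dark-ish grains on a light background; dark
  backgrounds require flipping the Otsu foreground flag.
* No illumination correction or color calibration is attempted.
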