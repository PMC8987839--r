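---
title: "Estimating the Green View Index with the chopped-picture method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the Green View Index with the chopped-picture method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The Green View Index (GVI) measures how much visible greenery a
pedestrian sees from the street. Given a survey of street-level
photographs (nominally 640×640 px, four cardinal headings per point),
the task is to decide, for each image, what share of the view is living
vegetation, and to aggregate that share over administrative districts
for mapping. Two families of automated approaches exist: per-pixel
colour rules, which are cheap but confuse green artificial surfaces
(turf, mats, signs) and mishandle shadows, and full semantic
segmentation, which is accurate but demands costly pixel-level
annotation. This package implements a middle road, the *chopped-picture
method* (CPM): weak rectangle annotations are chopped automatically
into thousands of small square patches that train a compact
convolutional classifier, which then scans whole images cell by cell.

```{r, eval = FALSE}
library(greenview)
fx <- generate_scene(random_scene_spec(1))      # synthetic streetscape
ann <- scene_to_annotations(fx, 4, 3, min_side = 96, seed = 2)
ps <- build_patchset(list(scene = fx$image), ann)
fit <- cpm_train(ps, cpm_config(epochs = 10))
g <- classify_grid(fx$image, fit)
gvi(g)                                          # percent greenery cells
```

## From rectangles to patches

An annotation is an axis-aligned box (0-based, half-open) labelled
greenery or other. `chop_rectangle()` tiles each box with 32×32-px
squares at a 16-px stride — 50% overlap both vertically and
horizontally — so a single 160×160 rectangle already yields 81 training
patches. Windows that would overhang the rectangle are discarded, never
padded: padding would fabricate pixels, and the tiling arithmetic
(`floor((side − 32)/16) + 1` per axis) stays exact. Patches inherit the
rectangle's label.

Because a 90%-pure rectangle still produces edge tiles that are mostly
background, `screen_patchset()` optionally re-checks every tile against
a per-pixel mask and keeps only tiles whose majority class matches
their label. This mirrors the manual screening step a human annotator
performs; it is automatic only where a ground-truth mask exists
(synthetic data), and real rectangle labels are otherwise trusted
as-is.

## The patch classifier

`cpm_train()` fits a LeNet-class binary network: two 3×3 convolution
blocks (32 and 64 feature maps, each ReLU + 2×2 max-pool), a 128-unit
dense layer with dropout 0.5, and a 2-way softmax. Published schematics
of patch classifiers at this input size leave the layer parameters
open, so the architecture is a configuration choice
(`cpm_config(filters=, dense_units=)`), not a constant. Training
defaults mirror the standard regime for this task: minibatches of 32,
Adam at its conventional default learning rate (10⁻³), a 20%
class-stratified validation split, 30 epochs. Class weighting is off by
default — annotation sets in this domain are naturally imbalanced
toward negatives and the method tolerates that — but a `"balanced"`
option exists.

The network itself is implemented in the package (C++ via
RcppArmadillo, im2col + GEMM convolutions) with every source of
randomness — initialisation, shuffling, the split, dropout masks —
drawn from R's RNG, so a seed fixes the entire fit and refits are
reproducible. Gradients were verified against central finite
differences during development; the separable-problem and texture-only
tests in the suite act as standing capacity oracles. The decision
threshold on the greenery probability defaults to 0.5 and is exposed in
the configuration; nothing in the method pins it.

## Scanning and the GVI

At inference `classify_grid()` tiles an image into *non-overlapping*
32-px cells — unlike training, because the evaluation convention and
the survey protocol use a disjoint 20×20 grid on a 640×640 image —
classifies every cell, and records the boolean cell mask. Remainder
pixels beyond the last full cell are truncated, consistent with the
chopper's discard rule. The per-image GVI is simply
`100 · positive_cells / total_cells`, kept in full precision internally
and formatted to two decimals only at I/O boundaries (65 of 400 cells
is 16.25%).

`aggregate_districts()` pools the per-image GVI by district with an
unweighted mean and drops districts with fewer than 10 images, the
conventional reliability floor for mapping. We pool all images rather
than first averaging the four headings per point: the survey defines a
district's GVI as the average positive rate of its images, and
per-point weighting is not part of that definition.

## The colour baseline

The comparison method is a per-pixel band-difference rule: a pixel is
greenery when G − R > δ and G − B > δ. The conventional δ = 0.05 is
interpreted on [0,1]-scaled channels; on a 0–255 scale 0.05 would be
below quantisation noise, so that reading is untenable. An optional
4-connected despeckler is provided but off by default, since reported
uses of the rule still leave shadow and artificial-green errors after
noise filtering. `color_mask_to_grid()` reduces the pixel mask with the
same strict >50% occupancy rule as everything else, putting both
methods on one footing.

## Evaluation protocol

`grid_confusion()` compares predicted and reference grids cell by cell
(paired by image id, shapes enforced) and `confusion_metrics()` reports
overall accuracy, precision and recall. A zero denominator (e.g. no
predicted positives) yields an explicit `NA` flagged in `undefined`,
never a silent zero — degenerate synthetic cases would otherwise
corrupt comparisons. Reference grids follow the rater rule: a cell is
positive when greenery occupies *strictly more than half* of it, so an
exact 50% tie is negative. Published applications of this protocol on
real street imagery report overall accuracy around 0.96, precision
0.73, recall 0.92 (one companion discussion restates recall as 0.90; we
treat the Results figure, 0.92, as canonical and note the
inconsistency); those numbers depend on proprietary imagery and serve
as qualitative anchors only.

## The synthetic scene generator

`generate_scene()` renders seeded streetscapes with a known per-pixel
greenery mask so the whole pipeline is testable offline. Regions are
painted in list order (later boxes overwrite earlier ones in both image
and mask) and the mask comes from region *geometry*, never from
rendered colours — ground truth must not depend on rendering noise.
The image is composited in floating point and quantised to 8-bit
levels at the end.

Category models, chosen once for separability of the signals the
method claims to use:

* **vegetation** — green base colour with multiplicative Gaussian
  luminance noise (amplitude 0.25) plus a mid-frequency blotch field
  (8-px scale): a texture signal a colour threshold cannot see.
* **shadow_vegetation** — vegetation with luminance scaled by a factor
  drawn from [0.3, 0.6]: dark but still textured and green-dominant.
* **artificial_green** — near-uniform green (amplitude 0.01): passes
  any colour rule, carries no texture.
* **sky** — vertical blue→white gradient; **building**/**road** —
  low-frequency gray shading with faint noise.

`random_scene_spec()` lays these out plausibly (sky band, building
band, road band, 2–4 vegetation boxes of 128–288 px, 0–1 shadowed, 1–2
artificial-green boxes of 96–192 px) on a 640×640 canvas.
`scene_to_annotations()` stands in for the human rater by
rejection-sampling boxes whose mask purity reaches 0.9 (positives) or
0.1 (negatives).

What the generator does *not* emulate: amorphous vegetation contours,
perspective, blur, seasonal/leafless vegetation, distant mountains,
image compression. No quantitative texture statistics of real
street-view vegetation were available to calibrate the amplitudes, so
they are chosen for class separability, not realism. Consequently a
passing synthetic suite demonstrates that the implementation is
correct and that the method's texture advantage over colour
thresholding is real *in the regime the generator creates*; it does
not certify field accuracy on real imagery.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere; pixel values live in
  [0,1] from patch creation onward (one normalisation point).
* Occupancy ties at exactly the threshold are negative (strict `>`).
* Max-pool ties take the first element scanned (deterministic);
  dropout uses inverted scaling so inference needs no correction.
* Single-class or empty patch sets, sub-cell images, zero-cell grids,
  mismatched grid shapes and infeasible annotation requests all fail
  fast with named errors rather than degrading silently.
* Byte-identical duplicate detection uses MD5 content hashes; "blank"
  means every channel's standard deviation is below 1.0 gray levels.

## Problem sizes in the test suite

The end-to-end recovery test trains on 12 synthetic scenes (84
rectangles of 128–224 px, ≈6.7 thousand chopped and ≈6.6 thousand
screened patches) for 10 epochs at the
default architecture and evaluates on 4 held-out scenes (1,600 cells),
checking cell accuracy ≥ 0.90 and that the classifier's false-positive
rate on artificial-green cells stays below the colour baseline's at
δ = 0.05. These sizes are the package's chosen desk-scale study
conditions; the unit suites use smaller networks (8/16 filters) and a
few hundred patches.

## Known limitations

* The classifier judges whole 32-px cells, so sparse greenery (branch
  tips, thin hedges) near the 50% occupancy boundary is the dominant
  error source — precision suffers before recall, consistent with what
  this protocol reports on real imagery.
* The CNN is intentionally compact; it is not a general vegetation
  detector and must be retrained per survey context.
* Blurred-image removal is a manifest exclude-list, not automated.
* GeoJSON export joins districts to polygons by id only; no geometric
  validation is attempted.
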