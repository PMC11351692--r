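---
title: "Measuring the fractal geometry of cultured neuronal arbors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the fractal geometry of cultured neuronal arbors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arborfract)
```

## The measurement problem

Cultured neurons imaged on a planar electrode form a network of dendritic
processes around cell bodies (somas). `arborfract` quantifies that geometry
with five measures:

* **D** — the box-counting fractal dimension of a single traced arbor, a
  measure of the ratio of fine- to coarse-scale dendritic structure,
  between 1 (a smooth curve) and 2 (a plane-filling pattern);
* **S** — the arbor's spatial coverage, the area of the convex hull of its
  trace (µm²);
* **N<sub>CNT</sub>** — total process length on the electrode divided by the
  electrode area (µm⁻¹);
* **G<sub>Si</sub>** — the fraction of the smooth substrate surrounding the
  electrode that is covered by glia;
* **coherency** — a structure-tensor statistic in [0, 1] that is 1 when all
  processes share one orientation and 0 for a uniform orientation
  distribution, used to verify that growth on the electrode is unrestricted.

Images are single-channel rasters with a physical calibration; the default
is `r round(AF_PIXEL_SIZE, 5)` µm/px (a 2048-px field of view spanning
662.65 µm). The electrode is a 2.145-mm square and orientation analysis is
restricted to its central 1.8-mm square to avoid edge effects; both lengths
are configurable in `pipeline_config()`.

## Tracing: from image to arbor

1. **Binarization** (`binarize`): global Otsu (default) or adaptive local
   mean thresholding, then removal of connected components smaller than
   `min_object_px`. Components are 8-connected throughout the package.
2. **Skeletonization** (`skeletonize`): Guo–Hall thinning — iterative,
   topology-preserving deletion of simple boundary pixels in two
   sub-iterations until no 2×2 foreground block remains. It is idempotent
   on already-thin input.
3. **Graph building** (`build_skeleton_graph`): skeleton pixels of degree 1
   (endpoints) and degree ≥ 3 (junctions) become nodes; maximal degree-2
   chains become edges. Edge length sums the chain steps with axial steps of
   one pixel and diagonal steps of √2 pixels. Each edge also carries its
   mean underlying intensity and mean local width (twice the distance
   transform of the pre-skeleton mask minus one pixel), the cues used for
   soma assignment.
4. **Soma detection** (`detect_somas`): blobs of the distance transform at
   least `min_soma_radius` wide are reported at their distance-transform
   maximum; ties fall to the first pixel in column-major order, and two
   somas closer than the radius threshold merge into one detection. This
   keeps the pipeline single-channel; a nuclear-stain detector is out of
   scope.
5. **Arbor extraction** (`extract_arbor`, `extract_arbors`) encodes the
   tracing rules as traversal predicates on the skeleton graph:
   * an edge is never visited twice;
   * at its attachment node, an edge must point at most 90° away from the
     radial direction from the soma. An edge violating this is admitted
     only if its territory cannot be reached by any admissible route — the
     "no other interpretation is possible" escape — in which case the
     least-violating connecting edge is taken;
   * traversal terminates at any other detected soma;
   * an edge claimed by several somas goes to the soma whose edges match it
     best under a configurable similarity score (equal weights on width
     continuity and normalized intensity continuity by default); ties break
     towards the shorter connecting path, then the lower soma index.

   The admitted edge set is computed as a fixpoint, so it is independent of
   node enumeration order. The radial rule is evaluated over the first five
   polyline steps of the edge (configurable via `rule_config()`).

## Box-counting dimension with scaling cut-offs

`box_count` covers the trace with a mesh of L×L boxes and records the
number of occupied boxes N(L). The "minimal covering" is approximated by
minimizing over four mesh origins (the origin and half-L shifts in x, y,
and both); the true minimal covering is a combinatorial problem, and offset
minimization is the standard approximation. Box sizes are log-spaced, 12
per decade, from 1 px to half the trace extent.

The fit window follows the measurement convention for dendritic arbors:

* fine cut-off `L_min` = the dendrite width, estimated as
  `2 × median(EDT on skeleton) − 1` pixels (exact for odd stroke widths,
  ±1 px otherwise);
* coarse cut-off `L_max` = 20% of the arbor width, where the arbor width is
  the larger side of the trace's tight bounding box (a maximum-caliper
  Feret alternative is available via `arbor_width = "feret"`; the choice of
  definition is a convention, and the bounding-box side is the default
  because it is parameter-free and deterministic).

`estimate_dimension` fits ordinary least squares to (log L, log N) inside
the window — no weighting, matching the plain-slope convention — and
reports D = −slope, the intercept, r², and the number of sizes in the
window. Fewer than three in-window sizes, or `L_max ≤ L_min`, raise an
"insufficient scaling range" error rather than returning a number.

`convex_hull_area` computes S by the shoelace formula over the convex hull
(base `chull`) of the trace's pixel centres; fewer than three non-collinear
points give S = 0 with a warning.

## The synthetic generator and what passing tests mean

The study images are not redistributable, so every estimator is validated
against synthetic ground truth:

* **Calibration shapes** (`calibration_shape`): a 1-px line (D = 1), a
  filled square (D = 2), and the triadic Koch curve
  (D = log 4 / log 3 ≈ 1.26186), with Koch iterations chosen as
  ⌊log₃(extent)⌋ so the smallest feature spans at least one pixel.
* **Self-similar trees** (`self_similar_tree`): binary trees with child /
  parent length ratio r = 2^(−1/D) — the similarity dimension of a binary
  tree — rooted at a soma. At the default 90° branch angle and r ≤ 1/√2 the
  H-tree layout is self-avoiding, so the box dimension of the ideal set
  equals D.
* **Network fields** (`network_field`): straight 100-µm processes at seeded
  random positions, either aligned at a fixed angle or with orientations
  uniform on [0°, 180°), for the coherency analysis. Segment centres are
  placed so segments lie fully inside the field, making the manifest length
  exact.

Every raster ships with a `ground_truth_manifest` recording total vector
length, nominal dimension, orientation mode, soma positions, stroke width,
noise level and seed.

### Dimension-recovery protocol

`dimension_recovery_experiment` fixes the study-scale conditions once:
arbors span ≈ 566 µm (85% of the field of view), per-seed trunk lengths are
scaled by U(0.85, 1.2) with a uniformly random initial orientation — this
averages the log-periodic oscillation that an exactly self-similar set
imposes on N(L) — branch angles carry ±5° of seeded jitter to break
grid-axis alignment, strokes are 1 px, canvases at least 2048 px, and the
depth (≥ 8) is chosen so terminal branches are ≈ 1.8 µm, several times the
dendritic width: a terminal branch must span several pixels to register as
a line element rather than a dot, and real terminal dendrites are likewise
much longer than they are wide.

Under this protocol the estimator recovers nominal D = 1.20 and D = 1.10
(the two group means the pipeline is anchored to) within ±0.05 over
10-seed means, as the test suite and `scripts/acceptance.R` verify.

### Known biases, stated rather than hidden

* **Finite-size bias of the tree oracle.** For a binary tree with ratio r,
  the box count of the ideal set obeys N(L) = A·x^D − B·x with x = span/L
  and B = 1/(2r − 1), so the local log–log slope (D − u)/(1 − u), with
  u = (B/A)·x^(1−D), exceeds D at any practical scale range and converges
  only like x^(−(D−1)). B ≈ 15.5 at D = 1.1: recovery there is biased
  upward by a few hundredths even in the ideal geometry. At D = 1.4 the
  opposite effect dominates — fine-scale inter-branch spacing approaches
  the stroke width, strokes merge, and recovered D lands near 1.30. The
  estimator is therefore trusted in the low-D regime the pipeline targets
  (≈ 1.0–1.25) and the high-D bias is a documented limitation.
* **Digitization bias of chain lengths.** The axial-1 / diagonal-√2 step
  convention overestimates the Euclidean length of a digitized straight
  line by (4/π)[sin 45° + (√2 − 1)(1 − cos 45°)] − 1 ≈ +5.5% in expectation
  over uniform orientations (zero for axis-aligned lines, +8.2% at 22.5°).
  Skeleton-length round trips on isotropic synthetic fields land at +5–6%
  for this reason; length comparisons between conditions are unaffected
  because the bias is common to both.
* **Coherency floor of finite fields.** The energy-weighted coherency of n
  independently oriented segments concentrates near √(π/(4n)), not at 0:
  a 200-segment field sits near 0.063 however isotropic its orientations.
  Electrode-scale images with thousands of processes can reach the
  10⁻³–10⁻² range; small synthetic fields cannot, and tests of the
  isotropic limit must be read against this floor.

The generator emulates single-channel fluorescence-like images of
skeleton-thin arbors: binary strokes without anti-aliasing, optional soma
disks, additive Gaussian background noise. It does not emulate dendrite
curvature or tapering, intensity falloff along processes, soma clustering,
out-of-focus light, or stitching artifacts — so passing tests validate the
estimators and the traversal semantics, not robustness to every property of
real micrographs.

## Orientation coherency

`orientation_coherency` Gaussian-smooths the image (σ = 2 px by default),
takes central-difference gradients, and sums the structure tensor over the
centre crop (energy weighting, matching the "entire region" convention).
Coherency is (λ₁ − λ₂)/(λ₁ + λ₂) of the summed tensor; the mean orientation
is the dominant structure direction in [0°, 180°) measured from the +x
axis. A constant crop has zero gradient energy and returns coherency 0 with
a `no_signal` flag instead of an undefined orientation.

## Group statistics

`group_summary` reports mean ± SEM (SD/√n) with a t-based 95% CI.
`paired_t` implements the two-sided paired t-test on differences, with
explicit degenerate handling: identical samples give t = 0, p = 1
(flagged); constant nonzero differences give t = ±∞, p = 0 (flagged).
Because the two culture ages sample *different* cells and no pairing map
between them is given, `comparison_table` defaults to Welch's unpaired test
and marks the variant used in its output; the paired variant is applied
only when the caller asserts a pairing (`pairing = TRUE`). No
multiple-testing correction is applied, matching the reporting convention
the pipeline reproduces.

## Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` use 2048-px canvases, 10-seed
replicate sets for dimension recovery and coherency, 1000 replicates for
the type-I-error check, and 64×64 masks for the brute-force box-counting
oracle — sizes at which every check runs in seconds to a couple of minutes
on one core. A single integer seed drives every stochastic stage;
`run_pipeline` writes a JSON run manifest (config, seed, package version)
sufficient to reproduce its outputs bit for bit.
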