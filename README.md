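# arborfract

Fractal morphometry of neuronal arbors on planar electrode surfaces.

Neurons cultured on flat electrode materials grow branched dendritic arbors
whose geometry changes as the network matures. `arborfract` is an R package
for quantifying that geometry from calibrated single-channel images of
labeled neurons: it traces individual arbors out of the network, measures
their box-counting fractal dimension and convex-hull coverage, summarizes
electrode-level process density, glial substrate coverage and orientation
coherency, and compares culture-age groups. It is written for
neuro-engineering and cell-biology groups who need these measurements to be
reproducible and testable: a synthetic-arbor generator with analytic ground
truth ships with the package, so every estimator can be validated without
access to raw microscope data.

## The measures

For a traced arbor covered by a mesh of boxes of side *L*, the minimal
number of occupied boxes scales as

&nbsp;&nbsp;&nbsp;&nbsp;*N(L) ~ L<sup>−D</sup>*

and **D** (the box-counting fractal dimension) is minus the slope of an
ordinary least-squares fit of log *N* against log *L*, restricted to the
scaling window between the dendrite width (fine cut-off) and 20% of the
arbor width (coarse cut-off). Alongside *D*, the package reports

* **S** — convex-hull area of the trace (µm²), the arbor's spatial coverage;
* **N<sub>CNT</sub>** = *N<sub>LCNT</sub>* / *A<sub>CNT</sub>* — total
  process length per electrode area (µm⁻¹);
* **G<sub>Si</sub>** — fraction of the surrounding substrate covered by glia;
* **coherency** = (λ₁ − λ₂)/(λ₁ + λ₂) of the region-summed structure tensor
  — 1 for total alignment, 0 for uniformly distributed orientations;
* group summaries (mean ± SEM, 95% CI) and two-sided paired or Welch
  *t*-tests between culture ages.

Tracing converts an image into a skeleton graph (Otsu/adaptive threshold,
Guo–Hall thinning, junction/endpoint graph with √2-weighted diagonal steps)
and extracts one arbor per soma under explicit traversal rules: no edge is
visited twice, edges may not turn more than 90° against the radial
direction from the soma unless no other interpretation is possible,
traversal stops at neighboring somas, and contested edges are assigned by
width/intensity continuity. The methods vignette
(`vignettes/arborfract-methods.Rmd`) documents the model, every tunable
parameter, and the known biases of the estimators.

## A worked example

Generate a synthetic arbor of known similarity dimension, rasterize it as a
fluorescence-style image on the default 2048-px field of view
(0.32356 µm/px), and run the full single-image analysis:

```r
library(arborfract)
set.seed(7)
tree <- self_similar_tree(1.2, depth = 9, trunk_length = 290,
                          jitter_deg = 5, initial_angle = runif(1, 0, 360))
ras  <- rasterize_geometry(tree, soma_radius = 5, min_canvas_px = 2048)
res  <- analyze_image(ras$image, pipeline_config())
res$arbors
#>   neuron_id  x_um  y_um     D r_squared L_min_um L_max_um  S_um2 length_um
#> 1         1 7.927 269.4 1.177    0.9944   0.3236    99.53 164749      5480

orientation_coherency(ras$image)
#> orientation_result: coherency 0.0142, mean orientation 4.4 deg
```

Reading the output: the soma was detected at (7.9, 269.4) µm; the traced
arbor's box-counting dimension is **D = 1.177** (fitted over box sizes from
the measured dendrite width, 0.32 µm, up to 99.5 µm = 20% of the arbor
width, with r² = 0.994) — close to the tree's nominal similarity dimension
of 1.20. The convex hull covers **S = 164,749 µm²**, the traced length is
5,480 µm, and the arbor's orientation coherency is near zero, as expected
for a branching pattern with no preferred direction.

`run_pipeline()` applies the same analysis to a set of electrode images
(TIFF in; CSV, SWC and a JSON run manifest out) and emits a group
comparison table when two culture ages are present. A thin command-line
wrapper with `simulate` and `analyze` subcommands is installed at
`inst/scripts/arborfract-cli.R`.

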