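# invasiveZone

Tumor-border digitization and invasive-zone analysis for nanoscale spatial
transcriptomics.

Margin tissue around a liver tumor is where invasion happens, but standard
spatial analyses treat a slide as one bag of spots. `invasiveZone` implements
a scanning-and-digitization model (SDM) of the tumor border for
Stereo-seq-style data: it recovers the border from the data themselves,
builds a coordinate system around it — six 250 µm layers on the two sides
plus distant reference bands, each layer cut into 100 equal-area tangential
tiles — and profiles cell composition and expression along both axes. The
package is for computational biologists analyzing tumor-margin slides (or
prototyping against synthetic ones): the 500 µm-wide band centered on the
border (the *invasive zone*) is where immune infiltration, exhaustion and
damaged SAA-high hepatocytes concentrate.

## The model

Given per-spot cell types (from the built-in marker scorer or an external
annotation), the SDM proceeds:

1. rasterize predicted hepatocytes into a binary mask (25 µm pixels), keep
   the dominant tissue component after window thresholding (5 px, ≥ 0.4);
2. march the mask boundary, drop slide-edge segments, and smooth x(s), y(s)
   with df = 20 splines on arc length → the border curve, oriented with the
   paratumor side positive;
3. offset the curve ±250/±500/±750 µm along its normals → layers l ∈
   {−3..−1, +1..+3}, plus distant bands at 2.00–2.25 mm;
4. cut each layer at equal-cumulative-area quantiles along the arc → tiles
   t ∈ 1..100;
5. assign each spot: layer from its signed border distance d via
   sign(d)·⌈|d|/250⌉, tile by the sign of the cross products of its centroid
   against the tile edges.

Downstream: per-layer composition under "all cells" and "nonparenchymal"
denominators, gene-set signature scores per unit, and the tangential pattern
analysis — merge the bilateral first-layer tiles at each position, drop
parenchymal cells, cluster the composition vectors on 1 − Pearson r
(Ward linkage, silhouette-selected k), and test pattern–recurrence
association with a chi-squared test plus a log2 observed/expected enrichment
score.

A ground-truthed generator (`generate_slide()`, `generate_cohort()`)
simulates margin slides with the published gradients planted (macrophages
3.9% → 8.6% toward the border, exhausted T 0.09% → 0.54%, immune > 30% in
the first tumor-side layer, SAA-high hepatocytes confined to the first
paratumor layer, five tangential archetypes), so the whole pipeline is
testable without access-controlled human data.

## Worked example

```r
library(invasiveZone)

# a 3 x 3 mm synthetic margin slide with a gentle cosine border
sl <- generate_slide(
  config = slide_config(slide_extent_um = c(3000, 3000), rng_seed = 7),
  border = border_spec(amplitude_um = 200, period_um = 3000, center_um = 1500),
  seed = 7)

bm  <- cpm_normalize(aggregate_bins(sl$gem, 50))   # bin50 pseudo-spots
ann <- annotate_spots(bm, sl$model, seed = 1)      # marker-score typing
mod <- build_border_model(ann, c(3000, 3000), df = 8)
asn <- assign_spots(ann, mod)
prof <- layer_composition(asn, ann, denominator = "all")
prof[prof$layer %in% c("-3", "-1") & prof$cell_type == "macrophage", ]
```

```
    slide  layer  cell_type     n n_layer   fraction denominator   flag
   <char> <char>     <char> <int>   <int>      <num>      <char> <char>
1: slide1     -3 macrophage    55    1252 0.04392971         all
2: slide1     -1 macrophage   112    1257 0.08910103         all
```

The generator planted 3.9% macrophages in layer −3 and 8.6% in layer −1; the
pipeline, working only from counts, recovers 4.4% and 8.9% on this small
slide — the residual error comes from border-recovery bias (~14 µm on a
25 µm raster) and the ~1250 spots per layer. On the full 10 × 10 mm default
slide the estimates are 4.1% and 8.4% with ~4400 spots per layer.

```r
mean(ann$cell_type[match(sl$truth$spot_id, ann$spot_id)] == sl$truth$cell_type,
     na.rm = TRUE)
#> [1] 0.9986111   # typing accuracy against generator truth
```

`run_pipeline(default_run_config(seed = 1), out_dir = "sdm_out")` chains
simulate → bin → type → digitize → assign → profile and writes assignment,
annotation and profile TSVs, border/band geometry as WKT, and a JSON manifest
with parameter and file hashes; reruns are byte-identical.

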