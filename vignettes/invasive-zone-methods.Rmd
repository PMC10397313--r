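---
title: "Digitizing the tumor border: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digitizing the tumor border: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`invasiveZone` implements a scanning-and-digitization model (SDM) for tumor
borders in nanoscale spatial transcriptomics of liver-cancer margin slides,
together with the downstream analyses of the 500 µm-wide *invasive zone*
centered on that border. This vignette explains the model, its parameters,
the numerical choices behind the implementation, and what the synthetic-slide
generator does and does not emulate.

## The data model

The input is a GEM table: one record per (gene, x, y, count), where x and y
index DNA-nanoball (DNB) capture bins on a ~0.5 µm grid. Because single-bin
capture is shallow, records are convolved into square pseudo-spots:
50 × 50 bins (25 µm, "bin50") approximates one cell and is the unit of cell
typing; 1000 × 1000 bins (500 µm, "bin1000") gives local pseudo-bulk
microenvironment units, about 400 per 10 × 10 mm slide. One declared
convention prevents unit drift: files store integer bin indices, all geometry
is computed in µm (`µm = index × bin_pitch_um`), origin at the slide's
lower-left corner.

## Cell typing

Spots are typed from CPM-normalized expression by marker-panel scoring: each
marker gene is standardized across spots (z-score), a panel's score is the
mean z over its genes, and the spot takes the highest-scoring panel (ties by
panel order). Subtypes are resolved the same way within the parent type
(here: conventional vs exhausted T/NK). SAA-high hepatocytes (Hep1) are
called by the difference of two gene-set module scores — GS1, the SAA program
(SAA1/SAA2 plus acute-phase genes), against GS2, its SAA-low counterpart — a
spot is Hep1 iff score(GS1) − score(GS2) > 0. The module score is mean
expression of the set minus the mean of control genes drawn per set-gene from
the same average-expression quantile bin (25 bins, 100 controls per gene,
fixed seed); this is the standard bin-matched-control construction and is
deterministic given a seed. The threshold of 0 on the score difference is the
natural symmetric choice; no tuned cut is involved.

Real-data workflows may type spots externally (e.g. by reference
deconvolution); the pipeline accepts a pre-computed annotation table and then
skips marker scoring, so the SDM is independent of how types were obtained.

## The border SDM

1. **Mask.** Spots typed hepatocyte are rasterized into a binary image
   (default pixel 25 µm, one bin50 spot).
2. **Denoise.** A pixel is foreground iff the foreground fraction in its
   5 × 5 window is ≥ 0.4; this removes scattered hepatocyte calls on the
   tumor side and solidifies the paratumor field. Only the largest connected
   component — the bulk liver tissue — is retained. Both parameters are
   exposed; the defaults assume the paratumor field is hepatocyte-majority
   (fraction > 0.4), which holds for liver margin tissue.
3. **Contour.** The component's ordered boundary is marched, clipped to the
   slide interior (segments running along the slide edge are removed), and
   refined by half a pixel toward the background: boundary pixel *centers*
   sit half a pixel inside the region, so this standard rasterization
   correction removes most of the systematic offset of the recovered border.
4. **Smoothing.** x(s) and y(s) are fit with smoothing splines on the
   chord-length parameter (default df = 20) and resampled at ≤ 5 µm. The
   default df is calibrated to a ~10 mm border (about one basis function per
   500 µm); for shorter borders df should be scaled down proportionally,
   otherwise the spline has spare degrees of freedom to chase raster noise
   and the resulting wiggles show up as spurious curvature. The curve is
   oriented so the hepatocyte (paratumor) side is signed-positive.
   Self-intersecting fits raise an error advising local segmentation —
   automated handling of pathological borders (multifocal tumors, parabola-
   like folds) is out of scope.
5. **Layers.** Offset curves at ±250, ±500, ±750 µm are built by normal
   displacement of the resampled spline, with pruning of locally inverted
   vertices; bands are closed against the slide rectangle. A precondition
   check requires the radius of curvature to exceed the outermost offset
   along ≥ 95% of the arc, because normal offsets are ill-defined past the
   local center of curvature. Two 250 µm *distant* reference bands at
   2.00–2.25 mm complete the layer set; their membership is defined by signed
   distance (offsets at 2 mm can fold on curved borders, so the distant bands
   are never tiled).
6. **Tiles.** Each layer is divided into 100 tiles of approximately equal
   area: cumulative band area is accumulated along the arc at ≤ 5 µm
   resolution and 99 cut lines are placed along local normals at equal-area
   quantiles. Areas are accumulated on slide-clipped strips, so the tiles
   partition the *in-slide* band area; a tile fully swallowed by the slide
   boundary is kept as a flagged empty placeholder so indices stay aligned
   along the border.
7. **Assignment.** A spot's layer comes from its signed distance
   (`ceil(|d|/250)` with the sign giving the side); its tile is verified by
   the cross-product rule — the spot is inside a (fan-decomposed) tile iff
   the cross products against all edges share a sign — with boundary spots
   going to the lower (layer, tile) index. The signed-distance field is the
   cross-check oracle for the band geometry, and an independent even–odd
   ray-casting test is used in the test suite to validate assignments.

## Zone profiles and tangential patterns

Layer composition is reported under two denominators, *all cells* and
*nonparenchymal* (excluding malignant/cholangiocyte and hepatocyte), because
margin-area studies use both. Exhausted T cells are counted as their own
composition entry (they are generated and detected as a T/NK subtype). A
light-weight signature score (mean z-score of a gene set across units) is
provided for direction-of-effect comparisons between zones; it is a declared
stand-in, not an implementation of GSVA.

For the tangential analysis, the two bilateral first-layer tiles at each
position t are merged, parenchymal cells are excluded, and the resulting
composition vectors (7 nonparenchymal types; exhausted T folded back into
T/NK) are clustered on the distance 1 − Pearson r. The tree is cut at the
k ∈ 2..10 maximizing the mean silhouette width, or at a fixed k. The default
linkage is Ward (ward.D2): with average linkage the silhouette criterion
systematically merges the intermediate fibroblast+macrophage pattern into its
fibroblast- and macrophage-dominant neighbours at realistic cells-per-
subregion, collapsing five planted patterns to four; Ward favours compact,
balanced clusters and resolves the intermediate pattern reliably. Average
linkage remains available via the `linkage` argument. Pattern–recurrence
association uses a chi-squared test on the pattern × recurrence table of
subregions, and the per-pattern enrichment score is log2(observed recurrent
fraction / overall recurrent fraction) — a reconstruction, since enrichment
bar charts of this kind rarely state their formula.

## The synthetic-slide generator

The generator is first-class, tested code: it lays pseudo-spots on the bin50
grid, draws a true border (straight or cosine; cosine phase is chosen with
zero slope at the slide edges so offsets stay inside), assigns each spot a
true type from its layer's composition profile, and draws counts from a
multinomial-Poisson model with negative-binomial depth (mean 2000,
dispersion 0.5, inside the observed 589–4642 molecules per spot) and marker
panels up-weighted 2^3 over a lognormal baseline (200 genes total: 130
structured, 70 background). GEM records land on random DNB bins inside each
spot's window, so bin aggregation is exercised end to end.

The default composition profile plants the study conditions: macrophages
3.9% → 8.6% from the third to the first tumor-side layer, exhausted T cells
0.09% → 0.54%, total immune fraction > 30% in the first layer, and SAA-high
hepatocytes confined to the first paratumor layer (half of its hepatocytes).
Layer gradients of the remaining types are free parameters chosen to fall
off smoothly with distance from the border.

Two generator design choices matter for interpreting test results:

* **Balanced composition draws.** Within each truth region, types are
  allocated by largest-remainder apportionment of the exact profile and then
  randomly permuted over spots. The realized composition therefore matches
  the profile at the realized n (up to rounding), so recovery error measured
  by the tests reflects the pipeline (border recovery, typing error,
  boundary mixing) rather than simulator sampling noise. An i.i.d.
  multinomial draw would add ±0.4 percentage points of noise to a layer
  fraction at n ≈ 4000, which would dominate the quantities under study.
* **Blockwise archetypes.** Cohort slides plant tangential composition
  archetypes in contiguous blocks of 10 segments, emulating the spatially
  autocorrelated niches seen along real borders; only block boundaries
  produce mixed subregions.

Cohort defaults: 16 patients × 2 slides of 6 × 2.5 mm (3200 candidate
subregions, matching the real denominator), five archetypes (fibroblast;
fibroblast+macrophage; macrophage; B+T/NK; endothelial-dominant) with
per-segment lognormal jitter (sd 0.15), and a recurrence mixture with
archetype weights (1,1,2,1,1) in recurrent and (3,1,1,1,1) in non-recurrent
patients — a planted odds ratio of 3 for the macrophage-dominant archetype.
The cohort profile raises the nonparenchymal share of the two first layers
(an immune-active margin) so each merged subregion carries ~29 nonparenchymal
cells, enough for its composition to be informative, while keeping the first
paratumor layer hepatocyte-majority so the mask stays well defined.

What the generator does **not** emulate: transcriptome-wide covariance,
doublets and segmentation errors, spatial expression gradients within a
type, capture-efficiency variation across the chip, tissue morphology, and
multifocal borders. Green tests demonstrate that the pipeline recovers the
structure it is designed to measure under a faithful but idealized data
model; they do not certify performance on real slides, where typing error
and mask quality are the dominant risks.

## Numerical choices and degenerate inputs

* Problem sizes: the default slide is the full 10 × 10 mm study condition
  (160k spots, ~30M records, ~2 min end to end); the test suite uses 3 × 3 mm
  slides with df = 8 for unit-level checks.
* All randomness flows from explicit seeds; module-score control sampling
  saves and restores the caller's RNG state, and reruns of the pipeline with
  one config are byte-identical.
* Ties: argmax typing breaks ties by panel order; boundary spots go to the
  lower (layer, tile) index; silhouette ties resolve to the smaller k via
  `which.max`.
* Degenerate inputs raise early, named errors: empty masks, multi-component
  masks, borders leaving the slide, curvature beyond the offset radius,
  zero-area bands, identical GS1/GS2 sets, gene sets absent from the matrix,
  all-zero spots pass through CPM as zero rows and are excluded from
  z-scoring panels via the zero-variance rule (with a warning).
* `signed_distance` uses a coarse-to-fine nearest-vertex search with segment
  projection; against a brute-force oracle on a 0.25 µm-resampled curve its
  error is bounded by ~2.5 µm, well below the 25 µm raster pixel.

## Known limitations

The cross-product tile test presumes near-convex tiles; at curvature radii
approaching the layer offset, tiles distort and the fan decomposition about
the centroid is the operative definition. Borders must be single, simple
curves spanning the slide; multifocal tumors are out of scope. The
recurrence enrichment score treats subregions as independent, as the source
analysis does, although subregions within a patient are correlated — the
chi-squared p-value is anti-conservative in that sense and should be read as
a ranking device, not a calibrated error rate.
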