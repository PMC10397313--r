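# Shared fixtures, computed lazily once per test run. The standard small
# slide is 3 x 3 mm with a gentle cosine border (radius of curvature
# ~1.5 mm, curvature-safe for 750 um offsets); spline df scales with border
# length (~1 basis function per 500 um of border, matching 20 df on a 10 mm
# border).

fx_env <- new.env(parent = emptyenv())

fx_config <- function() slide_config(slide_extent_um = c(3000, 3000),
                                     rng_seed = 42L)
fx_border <- function() border_spec(amplitude_um = 150, period_um = 3000,
                                    center_um = 1500)
FX_DF <- 8

fx_slide <- function() {
  if (is.null(fx_env$slide))
    fx_env$slide <- generate_slide(config = fx_config(), border = fx_border(),
                                   seed = 42L)
  fx_env$slide
}

fx_bm <- function() {
  if (is.null(fx_env$bm))
    fx_env$bm <- cpm_normalize(aggregate_bins(fx_slide()$gem, 50))
  fx_env$bm
}

fx_ann <- function() {
  if (is.null(fx_env$ann))
    fx_env$ann <- annotate_spots(fx_bm(), fx_slide()$model, seed = 7L)
  fx_env$ann
}

fx_model <- function() {
  if (is.null(fx_env$model))
    fx_env$model <- build_border_model(fx_ann(), c(3000, 3000), df = FX_DF)
  fx_env$model
}

fx_asn <- function() {
  if (is.null(fx_env$asn))
    fx_env$asn <- assign_spots(fx_ann(), fx_model())
  fx_env$asn
}

# small random GEM table on a bounded grid
toy_gem <- function(n = 1000, n_genes = 20, grid = 500L, seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed(as_gem_table(data.frame(
    gene = sample(sprintf("g%02d", seq_len(n_genes)), n, replace = TRUE),
    x = sample.int(grid, n, replace = TRUE) - 1L,
    y = sample.int(grid, n, replace = TRUE) - 1L,
    count = sample.int(5, n, replace = TRUE))))
}

# bin_matrix built directly from a dense counts matrix (spots x genes);
# centroids on a unit grid
toy_bm <- function(counts, bin_size = 50, bin_pitch_um = 0.5) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("s", seq_len(nrow(counts)) - 1L, "_0")
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("g", seq_len(ncol(counts)))
  gx <- seq_len(nrow(counts)) - 1L
  coords <- data.table::data.table(
    spot_id = rownames(counts), gx = gx, gy = 0L,
    x_um = (gx + 0.5) * bin_size * bin_pitch_um,
    y_um = 0.5 * bin_size * bin_pitch_um)
  structure(list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                      "CsparseMatrix"),
                 coords = coords, bin_size = bin_size,
                 bin_pitch_um = bin_pitch_um, norm = NULL, norm_type = NULL),
            class = "bin_matrix")
}

# even-odd ray-casting point-in-polygon oracle (mgcv::in.out)
ray_cast_inside <- function(points, poly) {
  bnd <- rbind(poly, poly[1, ])
  mgcv::in.out(bnd, as.matrix(points))
}
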