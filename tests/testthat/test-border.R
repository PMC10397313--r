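# Geometry core: mask, contour, smoothing, signed distance, layers, tiles,
# spot assignment.

test_that("build_mask rasterizes hepatocyte centroids", {
  ann <- data.frame(x_um = 30, y_um = 30, cell_type = "hepatocyte")
  mask <- build_mask(ann, c(100, 100), pixel_um = 25)
  expect_equal(dim(mask$mask), c(4, 4))
  expect_equal(which(mask$mask == 1), 2 + 1 * 4) # pixel (2, 2) 1-based
  expect_error(build_mask(data.frame(x_um = 1, y_um = 1, cell_type = "B"),
                          c(100, 100)), "no hepatocyte")
  # checkerboard: foreground exactly where hepatocyte centroids fall
  xy <- expand.grid(px = 0:3, py = 0:3)
  keep <- (xy$px + xy$py) %% 2 == 0
  ann2 <- data.frame(x_um = xy$px[keep] * 25 + 12.5,
                     y_um = xy$py[keep] * 25 + 12.5,
                     cell_type = "hepatocyte")
  m2 <- build_mask(ann2, c(100, 100), 25)
  expected <- outer(0:3, 0:3, function(i, j) as.integer((i + j) %% 2 == 0))
  expect_equal(m2$mask, expected)
})

test_that("denoise_mask removes scatter and keeps the largest component", {
  m <- matrix(0L, 40, 40)
  m[5:40, 20:40] <- 1L       # large solid block
  m[2, 3] <- 1L              # isolated scatter pixel
  mask <- structure(list(mask = m, pixel_um = 25), class = "binary_mask")
  den <- denoise_mask(mask, window = 5, keep_fraction = 0.4)
  expect_equal(den$mask[2, 3], 0L)
  expect_gt(sum(den$mask), 0.9 * sum(m[5:40, 20:40]))
  expect_error(denoise_mask(structure(list(mask = matrix(0L, 10, 10),
                                           pixel_um = 25),
                                      class = "binary_mask")),
               "empty-mask")
  # two blobs: only the larger connected component survives
  m2 <- matrix(0L, 50, 50)
  m2[1:30, 1:20] <- 1L
  m2[45:50, 45:50] <- 1L
  den2 <- denoise_mask(structure(list(mask = m2, pixel_um = 25),
                                 class = "binary_mask"), 3, 0.3)
  expect_equal(sum(den2$mask[45:50, 45:50]), 0)
  expect_gt(sum(den2$mask[1:30, 1:20]), 0)
  expect_error(denoise_mask(mask, window = 4), "odd")
})

test_that("extract_contour recovers a known half-plane boundary", {
  m <- matrix(0L, 40, 40)
  m[, 21:40] <- 1L # foreground where y >= 500 um (pixel 25 um)
  mask <- structure(list(mask = m, pixel_um = 25), class = "binary_mask")
  ct <- extract_contour(mask)
  # boundary refined to the pixel edge at y = 500
  expect_lt(max(abs(ct[, 2] - 500)), 25)
  expect_equal(attr(ct, "interior_side") %in% c("left", "right"), TRUE)
  # full raster has no interior boundary
  full <- structure(list(mask = matrix(1L, 30, 30), pixel_um = 25),
                    class = "binary_mask")
  expect_error(extract_contour(full), "degenerate-border")
  # two components refuse
  m3 <- matrix(0L, 30, 30); m3[2:5, 2:5] <- 1L; m3[20:25, 20:25] <- 1L
  expect_error(extract_contour(structure(list(mask = m3, pixel_um = 25),
                                         class = "binary_mask")),
               "exactly one")
})

test_that("smooth_border reproduces straight lines and stays near endpoints", {
  s <- seq(0, 2000, by = 25)
  line <- cbind(s, 0.5 * s + 100)
  curve <- smooth_border(line, df = 10)
  V <- invasiveZone:::curve_vertices(curve)
  expect_lt(max(abs(V[, 2] - (0.5 * V[, 1] + 100))), 1e-6)
  expect_lt(sqrt(sum((V[1, ] - line[1, ])^2)), 25)
  expect_lt(sqrt(sum((V[nrow(V), ] - line[nrow(line), ])^2)), 25)
  expect_error(smooth_border(line[1:8, ], df = 10), "fewer than")
})

test_that("spline smoothing reduces contour noise against the truth curve", {
  set.seed(4)
  truth <- true_border_curve(border_spec(amplitude_um = 150, period_um = 3000,
                                         center_um = 1500), c(3000, 3000))
  x <- seq(0, 3000, by = 25)
  y_true <- 1500 + 150 * cos(2 * pi * x / 3000)
  noisy <- cbind(x, y_true + rnorm(length(x), 0, 10))
  sm <- smooth_border(noisy, df = 8)
  rms <- function(pts) sqrt(mean(signed_distance(truth, pts)$d_um^2))
  expect_lt(rms(invasiveZone:::curve_vertices(sm)), rms(noisy))
})

test_that("signed_distance matches closed forms and a brute-force oracle", {
  straight <- border_curve(cbind(seq(0, 1000, 5), 0))
  on_curve <- signed_distance(straight, cbind(500, 0))
  expect_equal(on_curve$d_um, 0, tolerance = 1e-9)
  above <- signed_distance(straight, cbind(300, 100))
  expect_equal(above$d_um, 100, tolerance = 1e-9) # left of travel = positive
  expect_equal(above$s_um, 300, tolerance = 1e-6)
  below <- signed_distance(straight, cbind(300, -50))
  expect_equal(below$d_um, -50, tolerance = 1e-9)

  curve <- true_border_curve(border_spec(amplitude_um = 300, period_um = 4000,
                                         center_um = 2000), c(4000, 4000))
  set.seed(2)
  pts <- cbind(runif(1000, 0, 4000), runif(1000, 0, 4000))
  d <- signed_distance(curve, pts)$d_um
  dense <- invasiveZone:::resample_polyline(cbind(curve$x, curve$y), 0.25)
  d_bf <- vapply(seq_len(nrow(pts)), function(i) {
    min(sqrt((dense[, 1] - pts[i, 1])^2 + (dense[, 2] - pts[i, 2])^2))
  }, numeric(1))
  expect_lt(max(abs(abs(d) - d_bf)), 2.5)
})

test_that("build_layers produces exact bands for a straight border", {
  curve <- border_curve(cbind(seq(0, 10000, 5), 5000))
  ls <- build_layers(curve, c(10000, 10000))
  expect_length(ls$bands, 8)
  for (lab in c("-3", "-2", "-1", "+1", "+2", "+3"))
    expect_equal(ls$areas[[lab]], 250 * 10000, tolerance = 1e-3)
  # distant bands: only points with |d| in [2000, 2250]
  expect_equal(ls$areas[["distant+"]], 250 * 10000, tolerance = 1e-3)
  b <- ls$bands[["+1"]]
  expect_equal(range(b[, 2]), c(5000, 5250), tolerance = 1e-6)
  bd <- ls$bands[["distant-"]]
  expect_equal(range(bd[, 2]), c(5000 - 2250, 5000 - 2000), tolerance = 1e-6)
})

test_that("band membership satisfies the signed-distance invariant", {
  curve <- true_border_curve(border_spec(amplitude_um = 500, period_um = 5000),
                             c(10000, 10000))
  ls <- build_layers(curve, c(10000, 10000))
  set.seed(8)
  pts <- cbind(runif(10000, 100, 9900), runif(10000, 100, 9900))
  d <- signed_distance(curve, pts)$d_um
  lab <- layer_from_distance(d)
  for (band in c("-2", "+1", "+3")) {
    # sampled points of the band (excluding a 1% fringe) lie in its polygon
    w <- 250
    lo <- (abs(as.integer(band)) - 1) * w; hi <- abs(as.integer(band)) * w
    core <- lab == band & abs(abs(d) - lo) > 0.01 * w & abs(abs(d) - hi) > 0.01 * w
    inside <- ray_cast_inside(pts[core, , drop = FALSE], ls$bands[[band]])
    expect_gt(mean(inside), 0.999)
  }
})

test_that("curvature beyond the offset radius raises an error", {
  tight <- true_border_curve(border_spec(amplitude_um = 700, period_um = 2500,
                                         center_um = 2000), c(4000, 4000))
  expect_error(build_layers(tight, c(4000, 4000)), "curvature error")
})

test_that("tile_layer cuts equal-area tiles ordered along the border", {
  straight <- border_curve(cbind(seq(0, 10000, 5), 5000))
  tl <- tile_layer(straight, 0, 250, 100, c(10000, 10000))
  expect_length(tl$polys, 100)
  expect_equal(sd(tl$info$area), 0, tolerance = 1e-6)
  expect_equal(sum(tl$info$area), 250 * 10000, tolerance = 1e-3)
  expect_true(all(diff(tl$info$s0) > 0))
  # single tile = the band itself
  t1 <- tile_layer(straight, 0, 250, 1, c(10000, 10000))
  expect_equal(t1$info$area, 250 * 10000, tolerance = 1e-3)

  sin_curve <- true_border_curve(border_spec(amplitude_um = 500,
                                             period_um = 5000),
                                 c(10000, 10000))
  tl2 <- tile_layer(sin_curve, -500, -750, 100, c(10000, 10000))
  a <- tl2$info$area[!tl2$info$empty]
  expect_lt(sd(a) / mean(a), 0.10)
  band_area <- polygon_area(build_layers(sin_curve,
                                         c(10000, 10000))$bands[["-3"]])
  expect_equal(sum(tl2$info$area), band_area, tolerance = 2e-3)
})

test_that("assign_spots implements the cross-product rule with the tie-break", {
  straight <- border_curve(cbind(seq(0, 1000, 5), 1000))
  model <- border_model_from_curve(straight, c(1000, 3500), n_tiles = 10)
  # tile width 100 um; spot at the center of (+1, tile 4)
  asn <- assign_spots(data.frame(spot_id = "a", x_um = 350, y_um = 1100), model)
  expect_equal(asn$layer, "+1")
  expect_equal(asn$tile, 4L)
  # spot exactly on the shared edge between tiles 3 and 4 -> lower index
  edge <- assign_spots(data.frame(spot_id = "e", x_um = 300, y_um = 1100), model)
  expect_equal(edge$tile, 3L)
  # outside all layers / in the distant band
  far <- assign_spots(data.frame(spot_id = "f", x_um = 500, y_um = 2900), model)
  expect_equal(far$layer, "none")
  expect_true(is.na(far$tile))
  dst <- assign_spots(data.frame(spot_id = "d", x_um = 500, y_um = 3100), model)
  expect_equal(dst$layer, "distant+")
})

test_that("assignment agrees with an even-odd ray-casting oracle", {
  model <- fx_model()
  set.seed(12)
  pts <- data.frame(spot_id = sprintf("p%04d", 1:10000),
                    x_um = runif(10000, 0, 3000),
                    y_um = runif(10000, 0, 3000))
  asn <- assign_spots(pts, model)
  info <- model$tiles$info
  oracle_layer <- rep(NA_character_, nrow(pts))
  oracle_tile <- rep(NA_integer_, nrow(pts))
  P <- cbind(pts$x_um, pts$y_um)
  for (lab in c("-3", "-2", "-1", "+1", "+2", "+3")) {
    for (t in seq_len(100)) {
      poly <- model$tiles$tiles[[lab]][[t]]
      if (nrow(poly) < 3) next
      undecided <- is.na(oracle_tile)
      if (!any(undecided)) break
      hit <- ray_cast_inside(P[undecided, , drop = FALSE], poly)
      idx <- which(undecided)[hit]
      oracle_layer[idx] <- lab
      oracle_tile[idx] <- t
    }
  }
  ours <- paste(asn$layer, asn$tile)
  theirs <- paste(oracle_layer, oracle_tile)
  has_tile <- !is.na(asn$tile) | !is.na(oracle_tile)
  agree <- ours[has_tile] == theirs[has_tile]
  expect_gte(mean(agree), 0.999)
  # any residual disagreement sits within a micron of a tile boundary
  if (any(!agree)) {
    d <- asn$d_um[has_tile][!agree]
    frac <- pmin(abs(d) %% 250, 250 - abs(d) %% 250)
    expect_true(all(frac < 1 | is.na(asn$tile[has_tile][!agree]) !=
                      is.na(oracle_tile[has_tile][!agree])))
  }
})

test_that("assigned layers equal the signed-distance rule and are deterministic", {
  asn <- fx_asn()
  expect_equal(asn$layer,
               layer_from_distance(asn$d_um))
  asn2 <- assign_spots(fx_ann(), fx_model())
  expect_identical(data.frame(asn), data.frame(asn2))
  # no spot appears twice
  expect_equal(anyDuplicated(asn$spot_id), 0)
})

test_that("the recovered border tracks the truth curve within two pixels RMS", {
  sl <- fx_slide()
  model <- fx_model()
  d <- signed_distance(sl$curve, invasiveZone:::curve_vertices(model$curve))$d_um
  expect_lt(sqrt(mean(d^2)), 50) # 2 x 25 um pixels
})

test_that("tiles within a layer are interior-disjoint", {
  model <- fx_model()
  polys <- model$tiles$tiles[["-1"]]
  set.seed(3)
  pts <- cbind(runif(2000, 0, 3000), runif(2000, 0, 3000))
  hits <- matrix(FALSE, nrow(pts), 20)
  for (t in 1:20) { # enough tiles to detect systematic overlap
    poly <- polys[[t]]
    if (nrow(poly) < 3) next
    # shrink test points away from shared edges by 1 um to avoid boundary hits
    hits[, t] <- ray_cast_inside(pts, poly)
  }
  multi <- rowSums(hits)
  expect_lte(max(multi), 1)
})
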