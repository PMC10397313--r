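# Border scanning-and-digitization model (SDM): hepatocyte mask -> contour ->
# spline-smoothed border -> offset-curve layers -> equal-area tangential
# tiles -> spot assignment.

#' Resample a polyline to (at most) a given vertex spacing
#' @param xy n x 2 matrix of vertices.
#' @param spacing_um target spacing (default 5).
#' @return m x 2 matrix with uniform spacing <= `spacing_um`.
#' @keywords internal
resample_polyline <- function(xy, spacing_um = 5) {
  seg <- sqrt(rowSums(diff(xy)^2))
  keep <- c(TRUE, seg > 1e-9)
  xy <- xy[keep, , drop = FALSE]
  s <- c(0, cumsum(sqrt(rowSums(diff(xy)^2))))
  L <- s[length(s)]
  if (L <= 0) stop("polyline has zero length", call. = FALSE)
  n_out <- max(2L, ceiling(L / spacing_um) + 1L)
  s_out <- seq(0, L, length.out = n_out)
  cbind(stats::approx(s, xy[, 1], xout = s_out)$y,
        stats::approx(s, xy[, 2], xout = s_out)$y)
}

#' Construct a border curve object
#'
#' A border curve is an ordered vertex list with an arc-length
#' parameterization, oriented so that its left-hand normal points to the
#' paratumor (hepatocyte) side; signed distances are positive on that side.
#'
#' @param xy n x 2 matrix of vertices in um, ordered along the border.
#' @param spacing_um resampling spacing (default 5 um).
#' @return a `border_curve`: list with `x`, `y`, `s` (arc length), `L`.
#' @export
border_curve <- function(xy, spacing_um = 5) {
  xy <- resample_polyline(as.matrix(xy), spacing_um)
  s <- c(0, cumsum(sqrt(rowSums(diff(xy)^2))))
  structure(list(x = xy[, 1], y = xy[, 2], s = s, L = s[length(s)],
                 spacing_um = spacing_um),
            class = "border_curve")
}

#' @export
print.border_curve <- function(x, ...) {
  cat(sprintf("border_curve: %d vertices, length %.0f um\n", length(x$x), x$L))
  invisible(x)
}

curve_vertices <- function(curve) cbind(curve$x, curve$y)

# Unit left-hand normals at curve vertices (central differences).
curve_normals <- function(curve) {
  x <- curve$x; y <- curve$y; n <- length(x)
  ix <- c(2:n, n); im <- c(1, 1:(n - 1))
  tx <- x[ix] - x[im]; ty <- y[ix] - y[im]
  len <- sqrt(tx^2 + ty^2)
  cbind(-ty / len, tx / len)
}

# Signed curvature at vertices (positive bending toward the left normal).
curve_curvature <- function(curve) {
  x <- curve$x; y <- curve$y; n <- length(x)
  ix <- c(2:n, n); im <- c(1, 1:(n - 1))
  ds <- (curve$s[ix] - curve$s[im])
  dx <- (x[ix] - x[im]) / ds; dy <- (y[ix] - y[im]) / ds
  ddx <- (dx[ix] - dx[im]) / ds; ddy <- (dy[ix] - dy[im]) / ds
  (dx * ddy - dy * ddx) / (dx^2 + dy^2)^1.5
}

#' Signed distance from points to a border curve
#'
#' Minimum Euclidean distance from each point to the curve, signed positive on
#' the curve's left-hand (paratumor) side, together with the arc-length
#' position of the nearest curve point (the foot of the normal). Nearest
#' vertices are located with a coarse-to-fine search, then refined by
#' projection onto the adjacent segments.
#'
#' @param curve a `border_curve`.
#' @param points n x 2 matrix or data.frame of (x, y) in um.
#' @return data.frame with columns `d_um` (signed) and `s_um`.
#' @export
signed_distance <- function(curve, points) {
  P <- as.matrix(points)[, 1:2, drop = FALSE]
  V <- curve_vertices(curve)
  nv <- nrow(V)
  np <- nrow(P)
  k <- max(1L, as.integer(round(25 / curve$spacing_um)))
  coarse_idx <- unique(c(seq(1L, nv, by = k), nv))
  C <- V[coarse_idx, , drop = FALSE]
  nearest <- integer(np)
  chunk <- 4096L
  for (lo in seq(1L, np, by = chunk)) {
    hi <- min(lo + chunk - 1L, np)
    px <- P[lo:hi, 1]; py <- P[lo:hi, 2]
    d2 <- outer(px, C[, 1], "-")^2 + outer(py, C[, 2], "-")^2
    nearest[lo:hi] <- coarse_idx[max.col(-d2, ties.method = "first")]
  }
  # refine within +-2k vertices of the coarse hit
  w <- (-2L * k):(2L * k)
  refine <- matrix(pmin(pmax(outer(nearest, w, "+"), 1L), nv), nrow = np)
  dx <- matrix(V[refine, 1], nrow = np) - P[, 1]
  dy <- matrix(V[refine, 2], nrow = np) - P[, 2]
  iv <- refine[cbind(seq_len(np), max.col(-(dx^2 + dy^2), ties.method = "first"))]
  # project onto the two segments adjacent to the nearest vertex
  best_d2 <- rep(Inf, np); best_s <- numeric(np); best_sign <- numeric(np)
  for (side in c(-1L, 0L)) {
    a_idx <- pmin(pmax(iv + side, 1L), nv - 1L)
    b_idx <- a_idx + 1L
    ax <- V[a_idx, 1]; ay <- V[a_idx, 2]
    bx <- V[b_idx, 1]; by <- V[b_idx, 2]
    ex <- bx - ax; ey <- by - ay
    el2 <- ex^2 + ey^2
    t <- pmin(pmax(((P[, 1] - ax) * ex + (P[, 2] - ay) * ey) / el2, 0), 1)
    qx <- ax + t * ex; qy <- ay + t * ey
    d2 <- (P[, 1] - qx)^2 + (P[, 2] - qy)^2
    cr <- ex * (P[, 2] - ay) - ey * (P[, 1] - ax)
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_s[upd] <- curve$s[a_idx[upd]] + t[upd] * sqrt(el2[upd])
    best_sign[upd] <- sign(cr[upd])
  }
  best_sign[best_sign == 0] <- 1
  data.frame(d_um = best_sign * sqrt(best_d2), s_um = best_s)
}

# ---- binary mask ------------------------------------------------------------

#' Rasterize predicted hepatocytes into a binary mask
#'
#' Foreground pixels are those containing at least one spot annotated as
#' hepatocyte. The raster covers the full slide extent with square pixels.
#'
#' @param annotation data.frame with `x_um`, `y_um`, `cell_type`.
#' @param slide_extent_um numeric length-2 slide (width, height) in um.
#' @param pixel_um pixel edge in um (default 25, one bin50 spot).
#' @return a `binary_mask`: list with `mask` (nx x ny 0/1 matrix, first index
#'   x), `pixel_um`.
#' @export
build_mask <- function(annotation, slide_extent_um, pixel_um = 25) {
  assert_cols(annotation, c("x_um", "y_um", "cell_type"), "annotation")
  hep <- annotation[annotation$cell_type == "hepatocyte", , drop = FALSE]
  if (nrow(hep) == 0) stop("empty-mask error: no hepatocyte spots", call. = FALSE)
  nx <- ceiling(slide_extent_um[1] / pixel_um)
  ny <- ceiling(slide_extent_um[2] / pixel_um)
  px <- pmin(pmax(floor(hep$x_um / pixel_um), 0), nx - 1) + 1L
  py <- pmin(pmax(floor(hep$y_um / pixel_um), 0), ny - 1) + 1L
  m <- matrix(0L, nx, ny)
  m[cbind(px, py)] <- 1L
  structure(list(mask = m, pixel_um = pixel_um), class = "binary_mask")
}

#' Denoise a binary mask by window thresholding
#'
#' A pixel is foreground after denoising iff the foreground fraction in its
#' `window` x `window` neighborhood is at least `keep_fraction` (this both
#' removes scattered signals and fills sparse tissue into a solid region);
#' afterwards only the largest connected foreground component (the bulk
#' paratumor liver tissue) is retained.
#'
#' @param mask a `binary_mask`.
#' @param window odd window size in pixels (default 5).
#' @param keep_fraction minimum foreground fraction (default 0.4).
#' @return a `binary_mask`.
#' @export
denoise_mask <- function(mask, window = 5, keep_fraction = 0.4) {
  if (window %% 2 != 1) stop("window must be odd", call. = FALSE)
  kern <- matrix(1 / window^2, window, window)
  frac <- EBImage::filter2(EBImage::Image(mask$mask), kern, boundary = "replicate")
  m <- matrix(as.integer(EBImage::imageData(frac) >= keep_fraction - 1e-9),
              nrow(mask$mask), ncol(mask$mask))
  if (!any(m == 1L)) stop("empty-mask error: all pixels removed", call. = FALSE)
  lab <- EBImage::bwlabel(EBImage::Image(m))
  labs <- EBImage::imageData(lab)
  tab <- tabulate(labs[labs > 0])
  keep <- which.max(tab)
  m <- matrix(as.integer(labs == keep), nrow(m), ncol(m))
  structure(list(mask = m, pixel_um = mask$pixel_um), class = "binary_mask")
}

#' Extract the raw border polyline from a single-component mask
#'
#' Marches the ordered boundary of the foreground component, converts pixel
#' indices to um at pixel centers, removes the portion running along the slide
#' edge, and returns the longest remaining run as an open polyline. The side
#' of the polyline on which the mask interior (hepatocyte tissue) lies is
#' recorded in the `interior_side` attribute ("left" or "right" of the
#' direction of travel).
#'
#' @param mask a `binary_mask` with exactly one foreground component.
#' @return an open polyline (n x 2 matrix, um) with attribute `interior_side`.
#' @export
extract_contour <- function(mask) {
  m <- mask$mask
  lab <- EBImage::bwlabel(EBImage::Image(m))
  ncomp <- max(EBImage::imageData(lab))
  if (ncomp != 1)
    stop("mask must have exactly one foreground component (found ", ncomp, ")",
         call. = FALSE)
  oc <- EBImage::ocontour(lab)[[1]] # 0-based (x, y) pixel indices, closed walk
  nx <- nrow(m); ny <- ncol(m)
  on_edge <- oc[, 1] <= 0 | oc[, 1] >= nx - 1 | oc[, 2] <= 0 | oc[, 2] >= ny - 1
  if (all(on_edge))
    stop("degenerate-border error: contour lies entirely on the slide edge",
         call. = FALSE)
  keep <- !on_edge
  # longest contiguous run of kept points in circular order
  n <- length(keep)
  if (all(keep)) {
    run_idx <- seq_len(n)
  } else {
    # rotate so the walk starts at a dropped point, then take the longest run
    start <- which(!keep)[1]
    ord <- c(start:n, seq_len(start - 1L))
    kr <- rle(keep[ord])
    ends <- cumsum(kr$lengths)
    starts <- ends - kr$lengths + 1L
    best <- which(kr$values)[which.max(kr$lengths[kr$values])]
    run_idx <- ord[starts[best]:ends[best]]
  }
  pts <- (oc[run_idx, , drop = FALSE] + 0.5) * mask$pixel_um
  if (nrow(pts) < 5)
    stop("degenerate-border error: border polyline too short", call. = FALSE)
  # probe which side of travel the mask interior lies on, at several stations
  mid_ids <- unique(pmax(2L, pmin(nrow(pts) - 1L,
    round(seq(0.2, 0.8, length.out = 7) * nrow(pts)))))
  votes <- vapply(mid_ids, function(i) {
    tx <- pts[i + 1L, 1] - pts[i - 1L, 1]; ty <- pts[i + 1L, 2] - pts[i - 1L, 2]
    len <- sqrt(tx^2 + ty^2)
    if (len == 0) return(0)
    probe_val <- function(q) {
      ii <- floor(q[1] / mask$pixel_um) + 1L; jj <- floor(q[2] / mask$pixel_um) + 1L
      if (ii < 1 || ii > nx || jj < 1 || jj > ny) return(0L)
      m[ii, jj]
    }
    left <- probe_val(pts[i, ] + 2 * mask$pixel_um * c(-ty, tx) / len)
    right <- probe_val(pts[i, ] - 2 * mask$pixel_um * c(-ty, tx) / len)
    left - right
  }, numeric(1))
  side <- if (sum(votes) >= 0) "left" else "right"
  # sub-pixel refinement: contour vertices are centers of boundary foreground
  # pixels; the region boundary runs along their outer edge, half a pixel
  # toward the background side
  npts <- nrow(pts)
  ix <- c(2:npts, npts); im <- c(1, 1:(npts - 1))
  tx <- pts[ix, 1] - pts[im, 1]; ty <- pts[ix, 2] - pts[im, 2]
  tl <- pmax(sqrt(tx^2 + ty^2), 1e-9)
  outward <- if (side == "left") -1 else 1
  pts <- pts + outward * (mask$pixel_um / 2) * cbind(-ty / tl, tx / tl)
  structure(pts, interior_side = side)
}

#' Smooth a raw border polyline by spline fitting
#'
#' Fits x(s) and y(s) with smoothing splines of `df` degrees of freedom on the
#' chord-length parameter, resamples the smoothed curve at <= 5 um spacing,
#' and orients it so the hepatocyte (paratumor) side is the left-hand /
#' signed-positive side.
#'
#' @param polyline n x 2 matrix (um), optionally with the `interior_side`
#'   attribute set by [extract_contour()].
#' @param df spline degrees of freedom (default 20).
#' @param spacing_um output vertex spacing (default 5).
#' @return a `border_curve`.
#' @export
smooth_border <- function(polyline, df = 20, spacing_um = 5) {
  pts <- as.matrix(polyline)
  if (nrow(pts) < df + 4)
    stop("polyline has fewer than df + 4 vertices", call. = FALSE)
  s <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  fx <- stats::smooth.spline(s, pts[, 1], df = df)
  fy <- stats::smooth.spline(s, pts[, 2], df = df)
  s_fine <- seq(0, s[length(s)], length.out = max(512L, length(s)))
  sm <- cbind(stats::predict(fx, s_fine)$y, stats::predict(fy, s_fine)$y)
  if (identical(attr(polyline, "interior_side"), "right")) sm <- sm[rev(seq_len(nrow(sm))), ]
  curve <- border_curve(sm, spacing_um = spacing_um)
  if (curve_self_intersects(curve))
    stop("smoothed border self-intersects; apply local segmentation and/or ",
         "rotation of the input region and re-fit", call. = FALSE)
  curve
}

# Approximate self-intersection test on a decimated copy of the curve.
curve_self_intersects <- function(curve, max_segments = 300L) {
  V <- curve_vertices(curve)
  idx <- unique(round(seq(1, nrow(V), length.out = min(max_segments + 1L, nrow(V)))))
  V <- V[idx, , drop = FALSE]
  n <- nrow(V) - 1L
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
    d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
    d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
    d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2L)) {
    for (j in seq(i + 2L, n)) {
      if (seg_int(V[i, ], V[i + 1L, ], V[j, ], V[j + 1L, ])) return(TRUE)
    }
  }
  FALSE
}

# ---- offset curves, layers, tiles ------------------------------------------

#' Offset a border curve along its normals
#'
#' Normal displacement of every vertex by `d` um (positive toward the
#' paratumor side), with pruning of locally inverted vertices where the
#' offset would fold back on itself (offset distance beyond the local radius
#' of curvature).
#'
#' @param curve a `border_curve`.
#' @param d signed offset in um.
#' @return m x 2 matrix of offset vertices (m <= number of curve vertices).
#' @export
offset_curve <- function(curve, d) {
  V <- curve_vertices(curve)
  N <- curve_normals(curve)
  O <- V + d * N
  if (d == 0) return(O)
  for (pass in 1:2) {
    if (nrow(O) < 3) break
    dV <- diff(V); dO <- diff(O)
    fwd <- rowSums(dV * dO) > 0
    keep <- c(TRUE, fwd) & c(fwd, TRUE)
    if (all(keep)) break
    O <- O[keep, , drop = FALSE]
    V <- V[keep, , drop = FALSE]
  }
  O
}

#' Build the six-layer band set around a border
#'
#' Offset curves are generated at 0, +-250, +-500, +-750 um (and at the
#' distant band boundaries) by normal displacement; consecutive offsets bound
#' the six 250 um bands, indexed -3..-1 (tumor side) and +1..+3 (paratumor
#' side). Bands are clipped to the slide rectangle. Band membership for
#' arbitrary points is defined by signed distance; the polygons expose the
#' same geometry for area computation and export.
#'
#' @param curve a `border_curve`.
#' @param slide_extent_um slide (width, height) in um.
#' @param half_widths offsets bounding the layers (default c(250, 500, 750)).
#' @param distant_um distant reference band (default c(2000, 2250)).
#' @param max_curvature_violation maximum tolerated arc fraction whose radius
#'   of curvature is below the outermost layer offset (default 0.05).
#' @return a `layer_set`: list with `bands` (named list of polygons), `areas`,
#'   `half_widths`, `distant_um`, `curve`.
#' @export
build_layers <- function(curve, slide_extent_um,
                         half_widths = c(250, 500, 750),
                         distant_um = c(2000, 2250),
                         max_curvature_violation = 0.05) {
  stopifnot(length(half_widths) >= 1, all(diff(half_widths) > 0))
  kappa <- curve_curvature(curve)
  radius <- 1 / pmax(abs(kappa), 1e-12)
  frac_bad <- mean(radius < max(half_widths))
  if (frac_bad > max_curvature_violation)
    stop(sprintf(paste0("curvature error: %.0f%% of the border has radius of ",
                        "curvature below %g um; offsets would self-intersect"),
                 100 * frac_bad, max(half_widths)), call. = FALSE)
  bounds <- c(0, half_widths)
  xlim <- c(0, slide_extent_um[1]); ylim <- c(0, slide_extent_um[2])
  bands <- list()
  for (side in c(-1, 1)) {
    for (l in seq_along(half_widths)) {
      o_in <- offset_curve(curve, side * bounds[l])
      o_out <- offset_curve(curve, side * bounds[l + 1])
      poly <- clip_polygon_rect(rbind(o_in, o_out[rev(seq_len(nrow(o_out))), ]),
                                xlim, ylim)
      lab <- paste0(if (side > 0) "+" else "-", l)
      bands[[lab]] <- poly
    }
    o_in <- offset_curve(curve, side * distant_um[1])
    o_out <- offset_curve(curve, side * distant_um[2])
    poly <- clip_polygon_rect(rbind(o_in, o_out[rev(seq_len(nrow(o_out))), ]),
                              xlim, ylim)
    bands[[if (side > 0) "distant+" else "distant-"]] <- poly
  }
  areas <- vapply(bands, function(p) if (nrow(p) >= 3) polygon_area(p) else 0,
                  numeric(1))
  structure(list(bands = bands, areas = areas, half_widths = half_widths,
                 distant_um = distant_um, curve = curve,
                 slide_extent_um = slide_extent_um),
            class = "layer_set")
}

#' Segment one layer band into tangential tiles of approximately equal area
#'
#' The cumulative band area is accumulated along the arc at the curve's
#' vertex resolution (<= 5 um); cut lines are placed along local normals at
#' the arc positions of equal-cumulative-area quantiles, yielding `n_tiles`
#' simple polygons ordered along the border.
#'
#' @param curve a `border_curve`.
#' @param d0,d1 signed offsets bounding the band (um), `|d0| < |d1|`.
#' @param n_tiles number of tiles (default 100).
#' @param slide_extent_um slide (width, height) for clipping.
#' @return list with `polys` (list of n_tiles polygons) and `info`
#'   (data.frame: tile, area, s0, s1).
#' @export
tile_layer <- function(curve, d0, d1, n_tiles = 100, slide_extent_um) {
  V <- curve_vertices(curve); N <- curve_normals(curve)
  o_in <- V + d0 * N
  o_out <- V + d1 * N
  n <- nrow(V)
  quad_area <- abs(
    (o_in[-n, 1] * o_in[-1, 2] - o_in[-1, 1] * o_in[-n, 2]) +
    (o_in[-1, 1] * o_out[-1, 2] - o_out[-1, 1] * o_in[-1, 2]) +
    (o_out[-1, 1] * o_out[-n, 2] - o_out[-n, 1] * o_out[-1, 2]) +
    (o_out[-n, 1] * o_in[-n, 2] - o_in[-n, 1] * o_out[-n, 2])) / 2
  # strips leaving the slide rectangle contribute only their clipped area, so
  # equal-area cuts partition the in-slide band area
  in_x <- range(0, slide_extent_um[1]); in_y <- range(0, slide_extent_um[2])
  strip_out <- which(
    pmin(o_in[-n, 1], o_in[-1, 1], o_out[-n, 1], o_out[-1, 1]) < in_x[1] |
    pmax(o_in[-n, 1], o_in[-1, 1], o_out[-n, 1], o_out[-1, 1]) > in_x[2] |
    pmin(o_in[-n, 2], o_in[-1, 2], o_out[-n, 2], o_out[-1, 2]) < in_y[1] |
    pmax(o_in[-n, 2], o_in[-1, 2], o_out[-n, 2], o_out[-1, 2]) > in_y[2])
  for (i in strip_out) {
    quad <- rbind(o_in[i, ], o_in[i + 1, ], o_out[i + 1, ], o_out[i, ])
    cq <- clip_polygon_rect(quad, in_x, in_y)
    quad_area[i] <- if (nrow(cq) >= 3) polygon_area(cq) else 0
  }
  cumA <- c(0, cumsum(quad_area))
  total <- cumA[length(cumA)]
  if (total <= 0) stop("geometry error: band has zero area", call. = FALSE)
  targets <- total * seq_len(n_tiles - 1) / n_tiles
  cut_at <- function(A) {
    i <- findInterval(A, cumA, rightmost.closed = TRUE)
    i <- min(max(i, 1L), n - 1L)
    f <- (A - cumA[i]) / max(cumA[i + 1] - cumA[i], 1e-12)
    list(inner = o_in[i, ] + f * (o_in[i + 1, ] - o_in[i, ]),
         outer = o_out[i, ] + f * (o_out[i + 1, ] - o_out[i, ]),
         s = curve$s[i] + f * (curve$s[i + 1] - curve$s[i]),
         idx = i, f = f)
  }
  cuts <- lapply(targets, cut_at)
  s_bounds <- c(0, vapply(cuts, `[[`, numeric(1), "s"), curve$L)
  xlim <- c(0, slide_extent_um[1]); ylim <- c(0, slide_extent_um[2])
  polys <- vector("list", n_tiles)
  info_area <- numeric(n_tiles)
  lo_idx <- 1L; lo_f <- 0
  lo_inner <- o_in[1, ]; lo_outer <- o_out[1, ]
  for (t in seq_len(n_tiles)) {
    if (t < n_tiles) {
      hi <- cuts[[t]]
    } else {
      hi <- list(inner = o_in[n, ], outer = o_out[n, ], s = curve$L,
                 idx = n - 1L, f = 1)
    }
    mid <- if (hi$idx >= lo_idx + 1L) seq(lo_idx + 1L, hi$idx) else integer(0)
    poly <- rbind(lo_inner, o_in[mid, , drop = FALSE], hi$inner,
                  hi$outer, o_out[rev(mid), , drop = FALSE], lo_outer)
    poly <- clip_polygon_rect(poly, xlim, ylim)
    if (nrow(poly) < 3) {
      # tile swallowed by the slide boundary (band edge leaves the slide):
      # kept as an empty placeholder so tile indices stay aligned along s
      polys[[t]] <- matrix(numeric(0), 0, 2)
      info_area[t] <- 0
    } else {
      polys[[t]] <- poly
      info_area[t] <- polygon_area(poly)
    }
    lo_idx <- hi$idx; lo_inner <- hi$inner; lo_outer <- hi$outer
  }
  list(polys = polys,
       info = data.frame(tile = seq_len(n_tiles), area = info_area,
                         empty = info_area == 0,
                         s0 = s_bounds[-length(s_bounds)], s1 = s_bounds[-1]))
}

#' Build the full tile set over the six layers
#' @param layers a `layer_set`.
#' @param n_tiles tiles per layer (default 100).
#' @return a `tile_set`: list with `tiles` (named list of per-layer polygon
#'   lists) and `info` (data.frame: layer, tile, area, s0, s1).
#' @export
tile_layers <- function(layers, n_tiles = 100) {
  bounds <- c(0, layers$half_widths)
  tiles <- list(); info <- list()
  for (side in c(-1, 1)) {
    for (l in seq_along(layers$half_widths)) {
      lab <- paste0(if (side > 0) "+" else "-", l)
      tl <- tile_layer(layers$curve, side * bounds[l], side * bounds[l + 1],
                       n_tiles = n_tiles,
                       slide_extent_um = layers$slide_extent_um)
      tiles[[lab]] <- tl$polys
      info[[lab]] <- data.frame(layer = lab, tl$info)
    }
  }
  structure(list(tiles = tiles, info = do.call(rbind, info),
                 n_tiles = n_tiles),
            class = "tile_set")
}

#' Assemble the complete border model from an annotation
#'
#' Convenience wrapper chaining [build_mask()], [denoise_mask()],
#' [extract_contour()], [smooth_border()], [build_layers()] and
#' [tile_layers()].
#'
#' @param annotation per-spot annotation with `x_um`, `y_um`, `cell_type`.
#' @param slide_extent_um slide (width, height) in um.
#' @param pixel_um mask pixel size (default 25).
#' @param window,keep_fraction denoising parameters (defaults 5, 0.4).
#' @param df spline degrees of freedom (default 20).
#' @param half_widths,distant_um layer geometry (defaults c(250,500,750),
#'   c(2000,2250)).
#' @param n_tiles tiles per layer (default 100).
#' @return a `border_model`: list with `curve`, `layers`, `tiles`, `params`.
#' @export
build_border_model <- function(annotation, slide_extent_um, pixel_um = 25,
                               window = 5, keep_fraction = 0.4, df = 20,
                               half_widths = c(250, 500, 750),
                               distant_um = c(2000, 2250), n_tiles = 100) {
  mask <- build_mask(annotation, slide_extent_um, pixel_um)
  mask <- denoise_mask(mask, window, keep_fraction)
  contour <- extract_contour(mask)
  curve <- smooth_border(contour, df = df)
  layers <- build_layers(curve, slide_extent_um, half_widths, distant_um)
  tiles <- tile_layers(layers, n_tiles)
  structure(list(curve = curve, layers = layers, tiles = tiles,
                 params = list(pixel_um = pixel_um, window = window,
                               keep_fraction = keep_fraction, df = df,
                               half_widths = half_widths,
                               distant_um = distant_um, n_tiles = n_tiles)),
            class = "border_model")
}

#' Border model from a known curve
#'
#' Builds layers and tiles directly from a given border curve, bypassing mask
#' extraction (used with ground-truth curves or externally drawn borders).
#' @param curve a `border_curve`.
#' @inheritParams build_border_model
#' @return a `border_model`.
#' @export
border_model_from_curve <- function(curve, slide_extent_um,
                                    half_widths = c(250, 500, 750),
                                    distant_um = c(2000, 2250), n_tiles = 100) {
  layers <- build_layers(curve, slide_extent_um, half_widths, distant_um)
  tiles <- tile_layers(layers, n_tiles)
  structure(list(curve = curve, layers = layers, tiles = tiles,
                 params = list(half_widths = half_widths,
                               distant_um = distant_um, n_tiles = n_tiles)),
            class = "border_model")
}

#' Assign spots to layers and tangential tiles
#'
#' Layers are assigned from the signed distance to the border
#' (`ceil(|d|/width)` with the sign giving the side); within the six tiled
#' layers, the containing tile is determined by the sign of the cross (outer)
#' products of the spot centroid against each tile edge (fan-decomposed for
#' near-quadrilateral tiles). Boundary spots are given to the lowest
#' (layer, tile) index. Spots outside all layers get `distant-`/`distant+` or
#' `none` from their signed distance.
#'
#' @param spots data.frame with `spot_id`, `x_um`, `y_um`.
#' @param model a `border_model`.
#' @return data.table: spot_id, x_um, y_um, d_um, s_um, layer, tile (integer
#'   or NA).
#' @export
assign_spots <- function(spots, model) {
  assert_cols(spots, c("spot_id", "x_um", "y_um"), "spots")
  ds <- signed_distance(model$curve, cbind(spots$x_um, spots$y_um))
  width <- diff(c(0, model$params$half_widths))[1]
  n_layers <- length(model$params$half_widths)
  layer <- layer_from_distance(ds$d_um, layer_width_um = width,
                               n_layers = n_layers,
                               distant_um = model$params$distant_um)
  tile <- rep(NA_integer_, nrow(spots))
  info <- model$tiles$info
  for (lab in names(model$tiles$tiles)) {
    in_layer <- which(layer == lab)
    if (!length(in_layer)) next
    li <- info[info$layer == lab, ]
    polys <- model$tiles$tiles[[lab]]
    nt <- length(polys)
    cand0 <- findInterval(ds$s_um[in_layer], c(li$s0, Inf),
                          rightmost.closed = FALSE)
    cand0 <- pmin(pmax(cand0, 1L), nt)
    for (k in seq_along(in_layer)) {
      i <- in_layer[k]
      pt <- c(spots$x_um[i], spots$y_um[i])
      found <- NA_integer_
      for (t in unique(pmin(pmax(cand0[k] + c(-1L, 0L, 1L), 1L), nt))) {
        if (point_in_poly_cross(pt, polys[[t]])) { found <- t; break }
      }
      if (is.na(found)) {
        for (t in seq_len(nt)) {
          if (point_in_poly_cross(pt, polys[[t]])) { found <- t; break }
        }
      }
      tile[i] <- found
    }
  }
  data.table::data.table(
    spot_id = as.character(spots$spot_id),
    x_um = spots$x_um, y_um = spots$y_um,
    d_um = ds$d_um, s_um = ds$s_um, layer = layer, tile = tile)
}
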