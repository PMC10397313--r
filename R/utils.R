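# Shared constants and small helpers.

# data.table `[` with `:=` is used throughout without attaching the package
.datatable.aware <- TRUE

# Canonical cell-type vocabulary. "exhausted-T" is generated and profiled as a
# subtype of T/NK but carried as its own entry in composition vectors so layer
# gradients of T-cell exhaustion can be expressed directly.
CELL_TYPES <- c(
  "malignant", "hepatocyte", "macrophage", "T/NK", "exhausted-T",
  "B", "plasma", "DC", "endothelial", "fibroblast"
)

# Primary typing runs over 9 panels: exhausted-T is resolved at subtype level.
PRIMARY_TYPES <- setdiff(CELL_TYPES, "exhausted-T")
PARENCHYMAL_TYPES <- c("malignant", "hepatocyte")
IMMUNE_TYPES <- c("macrophage", "T/NK", "exhausted-T", "B", "plasma", "DC")

# Layer vocabulary: six 250 um bands around the border (negative = tumor side,
# positive = paratumor side), two distant reference bands, "none" elsewhere.
LAYER_LEVELS <- c("-3", "-2", "-1", "+1", "+2", "+3", "distant-", "distant+", "none")
TILED_LAYERS <- c("-3", "-2", "-1", "+1", "+2", "+3")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG state
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so scoring functions are deterministic without disturbing an
#' enclosing simulation stream.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

assert_cols <- function(df, cols, what = "table") {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}

#' Map signed border distances to layer labels
#'
#' Implements the band convention: layer l covers signed distances with
#' |d| in ((|l|-1)*w, |l|*w] where w is the layer width; d >= 0 is the
#' paratumor side. Distances inside (distant_lo, distant_hi] map to the
#' distant reference band of their side; everything else maps to "none".
#'
#' @param d numeric vector of signed distances in um (positive = paratumor).
#' @param layer_width_um band width (default 250).
#' @param n_layers number of bands per side (default 3).
#' @param distant_um two-vector (lo, hi) for the distant band (default
#'   c(2000, 2250)).
#' @return character vector of layer labels.
#' @export
layer_from_distance <- function(d, layer_width_um = 250, n_layers = 3,
                                distant_um = c(2000, 2250)) {
  ad <- abs(d)
  idx <- pmax(ceiling(ad / layer_width_um), 1L)
  lab <- rep("none", length(d))
  in_layer <- ad <= n_layers * layer_width_um
  lab[in_layer] <- ifelse(d[in_layer] >= 0, paste0("+", idx[in_layer]),
                          paste0("-", idx[in_layer]))
  in_dist <- ad > distant_um[1] & ad <= distant_um[2]
  lab[in_dist] <- ifelse(d[in_dist] >= 0, "distant+", "distant-")
  lab
}

# Largest-remainder apportionment of n items to fractions p (sums to n).
apportion_counts <- function(n, p) {
  stopifnot(all(p >= 0), abs(sum(p) - 1) < 1e-6)
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# Shoelace area of a polygon given as an n x 2 matrix (absolute value).
polygon_area <- function(poly) {
  abs(pracma::polyarea(poly[, 1], poly[, 2]))
}

# Sutherland-Hodgman clip of a simple polygon to an axis-aligned rectangle.
clip_polygon_rect <- function(poly, xlim, ylim) {
  clip_half <- function(pts, side) {
    if (nrow(pts) == 0) return(pts)
    inside <- switch(side$dir,
      xmin = pts[, 1] >= side$v, xmax = pts[, 1] <= side$v,
      ymin = pts[, 2] >= side$v, ymax = pts[, 2] <= side$v)
    n <- nrow(pts)
    out <- vector("list", n)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      a <- pts[i, ]; b <- pts[j, ]
      a_in <- inside[i]; b_in <- inside[j]
      seg <- NULL
      if (a_in) seg <- rbind(seg, a)
      if (xor(a_in, b_in)) {
        if (side$dir %in% c("xmin", "xmax")) {
          t <- (side$v - a[1]) / (b[1] - a[1])
          seg <- rbind(seg, c(side$v, a[2] + t * (b[2] - a[2])))
        } else {
          t <- (side$v - a[2]) / (b[2] - a[2])
          seg <- rbind(seg, c(a[1] + t * (b[1] - a[1]), side$v))
        }
      }
      out[[i]] <- seg
    }
    res <- do.call(rbind, out)
    if (is.null(res)) matrix(numeric(0), 0, 2) else res
  }
  sides <- list(
    list(dir = "xmin", v = xlim[1]), list(dir = "xmax", v = xlim[2]),
    list(dir = "ymin", v = ylim[1]), list(dir = "ymax", v = ylim[2]))
  for (s in sides) poly <- clip_half(poly, s)
  # drop consecutive duplicate vertices introduced by clipping
  if (nrow(poly) > 1) {
    keep <- c(TRUE, rowSums(abs(diff(poly))) > 1e-9)
    poly <- poly[keep, , drop = FALSE]
  }
  poly
}

# Point-in-polygon by the cross-product (outer product) rule on a fan
# decomposition about the polygon centroid. Boundary points (a zero cross
# product) count as inside. `pt` is length-2; `poly` an n x 2 matrix.
point_in_poly_cross <- function(pt, poly) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  cx <- mean(poly[, 1]); cy <- mean(poly[, 2])
  ax <- poly[, 1]; ay <- poly[, 2]
  bx <- c(ax[-1], ax[1]); by <- c(ay[-1], ay[1])
  # triangle (c, a_i, b_i): signs of cross products of each edge with the point
  s1 <- (ax - cx) * (pt[2] - cy) - (ay - cy) * (pt[1] - cx)
  s2 <- (bx - ax) * (pt[2] - ay) - (by - ay) * (pt[1] - ax)
  s3 <- (cx - bx) * (pt[2] - by) - (cy - by) * (pt[1] - bx)
  any((s1 >= 0 & s2 >= 0 & s3 >= 0) | (s1 <= 0 & s2 <= 0 & s3 <= 0))
}
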