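#' Read a GEM table of nanoscale capture records
#'
#' GEM is the community long format for DNB-patterned spatial transcriptomics:
#' a tab-separated text file with one record per (gene, x, y, count), where x
#' and y are integer bin indices on the chip grid and count is the number of
#' molecular identifiers captured. Comment lines starting with `#` are
#' skipped. Both `MIDCount` and `UMICount` are accepted as the count column
#' (dialects differ between pipelines); extra columns are tolerated and
#' dropped. Duplicate (gene, x, y) records are summed.
#'
#' @param path path to a GEM text file.
#' @return a `gem_table`: a `data.table` with columns `gene` (character),
#'   `x`, `y` (integer bin indices) and `count` (positive integer).
#' @export
read_gem <- function(path) {
  if (!file.exists(path)) stop("GEM file not found: ", path, call. = FALSE)
  # skip leading '#' comment lines (GEM headers often carry chip metadata)
  head_lines <- readLines(path, n = 100L)
  skip <- match(FALSE, startsWith(head_lines, "#"), nomatch = 1L) - 1L
  dt <- data.table::fread(path, sep = "\t", header = TRUE, skip = skip,
                          showProgress = FALSE)
  cn <- names(dt)
  gene_col <- intersect(c("geneID", "gene", "gene_id"), cn)[1]
  count_col <- intersect(c("MIDCount", "UMICount", "count", "MIDCounts"), cn)[1]
  if (is.na(gene_col)) stop("GEM format error: missing gene column (geneID)", call. = FALSE)
  if (!"x" %in% cn) stop("GEM format error: missing column 'x'", call. = FALSE)
  if (!"y" %in% cn) stop("GEM format error: missing column 'y'", call. = FALSE)
  if (is.na(count_col))
    stop("GEM format error: missing count column (MIDCount/UMICount)", call. = FALSE)
  dt <- dt[, c(gene_col, "x", "y", count_col), with = FALSE]
  data.table::setnames(dt, c("gene", "x", "y", "count"))
  if (nrow(dt) == 0) {
    dt <- data.table::data.table(gene = character(), x = integer(),
                                 y = integer(), count = integer())
    return(as_gem_table(dt))
  }
  data.table::set(dt, j = "gene", value = as.character(dt$gene))
  for (col in c("x", "y", "count")) {
    v <- dt[[col]]
    if (!(is.integer(v) || (is.numeric(v) && all(v == floor(v))))) {
      bad <- which(is.na(suppressWarnings(as.integer(v))) | v != floor(v))[1]
      stop(sprintf("GEM parse error: non-integer '%s' at data line %d", col,
                   bad), call. = FALSE)
    }
    data.table::set(dt, j = col, value = as.integer(v))
  }
  as_gem_table(dt)
}

#' Construct and validate a gem_table
#'
#' Aggregates duplicate (gene, x, y) records and checks invariants
#' (counts >= 1, non-negative coordinates).
#' @param dt a data.frame/data.table with columns gene, x, y, count.
#' @return a validated `gem_table`.
#' @export
as_gem_table <- function(dt) {
  dt <- data.table::as.data.table(dt)
  assert_cols(dt, c("gene", "x", "y", "count"), "gem_table")
  if (nrow(dt)) {
    if (any(dt$count < 1)) stop("gem_table invariant violated: counts must be >= 1", call. = FALSE)
    if (any(dt$x < 0) || any(dt$y < 0))
      stop("gem_table invariant violated: bin indices must be >= 0", call. = FALSE)
    count <- NULL # NSE binding note for R CMD check
    dt <- dt[, list(count = sum(count)), by = c("gene", "x", "y")]
  }
  data.table::setattr(dt, "class", c("gem_table", class(data.table::data.table())))
  dt[]
}

#' Write a GEM table to disk
#'
#' @param gem a `gem_table`.
#' @param path output path; written tab-separated with a `geneID/x/y/MIDCount`
#'   header.
#' @return `path`, invisibly.
#' @export
write_gem <- function(gem, path) {
  out <- data.table::copy(data.table::as.data.table(gem))
  data.table::setnames(out, c("gene", "count"), c("geneID", "MIDCount"))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Slide configuration
#'
#' Physical constants of a chip/slide: the pitch of one DNB bin (center to
#' center, default 0.5 um so that 50 bins = 25 um) and the slide extent.
#' All downstream geometry is computed in um with the origin at the lower-left
#' corner, x rightward and y upward; a bin index maps to
#' `index * bin_pitch_um`.
#'
#' @param bin_pitch_um physical pitch of one bin in um (> 0).
#' @param slide_extent_um numeric length-2, slide (width, height) in um.
#' @param rng_seed integer seed recorded with the slide.
#' @return a `slide_config` list.
#' @export
slide_config <- function(bin_pitch_um = 0.5,
                         slide_extent_um = c(10000, 10000),
                         rng_seed = 1L) {
  stopifnot(bin_pitch_um > 0, length(slide_extent_um) == 2,
            all(slide_extent_um > 0))
  structure(list(bin_pitch_um = bin_pitch_um,
                 slide_extent_um = as.numeric(slide_extent_um),
                 rng_seed = as.integer(rng_seed)),
            class = "slide_config")
}

#' Write a spot assignment table
#'
#' One row per spot with its coordinates, layer, tile and cell type. Layer
#' must be one of `-3..-1`, `+1..+3`, `distant-`, `distant+`, `distant` or
#' `none`; tile is an integer in 1..n_tiles or `none`.
#'
#' @param assignments data.frame with columns `spot_id`, `x_um`, `y_um`,
#'   `layer`, `tile`, `cell_type`.
#' @param path output TSV path.
#' @param n_tiles maximum valid tile index (default 100).
#' @return `path`, invisibly.
#' @export
write_assignment_table <- function(assignments, path, n_tiles = 100) {
  assert_cols(assignments, c("spot_id", "x_um", "y_um", "layer", "tile", "cell_type"),
              "assignment table")
  lay <- as.character(assignments$layer)
  ok_layers <- c(LAYER_LEVELS, "distant")
  if (!all(lay %in% ok_layers))
    stop("assignment validation error: layer values outside ",
         paste(ok_layers, collapse = ","), call. = FALSE)
  tl <- as.character(assignments$tile)
  tl[is.na(tl)] <- "none"
  num <- suppressWarnings(as.integer(tl[tl != "none"]))
  if (any(is.na(num)) || any(num < 1 | num > n_tiles))
    stop("assignment validation error: tile indices must be in 1..", n_tiles,
         " or 'none'", call. = FALSE)
  out <- data.table::data.table(
    spot_id = as.character(assignments$spot_id),
    x_um = assignments$x_um, y_um = assignments$y_um,
    layer = lay, tile = tl, cell_type = as.character(assignments$cell_type))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read a spot assignment table written by [write_assignment_table()]
#' @param path TSV path.
#' @return data.table with the six assignment columns (`tile` as character,
#'   "none" for unassigned).
#' @export
read_assignment_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("spot_id", "layer", "tile", "cell_type")),
                          showProgress = FALSE)
  assert_cols(dt, c("spot_id", "x_um", "y_um", "layer", "tile", "cell_type"),
              "assignment table")
  dt
}

#' Write / read a spot annotation table
#'
#' Annotation tables carry per-spot typing results (or external annotations):
#' `spot_id`, `x_um`, `y_um`, `cell_type`, optional `subtype` and `hep_class`.
#' @param annotation data.frame of annotations.
#' @param path TSV path.
#' @return `path` (write) or a data.table (read).
#' @export
write_annotation_table <- function(annotation, path) {
  assert_cols(annotation, c("spot_id", "x_um", "y_um", "cell_type"), "annotation")
  data.table::fwrite(data.table::as.data.table(annotation), path, sep = "\t")
  invisible(path)
}

#' @rdname write_annotation_table
#' @export
read_annotation_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, showProgress = FALSE)
  assert_cols(dt, c("spot_id", "x_um", "y_um", "cell_type"), "annotation")
  dt
}

#' Read / write marker panels or gene sets as two-column TSV
#'
#' Format: columns `set_name`, `gene_id`; one row per (panel, gene).
#' @param path TSV path.
#' @return named list of character vectors (read); `path` invisibly (write).
#' @export
read_gene_sets <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, showProgress = FALSE)
  assert_cols(dt, c("set_name", "gene_id"), "gene set table")
  split(as.character(dt$gene_id), dt$set_name)
}

#' @rdname read_gene_sets
#' @param sets named list of character vectors.
#' @export
write_gene_sets <- function(sets, path) {
  dt <- data.table::data.table(
    set_name = rep(names(sets), lengths(sets)),
    gene_id = unlist(sets, use.names = FALSE))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

# ---- WKT geometry text export -----------------------------------------------

wkt_coords <- function(mat) {
  paste(sprintf("%.3f %.3f", mat[, 1], mat[, 2]), collapse = ", ")
}

#' Export border and tile geometry as WKT text
#'
#' The border polyline is written as a `LINESTRING`, each band/tile polygon as
#' a `POLYGON`, one geometry per row of a two-column TSV (`id`, `wkt`).
#' @param geoms named list of n x 2 coordinate matrices.
#' @param types character vector (recycled): "LINESTRING" or "POLYGON".
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_wkt <- function(geoms, types, path) {
  types <- rep_len(types, length(geoms))
  wkt <- vapply(seq_along(geoms), function(i) {
    m <- geoms[[i]]
    if (is.null(m) || nrow(m) == 0) return(paste(types[i], "EMPTY"))
    if (types[i] == "POLYGON") {
      if (any(m[1, ] != m[nrow(m), ])) m <- rbind(m, m[1, ])
      sprintf("POLYGON ((%s))", wkt_coords(m))
    } else sprintf("LINESTRING (%s)", wkt_coords(m))
  }, character(1))
  dt <- data.table::data.table(id = names(geoms), wkt = wkt)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read geometry written by [write_wkt()]
#' @param path TSV path with `id`, `wkt` columns.
#' @return named list of n x 2 coordinate matrices.
#' @export
read_wkt <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, showProgress = FALSE)
  out <- lapply(dt$wkt, function(w) {
    if (grepl("EMPTY$", w)) return(matrix(numeric(0), 0, 2))
    body <- gsub("^[A-Z]+ *\\(+|\\)+$", "", w)
    pts <- strsplit(strsplit(body, ", *")[[1]], " +")
    do.call(rbind, lapply(pts, as.numeric))
  })
  names(out) <- dt$id
  out
}

#' Read / write a run configuration as YAML
#' @param path YAML file path.
#' @return named list (read); `path` invisibly (write).
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

#' @rdname read_run_config
#' @param config named list of parameters.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
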