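#' Aggregate nanoscale records into pseudo-spots
#'
#' Convolves a GEM table into square pseudo-spots: record (g, x, y, c)
#' contributes c to spot (floor(x/bin_size), floor(y/bin_size)) for gene g.
#' `bin_size = 50` gives the 25 um "bin50" pseudo-spot used for cell typing
#' (at the default 0.5 um bin pitch); `bin_size = 1000` gives the 500 um
#' "bin1000" microenvironment unit. Empty spots are omitted; total counts are
#' conserved.
#'
#' @param gem a `gem_table`.
#' @param bin_size positive integer window size in bins.
#' @param bin_pitch_um physical bin pitch in um (default 0.5); used only to
#'   place spot centroids.
#' @return a `bin_matrix`: list with `counts` (sparse spots x genes
#'   dgCMatrix), `coords` (data.table: spot_id, gx, gy, x_um, y_um),
#'   `bin_size`, `bin_pitch_um`, and a `norm` slot (NULL until
#'   [cpm_normalize()]).
#' @export
aggregate_bins <- function(gem, bin_size, bin_pitch_um = 0.5) {
  if (length(bin_size) != 1 || is.na(bin_size) || bin_size < 1)
    stop("bin_size must be a positive integer", call. = FALSE)
  bin_size <- as.integer(bin_size)
  dt <- data.table::as.data.table(gem)
  gx <- gy <- count <- NULL
  agg <- dt[, list(gx = x %/% bin_size, gy = y %/% bin_size,
                   gene = gene, count = count)][
    , list(count = sum(count)), by = c("gene", "gx", "gy")]
  # numeric spot key avoids building millions of strings
  key <- agg$gx * 2^21 + agg$gy
  ukey <- sort(unique(key))
  ugx <- ukey %/% 2^21
  ugy <- ukey %% 2^21
  coords <- data.table::data.table(
    spot_id = paste0("s", ugx, "_", ugy), gx = as.integer(ugx), gy = as.integer(ugy))
  coords[, `:=`(
    x_um = (gx + 0.5) * bin_size * bin_pitch_um,
    y_um = (gy + 0.5) * bin_size * bin_pitch_um)]
  genes <- sort(unique(agg$gene))
  i <- match(key, ukey)
  j <- match(agg$gene, genes)
  counts <- Matrix::sparseMatrix(
    i = i, j = j, x = agg$count,
    dims = c(nrow(coords), length(genes)),
    dimnames = list(coords$spot_id, genes))
  structure(list(counts = counts, coords = coords, bin_size = bin_size,
                 bin_pitch_um = bin_pitch_um, norm = NULL, norm_type = NULL),
            class = "bin_matrix")
}

#' @export
print.bin_matrix <- function(x, ...) {
  cat(sprintf("bin_matrix: %d spots x %d genes (bin%d, %.0f um edge)%s\n",
              nrow(x$counts), ncol(x$counts), x$bin_size,
              x$bin_size * x$bin_pitch_um,
              if (is.null(x$norm)) "" else paste0(", normalized (", x$norm_type, ")")))
  invisible(x)
}

#' Convert a bin_matrix back to a gem_table of spot-grid records
#'
#' Each (spot, gene) entry becomes one record at the spot's grid index, so
#' re-aggregating with a coarser window composes (e.g. bin50 then 20 equals
#' bin1000 on the original grid).
#' @param bm a `bin_matrix`.
#' @return a `gem_table` with x, y equal to spot grid indices.
#' @export
as_gem <- function(bm) {
  tm <- Matrix::summary(bm$counts) # i, j, x triplets
  as_gem_table(data.table::data.table(
    gene = colnames(bm$counts)[tm$j],
    x = bm$coords$gx[tm$i], y = bm$coords$gy[tm$i],
    count = as.integer(tm$x)))
}

#' Counts-per-million normalization per spot
#'
#' Scales each nonzero spot's counts to sum to 1e6 ("CPM"), optionally
#' followed by log1p. All-zero spots pass through as zero. Fills the `norm`
#' slot of the bin_matrix; counts are kept untouched.
#'
#' @param bm a `bin_matrix`.
#' @param log1p if TRUE, store log(1 + CPM).
#' @return the `bin_matrix` with `norm` filled.
#' @export
cpm_normalize <- function(bm, log1p = FALSE) {
  if (nrow(bm$counts) == 0) stop("bin_matrix has no spots", call. = FALSE)
  libsize <- Matrix::rowSums(bm$counts)
  scale <- ifelse(libsize > 0, 1e6 / libsize, 0)
  norm <- Matrix::Diagonal(x = scale) %*% bm$counts
  norm <- methods::as(norm, "CsparseMatrix")
  dimnames(norm) <- dimnames(bm$counts)
  if (log1p) norm@x <- log1p(norm@x)
  bm$norm <- norm
  bm$norm_type <- if (log1p) "log1p-CPM" else "CPM"
  bm
}
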