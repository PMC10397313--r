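# Per-layer and per-tile profiling along the normal direction of the border.

# Effective profiling type: T/NK spots with the exhausted subtype are counted
# as "exhausted-T", so composition vectors carry the exhaustion gradient.
effective_type <- function(annotation) {
  ifelse(!is.na(annotation$subtype) & annotation$subtype == "exhausted" &
           annotation$cell_type == "T/NK",
         "exhausted-T", annotation$cell_type)
}

#' Per-layer cell-type composition
#'
#' Counts and fractions of each cell type per layer. The denominator is
#' either all annotated spots in the layer ("all") or spots excluding the
#' parenchymal types malignant/cholangiocyte and hepatocyte
#' ("nonparenchymal"); both conventions appear in margin-area reporting.
#' Empty layers yield NA fractions and are flagged.
#'
#' @param assignment data.frame from [assign_spots()] (spot_id, layer, ...).
#' @param annotation data.frame with spot_id, cell_type, optional subtype.
#' @param denominator "all" or "nonparenchymal".
#' @param slide_id identifier recorded in the output (default "slide1").
#' @return a `layer_profile` data.table: slide, layer, cell_type, n, n_layer,
#'   fraction, denominator, flag.
#' @export
layer_composition <- function(assignment, annotation,
                              denominator = c("all", "nonparenchymal"),
                              slide_id = "slide1") {
  denominator <- match.arg(denominator)
  ann <- data.table::as.data.table(annotation)
  if (!"subtype" %in% names(ann)) ann$subtype <- NA_character_
  asn <- data.table::as.data.table(assignment)[, c("spot_id", "layer")]
  dt <- merge(asn, ann[, list(spot_id, cell_type, subtype)], by = "spot_id")
  dt[, type := effective_type(dt)]
  if (denominator == "nonparenchymal")
    dt <- dt[!type %in% PARENCHYMAL_TYPES]
  layers <- setdiff(LAYER_LEVELS, "none")
  grid <- data.table::CJ(layer = layers,
                         cell_type = c(CELL_TYPES))
  n_dt <- dt[, list(n = .N), by = c("layer", "type")]
  data.table::setnames(n_dt, "type", "cell_type")
  out <- merge(grid, n_dt, by = c("layer", "cell_type"), all.x = TRUE)
  out[is.na(n), n := 0L]
  out[, n_layer := sum(n), by = "layer"]
  out[, fraction := ifelse(n_layer > 0, n / n_layer, NA_real_)]
  out[, flag := ifelse(n_layer == 0, "empty_layer", "")]
  out[, `:=`(slide = slide_id, denominator = denominator)]
  if (denominator == "nonparenchymal")
    out <- out[!cell_type %in% PARENCHYMAL_TYPES]
  data.table::setcolorder(out, c("slide", "layer", "cell_type", "n",
                                 "n_layer", "fraction", "denominator", "flag"))
  out[order(match(layer, layers), match(cell_type, CELL_TYPES))]
}

#' Summarize a cell type's layer gradient across slides
#'
#' Mean and sd of a type's per-layer fraction across slides, with two-sample
#' t-tests between adjacent layers (reporting plumbing; NA when variance is
#' zero or fewer than two slides are available).
#'
#' @param profiles a `layer_profile` table covering >= 1 slides (rbind of
#'   [layer_composition()] outputs).
#' @param type cell type to summarize.
#' @param layers layer labels in gradient order (default the six layers).
#' @return list with `summary` (layer, mean, sd, n_slides) and `tests`
#'   (layer_a, layer_b, t, p).
#' @export
gradient_summary <- function(profiles, type,
                             layers = c("-3", "-2", "-1", "+1", "+2", "+3")) {
  dt <- data.table::as.data.table(profiles)[cell_type == type & layer %in% layers]
  smry <- dt[, list(mean = mean(fraction, na.rm = TRUE),
                    sd = stats::sd(fraction),
                    n_slides = sum(!is.na(fraction))), by = "layer"]
  smry <- smry[order(match(layer, layers))]
  tests <- NULL
  if (length(unique(dt$slide)) >= 2) {
    tests <- do.call(rbind, lapply(seq_len(length(layers) - 1), function(i) {
      a <- dt$fraction[dt$layer == layers[i]]
      b <- dt$fraction[dt$layer == layers[i + 1]]
      tt <- tryCatch(stats::t.test(a, b), error = function(e) NULL)
      data.frame(layer_a = layers[i], layer_b = layers[i + 1],
                 t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
                 p = if (is.null(tt)) NA_real_ else tt$p.value)
    }))
  }
  list(summary = smry, tests = tests)
}

#' Mean z-score signature score per unit
#'
#' A light-weight signature score over spatial units (bin1000
#' microenvironment units or tiles): each gene of the set is z-scored across
#' units and the unit's score is the mean z over the set. This is a simple
#' stand-in for gene-set variation analysis, intended for direction-of-effect
#' comparisons between zones, not for pathway inference.
#'
#' @param bm a normalized `bin_matrix` whose rows are the units (>= 2).
#' @param gene_set character vector of gene ids.
#' @return named numeric vector of per-unit scores.
#' @export
signature_score <- function(bm, gene_set) {
  if (nrow(bm$counts) < 2)
    stop("need >= 2 units for a signature score", call. = FALSE)
  genes <- intersect(gene_set, colnames(bm$norm %||% bm$counts))
  if (!length(genes))
    stop("gene set absent from the matrix", call. = FALSE)
  z <- zscore_genes(bm, genes)
  stats::setNames(rowMeans(z), rownames(z))
}

#' Composition of the distant reference bands
#'
#' Profile over the 250 um-wide reference zones at least 2 mm from the border
#' on each side. Sides whose band is empty (slide does not extend far enough)
#' are flagged.
#'
#' @inheritParams layer_composition
#' @return a `layer_profile` restricted to `distant-` / `distant+`, with the
#'   `flag` column marking absent bands.
#' @export
distant_reference <- function(assignment, annotation,
                              denominator = c("all", "nonparenchymal"),
                              slide_id = "slide1") {
  prof <- layer_composition(assignment, annotation, denominator, slide_id)
  prof[layer %in% c("distant-", "distant+")]
}
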