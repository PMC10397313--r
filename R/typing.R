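# Marker-score cell typing and gene-set module scores on normalized
# pseudo-spot matrices.

# Dense, z-scored submatrix of the normalized layer for the requested genes.
# Zero-variance genes are dropped with a warning naming them.
zscore_genes <- function(bm, genes) {
  if (is.null(bm$norm))
    stop("bin_matrix is not normalized; call cpm_normalize() first", call. = FALSE)
  present <- intersect(genes, colnames(bm$norm))
  m <- as.matrix(bm$norm[, present, drop = FALSE])
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance gene(s) excluded: ",
            paste(present[sds == 0], collapse = ", "), call. = FALSE)
    m <- m[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  scale(m)
}

#' Score marker panels and assign the top-scoring type per spot
#'
#' For each panel, every marker gene present in the matrix is standardized
#' across spots (z-score, mean 0 / sd 1) and the panel score is the mean
#' z-score over the panel's genes; each spot is labeled with the
#' highest-scoring panel, ties broken by panel order. Panels with no usable
#' genes score NA and never win the argmax.
#'
#' @param bm a normalized `bin_matrix` (see [cpm_normalize()]).
#' @param panels named list of marker gene vectors.
#' @param spots optional character vector restricting scoring to a subset of
#'   spot ids (used for subtype calls within a parent type).
#' @return data.frame with `spot_id`, one score column per panel, and `label`.
#' @export
score_panels <- function(bm, panels, spots = NULL) {
  stopifnot(length(panels) >= 1, all(lengths(panels) >= 1))
  all_genes <- unique(unlist(panels))
  z <- zscore_genes(bm, all_genes)
  if (!is.null(spots)) {
    keep <- rownames(z) %in% spots
    z <- z[keep, , drop = FALSE]
  }
  scores <- sapply(panels, function(g) {
    g <- intersect(g, colnames(z))
    if (!length(g)) return(rep(NA_real_, nrow(z)))
    rowMeans(z[, g, drop = FALSE])
  })
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1,
                                             dimnames = list(NULL, names(panels)))
  usable <- colSums(is.na(scores)) < nrow(scores)
  if (!any(usable)) stop("no panel has genes present in the matrix", call. = FALSE)
  lab_idx <- max.col(replace(scores[, usable, drop = FALSE],
                             is.na(scores[, usable, drop = FALSE]), -Inf),
                     ties.method = "first")
  out <- data.frame(spot_id = rownames(z), scores, check.names = FALSE,
                    row.names = NULL)
  out$label <- names(panels)[usable][lab_idx]
  out
}

#' Gene-set module score with expression-bin-matched controls
#'
#' Per-spot score of a gene set: mean normalized expression of the set's
#' genes minus the mean over control genes, where each set gene contributes
#' `n_ctrl` control genes sampled from its own average-expression quantile
#' bin. Deterministic for a fixed seed; the caller's RNG state is untouched.
#'
#' @param bm a normalized `bin_matrix`.
#' @param gene_set character vector of gene ids.
#' @param n_bins number of average-expression quantile bins (default 25).
#' @param n_ctrl control genes sampled per set gene (default 100, with
#'   replacement if the bin is smaller).
#' @param seed integer seed for control sampling (default 0).
#' @return named numeric vector of per-spot scores.
#' @export
module_score <- function(bm, gene_set, n_bins = 25, n_ctrl = 100, seed = 0L) {
  if (is.null(bm$norm))
    stop("bin_matrix is not normalized; call cpm_normalize() first", call. = FALSE)
  genes <- colnames(bm$norm)
  set_present <- intersect(gene_set, genes)
  if (!length(set_present))
    stop("gene set is disjoint from the matrix genes", call. = FALSE)
  avg <- Matrix::colMeans(bm$norm)
  bin <- cut(rank(avg, ties.method = "first"), breaks = n_bins, labels = FALSE)
  names(bin) <- genes
  ctrl <- with_seed(seed, unlist(lapply(set_present, function(g) {
    pool <- genes[bin == bin[g]]
    sample(pool, n_ctrl, replace = length(pool) < n_ctrl)
  }), use.names = FALSE))
  set_mean <- Matrix::rowMeans(bm$norm[, set_present, drop = FALSE])
  tab <- table(ctrl)
  ctrl_mean <- as.numeric(bm$norm[, names(tab), drop = FALSE] %*%
                            as.numeric(tab)) / length(ctrl)
  scores <- set_mean - ctrl_mean
  stats::setNames(as.numeric(scores), rownames(bm$norm))
}

#' Classify hepatocyte spots as SAA-high (Hep1) or SAA-low (Hep2)
#'
#' Computes module scores for the two reference gene sets (GS1: the SAA-high
#' program; GS2: the SAA-low counterpart) and labels a spot Hep1 iff
#' score(GS1) - score(GS2) > 0.
#'
#' @param bm a normalized `bin_matrix`.
#' @param gs1,gs2 character vectors of gene ids (must differ).
#' @param hep_spots character vector of spot ids pre-filtered to hepatocytes.
#' @param n_bins,n_ctrl,seed passed to [module_score()].
#' @return data.frame with `spot_id`, `gs1_score`, `gs2_score`, `hep_class`.
#' @export
classify_hep <- function(bm, gs1, gs2, hep_spots, n_bins = 25, n_ctrl = 100,
                         seed = 0L) {
  if (setequal(gs1, gs2))
    stop("degenerate-sets error: GS1 and GS2 are identical", call. = FALSE)
  s1 <- module_score(bm, gs1, n_bins, n_ctrl, seed = seed)
  s2 <- module_score(bm, gs2, n_bins, n_ctrl, seed = seed + 1L)
  keep <- names(s1) %in% hep_spots
  data.frame(spot_id = names(s1)[keep],
             gs1_score = s1[keep], gs2_score = s2[keep],
             hep_class = ifelse(s1[keep] - s2[keep] > 0, "Hep1", "Hep2"),
             row.names = NULL)
}

#' Annotate all spots: primary type, T/NK subtype, hepatocyte class
#'
#' Orchestrates [score_panels()] over the primary marker panels, subtype
#' scoring of T/NK spots (conventional vs exhausted), and [classify_hep()]
#' on hepatocyte spots. Mirrors the two-stage procedure used on real slides
#' (primary typing, then marker standardization within the parent type).
#'
#' @param bm a normalized `bin_matrix`.
#' @param model an `expression_model` supplying panels and gene sets (or any
#'   list with `panels`, `subtype_panels`, `gs1`, `gs2`).
#' @param seed seed for module-score control sampling (default 0).
#' @return data.frame annotation: `spot_id`, `x_um`, `y_um`, `cell_type`,
#'   `subtype`, `hep_class`.
#' @export
annotate_spots <- function(bm, model, seed = 0L) {
  primary <- score_panels(bm, model$panels)
  ann <- data.frame(spot_id = primary$spot_id, cell_type = primary$label,
                    subtype = NA_character_, hep_class = NA_character_,
                    stringsAsFactors = FALSE)
  tnk <- ann$spot_id[ann$cell_type == "T/NK"]
  if (length(tnk)) {
    sub <- score_panels(bm, model$subtype_panels, spots = tnk)
    ann$subtype[match(sub$spot_id, ann$spot_id)] <- sub$label
  }
  hep <- ann$spot_id[ann$cell_type == "hepatocyte"]
  if (length(hep)) {
    hc <- classify_hep(bm, model$gs1, model$gs2, hep, seed = seed)
    ann$hep_class[match(hc$spot_id, ann$spot_id)] <- hc$hep_class
  }
  coords <- bm$coords[match(ann$spot_id, bm$coords$spot_id), ]
  ann$x_um <- coords$x_um
  ann$y_um <- coords$y_um
  ann[, c("spot_id", "x_um", "y_um", "cell_type", "subtype", "hep_class")]
}
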