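# Tangential composition patterns in the invasive zone: bilateral tile
# merging, correlation-based hierarchical clustering, recurrence enrichment.

# Types entering tangential composition vectors: nonparenchymal only, with
# exhausted-T folded into T/NK (patterns operate at the main-type level).
PATTERN_TYPES <- c("macrophage", "T/NK", "B", "plasma", "DC", "endothelial",
                   "fibroblast")

#' Build tangential composition vectors from the invasive zone
#'
#' For each tangential position t, the cell counts of the two bilateral
#' first-layer tiles (+1, t) and (-1, t) are merged, parenchymal cells
#' (malignant/cholangiocyte, hepatocyte) are excluded, and the remaining
#' counts are normalized to fractions. Positions with zero included cells are
#' marked missing.
#'
#' @param assignment output of [assign_spots()].
#' @param annotation per-spot annotation (spot_id, cell_type, subtype).
#' @param slide_id,patient_id identifiers recorded per vector.
#' @param n_tiles tangential positions (default 100).
#' @return a `tangential_vectors` list: `fractions` (n_tiles x 7 matrix, NA
#'   rows = missing), `counts`, `meta` (data.table: patient_id, slide_id,
#'   t, n_cells, missing).
#' @export
build_tangential_vectors <- function(assignment, annotation,
                                     slide_id = "slide1",
                                     patient_id = "patient1",
                                     n_tiles = 100) {
  ann <- data.table::as.data.table(annotation)
  if (!"subtype" %in% names(ann)) ann$subtype <- NA_character_
  asn <- data.table::as.data.table(assignment)
  dt <- merge(asn[layer %in% c("-1", "+1") & !is.na(tile),
                  list(spot_id, tile)],
              ann[, list(spot_id, cell_type)], by = "spot_id")
  dt <- dt[cell_type %in% PATTERN_TYPES]
  if (nrow(dt) == 0)
    stop("no nonparenchymal cells in the invasive zone", call. = FALSE)
  counts <- matrix(0L, n_tiles, length(PATTERN_TYPES),
                   dimnames = list(NULL, PATTERN_TYPES))
  tab <- dt[, list(n = .N), by = c("tile", "cell_type")]
  counts[cbind(tab$tile, match(tab$cell_type, PATTERN_TYPES))] <- tab$n
  n_cells <- rowSums(counts)
  fractions <- counts / ifelse(n_cells > 0, n_cells, NA_real_)
  meta <- data.table::data.table(
    patient_id = patient_id, slide_id = slide_id, t = seq_len(n_tiles),
    n_cells = n_cells, missing = n_cells == 0)
  structure(list(fractions = fractions, counts = counts, meta = meta),
            class = "tangential_vectors")
}

#' Merge tangential vectors from several slides
#' @param vector_list list of `tangential_vectors`.
#' @return a single `tangential_vectors` with stacked rows.
#' @export
bind_tangential_vectors <- function(vector_list) {
  structure(list(
    fractions = do.call(rbind, lapply(vector_list, `[[`, "fractions")),
    counts = do.call(rbind, lapply(vector_list, `[[`, "counts")),
    meta = data.table::rbindlist(lapply(vector_list, `[[`, "meta"))),
    class = "tangential_vectors")
}

#' Cluster tangential vectors into composition patterns
#'
#' Pairwise Pearson correlation between composition vectors defines the
#' distance 1 - r; hierarchical clustering (Ward linkage by default, which
#' resolves compact composition patterns including intermediates between two
#' dominant types; `"average"` is also supported) is cut either at a fixed k
#' or at the k in 2..max_k maximizing the mean silhouette width.
#' Zero-variance (constant) vectors cannot enter the correlation and are
#' assigned afterwards to the nearest pattern centroid (Euclidean), flagged
#' in the output.
#'
#' @param vectors a `tangential_vectors` object (or plain fraction matrix).
#' @param k "auto" or a fixed integer number of patterns.
#' @param max_k largest k tried under auto selection (default 10).
#' @param linkage hclust agglomeration method (default "ward.D2").
#' @return a `pattern_result`: list with `labels` (integer per non-missing
#'   vector, NA for missing), `k`, `correlation` (matrix), `hclust`,
#'   `centroids` (pattern x type mean composition), `silhouette` (per-k mean
#'   widths under auto), `meta`, `flags`.
#' @export
cluster_patterns <- function(vectors, k = "auto", max_k = 10,
                             linkage = "ward.D2") {
  fr <- if (inherits(vectors, "tangential_vectors")) vectors$fractions else vectors
  meta <- if (inherits(vectors, "tangential_vectors")) vectors$meta else NULL
  ok <- stats::complete.cases(fr)
  sds <- apply(fr, 1, stats::sd)
  usable <- ok & !is.na(sds) & sds > 0
  constant <- ok & !usable
  if (sum(usable) < 2)
    stop("need >= 2 non-missing, non-constant vectors", call. = FALSE)
  V <- fr[usable, , drop = FALSE]
  C <- stats::cor(t(V))
  D <- stats::as.dist(1 - C)
  hc <- stats::hclust(D, method = linkage)
  sil_by_k <- NULL
  if (identical(k, "auto")) {
    ks <- 2:min(max_k, nrow(V) - 1)
    sil_by_k <- vapply(ks, function(kk) {
      cl <- stats::cutree(hc, k = kk)
      mean(cluster::silhouette(cl, D)[, "sil_width"])
    }, numeric(1))
    names(sil_by_k) <- ks
    k <- ks[which.max(sil_by_k)]
  }
  cl <- stats::cutree(hc, k = k)
  # order patterns by size (largest = 1) for label stability across
  # permutations of the input rows
  size_rank <- rank(-tabulate(cl, nbins = k), ties.method = "first")
  cl <- size_rank[cl]
  centroids <- t(vapply(seq_len(k), function(p)
    colMeans(V[cl == p, , drop = FALSE]), numeric(ncol(V))))
  colnames(centroids) <- colnames(fr)
  labels <- rep(NA_integer_, nrow(fr))
  labels[usable] <- cl
  flags <- rep("", nrow(fr))
  if (any(constant)) {
    for (i in which(constant)) {
      d2 <- rowSums((centroids - matrix(fr[i, ], k, ncol(fr), byrow = TRUE))^2)
      labels[i] <- which.min(d2)
      flags[i] <- "constant_vector"
    }
  }
  structure(list(labels = labels, k = k, correlation = C, hclust = hc,
                 centroids = centroids, silhouette = sil_by_k, meta = meta,
                 flags = flags),
            class = "pattern_result")
}

#' @export
print.pattern_result <- function(x, ...) {
  cat(sprintf("pattern_result: %d vectors in %d patterns\n",
              sum(!is.na(x$labels)), x$k))
  invisible(x)
}

#' Recurrence enrichment of composition patterns
#'
#' For each pattern, the enrichment score is
#' log2(fraction of the pattern's vectors that come from recurrent patients /
#' overall recurrent-vector fraction), i.e. log2 observed/expected; a
#' chi-squared test on the patterns x recurrence contingency table assesses
#' association. The score formula is a declared reconstruction of
#' "recurrence enrichment" bar charts; the underlying tabulation is exact.
#'
#' @param result a `pattern_result` whose `meta` has `patient_id`.
#' @param patients data.table with `patient_id`, `recurrence` (logical).
#' @return list with `scores` (data.table: pattern, n, n_recurrent, fraction,
#'   expected, score), `chisq` (htest or NULL), `table` (contingency).
#' @export
recurrence_enrichment <- function(result, patients) {
  if (is.null(result$meta))
    stop("pattern_result carries no per-vector metadata", call. = FALSE)
  meta <- data.table::as.data.table(result$meta)
  meta$label <- result$labels
  meta <- meta[!is.na(label)]
  rec <- patients$recurrence[match(meta$patient_id, patients$patient_id)]
  if (any(is.na(rec)))
    stop("labeled vectors map to patients with unknown recurrence", call. = FALSE)
  if (length(unique(rec)) < 2) {
    return(list(scores = data.table::data.table(
      pattern = sort(unique(meta$label)), n = NA_integer_,
      n_recurrent = NA_integer_, fraction = NA_real_, expected = NA_real_,
      score = NA_real_), chisq = NULL, table = NULL))
  }
  tab <- table(pattern = meta$label, recurrent = rec)
  overall <- mean(rec)
  scores <- data.table::data.table(
    pattern = as.integer(rownames(tab)),
    n = as.integer(rowSums(tab)),
    n_recurrent = as.integer(tab[, "TRUE"]))
  scores[, `:=`(fraction = n_recurrent / n, expected = overall)]
  scores[, score := log2(fraction / expected)]
  chisq <- suppressWarnings(stats::chisq.test(tab))
  list(scores = scores, chisq = chisq, table = tab)
}
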