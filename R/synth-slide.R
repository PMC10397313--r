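# Ground-truthed synthetic slide generator. Emulates a liver-cancer margin
# slide: a curved tumor border separating a malignant-cell-dominated tumor
# side from a hepatocyte-dominated paratumor side, with layer-dependent
# immune-cell gradients, SAA-high hepatocytes confined to the first paratumor
# layer, and (optionally) tangential composition archetypes in the invasive
# zone.

#' Parametric border specification
#'
#' The synthetic border is a simple curve spanning the slide left-to-right:
#' either a horizontal line or a cosine wave (zero slope at the slide edges so
#' normal offsets stay inside the slide). The tumor side is below the curve
#' (negative signed distance), the paratumor side above.
#'
#' @param shape "sinusoid" or "straight".
#' @param amplitude_um wave amplitude (um), sinusoid only.
#' @param period_um wave period (um), sinusoid only.
#' @param center_um y position of the border midline; defaults to half the
#'   slide height at generation time.
#' @return a `border_spec` list.
#' @export
border_spec <- function(shape = c("sinusoid", "straight"),
                        amplitude_um = 500, period_um = 5000,
                        center_um = NULL) {
  shape <- match.arg(shape)
  structure(list(shape = shape, amplitude_um = amplitude_um,
                 period_um = period_um, center_um = center_um),
            class = "border_spec")
}

#' Realize a border specification as a curve
#' @param spec a `border_spec`.
#' @param slide_extent_um slide (width, height) in um.
#' @param spacing_um vertex spacing (default 5).
#' @return a `border_curve` oriented with the paratumor side positive (above).
#' @export
true_border_curve <- function(spec, slide_extent_um, spacing_um = 5) {
  W <- slide_extent_um[1]; H <- slide_extent_um[2]
  cy <- spec$center_um %||% (H / 2)
  x <- seq(0, W, by = spacing_um / 2)
  y <- switch(spec$shape,
    straight = rep(cy, length(x)),
    sinusoid = cy + spec$amplitude_um * cos(2 * pi * x / spec$period_um))
  if (any(y <= 0) || any(y >= H))
    stop("geometry error: border leaves the slide vertically", call. = FALSE)
  border_curve(cbind(x, y), spacing_um = spacing_um)
}

#' Layerwise cell-type composition profile
#'
#' A matrix of cell-type fractions (rows = layers -3..-1, +1..+3, distant-,
#' distant+; columns = the ten cell types). Every row must sum to 1.
#' @param mat numeric matrix with the required dimnames.
#' @return a validated `composition_profile` matrix.
#' @export
composition_profile <- function(mat) {
  need_rows <- c("-3", "-2", "-1", "+1", "+2", "+3", "distant-", "distant+")
  if (!all(need_rows %in% rownames(mat)))
    stop("config error: composition profile must have rows ",
         paste(need_rows, collapse = ", "), call. = FALSE)
  if (!all(CELL_TYPES %in% colnames(mat)))
    stop("config error: composition profile must have columns for all cell types",
         call. = FALSE)
  mat <- mat[need_rows, CELL_TYPES]
  if (any(mat < 0)) stop("config error: negative fractions", call. = FALSE)
  bad <- abs(rowSums(mat) - 1) > 1e-9
  if (any(bad))
    stop("config error: layer fractions must sum to 1 (rows: ",
         paste(rownames(mat)[bad], collapse = ", "), ")", call. = FALSE)
  structure(mat, class = c("composition_profile", "matrix"))
}

#' Default layer composition profile
#'
#' The tumor-side gradients reproduce the printed margin-area values:
#' macrophages rise from 3.9% (layer -3) to 8.6% (layer -1), exhausted T cells
#' from 0.09% to 0.54%, and total immune cells exceed 30% of all cell
#' components in layer -1. Paratumor layers are hepatocyte-dominated.
#' Gradients of the remaining types fall off with distance from the border.
#' @return a `composition_profile`.
#' @export
default_composition_profile <- function() {
  m <- rbind(
    #          malig   hep    mac   T/NK   exhT     B  plasma    DC   endo  fibro
    "-3"       = c(70.0, 1.0, 3.90,  6.0, 0.09, 2.5, 1.5, 1.5, 5.0, 8.51),
    "-2"       = c(62.0, 1.0, 6.00,  8.0, 0.25, 3.5, 2.0, 2.0, 6.0, 9.25),
    "-1"       = c(50.0, 1.0, 8.60, 12.0, 0.54, 5.0, 3.0, 3.0, 6.0, 10.86),
    "+1"       = c( 2.0, 65.0, 5.50,  7.0, 0.20, 3.0, 2.0, 1.5, 5.0, 8.80),
    "+2"       = c( 1.0, 75.0, 3.50,  4.5, 0.10, 2.0, 1.5, 1.0, 4.5, 6.90),
    "+3"       = c( 0.5, 80.0, 2.80,  3.5, 0.06, 1.5, 1.0, 1.0, 4.0, 5.64),
    "distant-" = c(78.0, 0.5, 3.00,  4.0, 0.05, 1.5, 1.0, 1.0, 4.5, 6.45),
    "distant+" = c( 0.2, 85.0, 2.50,  2.5, 0.03, 1.0, 0.8, 0.8, 3.5, 3.67))
  colnames(m) <- CELL_TYPES
  composition_profile(m / 100)
}

#' Default synthetic expression model
#'
#' Defines gene identities, marker panels, baseline abundances and the count
#' model. Each of the nine primary types has `markers_per_type` private
#' markers up-weighted by `2^log2fc`; T/NK cells carry additional subtype
#' markers (conventional vs exhausted); hepatocytes carry one of two programs:
#' GS1 (SAA1/SAA2 plus acute-phase genes, the SAA-high "Hep1" state) or GS2
#' (the SAA-low "Hep2" state). Per-spot depth is negative binomial.
#'
#' @param n_genes total gene count (default 200; 130 structured + background).
#' @param markers_per_type markers per panel (default 10).
#' @param log2fc marker log2 fold-change over baseline (default 3).
#' @param depth_mean,depth_dispersion negative binomial depth model (defaults
#'   2000 and 0.5; variance = mu + dispersion * mu^2).
#' @param hep1_fraction fraction of layer +1 hepatocytes in the SAA-high state
#'   (default 0.5).
#' @return an `expression_model` list.
#' @export
default_expression_model <- function(n_genes = 200, markers_per_type = 10,
                                     log2fc = 3, depth_mean = 2000,
                                     depth_dispersion = 0.5,
                                     hep1_fraction = 0.5) {
  k <- markers_per_type
  panels <- list(
    "malignant"   = sprintf("MAL%02d", 1:k),
    "hepatocyte"  = sprintf("HEP%02d", 1:k),
    "macrophage"  = sprintf("MAC%02d", 1:k),
    "T/NK"        = sprintf("TNK%02d", 1:k),
    "B"           = sprintf("BCL%02d", 1:k),
    "plasma"      = sprintf("PLS%02d", 1:k),
    "DC"          = sprintf("DCC%02d", 1:k),
    "endothelial" = sprintf("END%02d", 1:k),
    "fibroblast"  = sprintf("FIB%02d", 1:k))
  subtype_panels <- list(
    "conventional" = sprintf("TCV%02d", 1:k),
    "exhausted"    = sprintf("TEX%02d", 1:k))
  gs1 <- c("SAA1", "SAA2", sprintf("APR%02d", seq_len(max(k - 2, 0))))
  gs2 <- sprintf("HLP%02d", 1:k)
  structured <- c(unlist(panels, use.names = FALSE),
                  unlist(subtype_panels, use.names = FALSE), gs1, gs2)
  n_bg <- n_genes - length(structured)
  if (n_bg < 10)
    stop("n_genes too small for the marker panels (need >= ",
         length(structured) + 10, ")", call. = FALSE)
  genes <- c(structured, sprintf("BG%03d", seq_len(n_bg)))
  # baseline relative abundances: mildly lognormal, deterministic
  baseline <- with_seed(20260101, stats::rlnorm(length(genes), 0, 0.4))
  names(baseline) <- genes
  structure(list(genes = genes, baseline = baseline, panels = panels,
                 subtype_panels = subtype_panels, gs1 = gs1, gs2 = gs2,
                 log2fc = log2fc, depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 hep1_fraction = hep1_fraction),
            class = "expression_model")
}

# Expression classes: the concrete transcriptional states spots are drawn
# from. Returns a classes x genes matrix of multinomial probabilities.
expression_class_probs <- function(model) {
  fc <- 2^model$log2fc
  up <- list(
    "malignant"       = model$panels[["malignant"]],
    "hepatocyte_Hep1" = c(model$panels[["hepatocyte"]], model$gs1),
    "hepatocyte_Hep2" = c(model$panels[["hepatocyte"]], model$gs2),
    "macrophage"      = model$panels[["macrophage"]],
    "T/NK"            = c(model$panels[["T/NK"]], model$subtype_panels[["conventional"]]),
    "exhausted-T"     = c(model$panels[["T/NK"]], model$subtype_panels[["exhausted"]]),
    "B"               = model$panels[["B"]],
    "plasma"          = model$panels[["plasma"]],
    "DC"              = model$panels[["DC"]],
    "endothelial"     = model$panels[["endothelial"]],
    "fibroblast"      = model$panels[["fibroblast"]])
  probs <- matrix(rep(model$baseline, each = length(up)), nrow = length(up),
                  dimnames = list(names(up), model$genes))
  for (cl in names(up)) probs[cl, up[[cl]]] <- probs[cl, up[[cl]]] * fc
  probs / rowSums(probs)
}

# Balanced draw from a composition: exact largest-remainder counts, randomly
# permuted over the group's spots. The realized composition matches the
# profile at the realized n (up to rounding), so downstream recovery error
# reflects the pipeline, not simulator sampling noise.
balanced_types <- function(n, fractions) {
  counts <- apportion_counts(n, fractions)
  sample(rep(names(fractions), counts))
}

#' Generate a ground-truthed synthetic slide
#'
#' Lays pseudo-spots on the bin50 grid, assigns each a true cell type from its
#' layer's composition profile (balanced draw), marks SAA-high hepatocytes in
#' the first paratumor layer, and draws gene counts from the expression model
#' (negative binomial depth, multinomial-Poisson genes with the type's markers
#' up-weighted). GEM records are placed at per-DNB bin coordinates inside each
#' spot's window, so bin aggregation is exercised end to end.
#'
#' @param config a [slide_config()].
#' @param border a [border_spec()].
#' @param profile a [composition_profile()].
#' @param model an [default_expression_model()].
#' @param seed integer seed (defaults to `config$rng_seed`).
#' @param spot_bins bins per spot edge (default 50, the bin50 grid).
#' @param tangential_archetypes optional list with `labels` (archetype id per
#'   tangential segment) and `compositions` (archetypes x nonparenchymal-types
#'   fraction matrix); when given, the nonparenchymal composition of layers
#'   +-1 follows the per-segment archetype.
#' @param n_segments tangential truth segments in the invasive zone (default
#'   100).
#' @param archetype_sd lognormal jitter applied to per-segment archetype
#'   compositions (default 0.15).
#' @return a `synthetic_slide`: list with `gem` (gem_table), `truth` (per-spot
#'   annotation with true type, subtype, hep class, layer, segment, signed
#'   distance), `border_xy` (truth polyline), `curve` (truth border_curve),
#'   `config`, `model`, `profile`, `archetype_labels`.
#' @export
generate_slide <- function(config = slide_config(),
                           border = border_spec(),
                           profile = default_composition_profile(),
                           model = default_expression_model(),
                           seed = config$rng_seed,
                           spot_bins = 50L,
                           tangential_archetypes = NULL,
                           n_segments = 100L,
                           archetype_sd = 0.15) {
  set.seed(seed)
  pitch <- config$bin_pitch_um
  W <- config$slide_extent_um[1]; H <- config$slide_extent_um[2]
  edge <- spot_bins * pitch
  nx <- floor(W / edge); ny <- floor(H / edge)
  grid <- data.table::CJ(gx = 0:(nx - 1), gy = 0:(ny - 1))
  grid[, `:=`(x_um = (gx + 0.5) * edge, y_um = (gy + 0.5) * edge,
              spot_id = paste0("s", gx, "_", gy))]
  curve <- true_border_curve(border, config$slide_extent_um)
  ds <- signed_distance(curve, cbind(grid$x_um, grid$y_um))
  grid[, `:=`(d_um = ds$d_um, s_um = ds$s_um)]
  grid[, layer := layer_from_distance(d_um)]
  # profile row used for type sampling ("none" falls back to its side's
  # distant profile)
  grid[, region := ifelse(layer == "none",
                          ifelse(d_um >= 0, "distant+", "distant-"), layer)]
  grid[, segment := pmin(pmax(ceiling(s_um / curve$L * n_segments), 1L),
                         as.integer(n_segments))]

  grid[, truth_type := NA_character_]
  if (is.null(tangential_archetypes)) {
    for (rg in unique(grid$region)) {
      idx <- which(grid$region == rg)
      data.table::set(grid, i = idx, j = "truth_type",
                      value = balanced_types(length(idx), profile[rg, ]))
    }
    arch_labels <- NULL
  } else {
    labels <- tangential_archetypes$labels
    comps <- tangential_archetypes$compositions
    if (is.null(dim(comps)) || nrow(comps) < 2)
      stop("config error: need at least 2 archetypes", call. = FALSE)
    if (length(labels) != n_segments)
      stop("config error: need one archetype label per tangential segment",
           call. = FALSE)
    nonpar <- colnames(comps)
    for (rg in setdiff(unique(grid$region), c("-1", "+1"))) {
      idx <- which(grid$region == rg)
      data.table::set(grid, i = idx, j = "truth_type",
                      value = balanced_types(length(idx), profile[rg, ]))
    }
    for (rg in intersect(c("-1", "+1"), unique(grid$region))) {
      base <- profile[rg, ]
      f_par <- sum(base[PARENCHYMAL_TYPES])
      for (seg in unique(grid$segment[grid$region == rg])) {
        idx <- which(grid$region == rg & grid$segment == seg)
        comp <- comps[labels[seg], ]
        comp <- comp * exp(stats::rnorm(length(comp), 0, archetype_sd))
        comp <- comp / sum(comp)
        fr <- stats::setNames(numeric(length(CELL_TYPES)), CELL_TYPES)
        fr[PARENCHYMAL_TYPES] <- base[PARENCHYMAL_TYPES]
        fr[nonpar] <- (1 - f_par) * comp
        fr <- fr / sum(fr)
        data.table::set(grid, i = idx, j = "truth_type",
                        value = balanced_types(length(idx), fr))
      }
    }
    arch_labels <- data.table::data.table(segment = seq_len(n_segments),
                                          archetype = labels)
  }

  # SAA-high hepatocytes confined to the first paratumor layer
  grid[, hep_class := ifelse(truth_type == "hepatocyte", "Hep2", NA_character_)]
  p1_hep <- which(grid$truth_type == "hepatocyte" & grid$layer == "+1")
  n_hep1 <- round(model$hep1_fraction * length(p1_hep))
  if (n_hep1 > 0)
    data.table::set(grid, i = sample(p1_hep, n_hep1), j = "hep_class",
                    value = "Hep1")

  grid[, subtype := data.table::fifelse(
    truth_type == "exhausted-T", "exhausted",
    data.table::fifelse(truth_type == "T/NK", "conventional", NA_character_))]
  grid[, cell_type := ifelse(truth_type == "exhausted-T", "T/NK", truth_type)]
  grid[, expr_class := data.table::fcase(
    truth_type == "hepatocyte" & hep_class == "Hep1", "hepatocyte_Hep1",
    truth_type == "hepatocyte", "hepatocyte_Hep2",
    rep(TRUE, .N), truth_type)]

  # ---- expression -----------------------------------------------------------
  probs <- expression_class_probs(model)
  size <- 1 / model$depth_dispersion
  depth <- stats::rnbinom(nrow(grid), size = size, mu = model$depth_mean)
  gi_list <- list()
  for (cl in rownames(probs)) {
    idx <- which(grid$expr_class == cl)
    if (!length(idx)) next
    lam <- outer(depth[idx], probs[cl, ])
    cnt <- matrix(stats::rpois(length(lam), lam), nrow = length(idx))
    nz <- which(cnt > 0, arr.ind = TRUE)
    gi_list[[cl]] <- data.table::data.table(
      spot = idx[nz[, 1]], gene_i = nz[, 2],
      count = cnt[nz])
    rm(lam, cnt, nz)
  }
  rec <- data.table::rbindlist(gi_list)
  rm(gi_list)
  # per-DNB coordinates: each (spot, gene) record lands on a random bin inside
  # the spot's window
  rec[, `:=`(
    x = grid$gx[spot] * spot_bins + sample.int(spot_bins, .N, replace = TRUE) - 1L,
    y = grid$gy[spot] * spot_bins + sample.int(spot_bins, .N, replace = TRUE) - 1L,
    gene = model$genes[gene_i])]
  gem <- as_gem_table(rec[, c("gene", "x", "y", "count")])

  truth <- grid[, c("spot_id", "x_um", "y_um", "cell_type", "subtype",
                    "hep_class", "truth_type", "layer", "segment", "d_um",
                    "s_um")]
  data.table::setnames(truth, "layer", "truth_layer")
  structure(list(gem = gem, truth = truth,
                 border_xy = curve_vertices(curve), curve = curve,
                 config = config, model = model, profile = profile,
                 archetype_labels = arch_labels, seed = seed),
            class = "synthetic_slide")
}

#' @export
print.synthetic_slide <- function(x, ...) {
  cat(sprintf("synthetic_slide: %d spots, %d GEM records, seed %d\n",
              nrow(x$truth), nrow(x$gem), x$seed))
  invisible(x)
}

#' Default tangential composition archetypes
#'
#' Five nonparenchymal composition archetypes for invasive-zone subregions:
#' 1 fibroblast-dominant, 2 fibroblast+macrophage, 3 macrophage-dominant,
#' 4 B+T/NK, 5 endothelial-dominant.
#' @return 5 x 7 fraction matrix (rows sum to 1).
#' @export
default_pattern_archetypes <- function() {
  m <- rbind(
    P1 = c(0.04, 0.06, 0.04, 0.04, 0.02, 0.08, 0.72),
    P2 = c(0.42, 0.04, 0.03, 0.02, 0.04, 0.03, 0.42),
    P3 = c(0.76, 0.06, 0.04, 0.03, 0.07, 0.02, 0.02),
    P4 = c(0.03, 0.40, 0.36, 0.12, 0.05, 0.02, 0.02),
    P5 = c(0.04, 0.05, 0.03, 0.02, 0.02, 0.72, 0.12))
  colnames(m) <- c("macrophage", "T/NK", "B", "plasma", "DC", "endothelial",
                   "fibroblast")
  stopifnot(all(abs(rowSums(m) - 1) < 1e-9))
  m
}

#' Cohort-slide layer composition
#'
#' Same layer structure as [default_composition_profile()] but with an
#' immune-active invasive zone: the parenchymal share of the two first layers
#' is reduced so that tangential subregions carry enough nonparenchymal cells
#' for composition patterns to be well determined at 100 subregions per
#' slide. The paratumor first layer keeps a hepatocyte majority so the
#' hepatocyte mask (and hence border extraction) stays well defined.
#' @return a `composition_profile`.
#' @export
cohort_composition_profile <- function() {
  m <- unclass(default_composition_profile())
  adjust <- function(row, malig, hep) {
    nonpar <- row[!names(row) %in% PARENCHYMAL_TYPES]
    row[["malignant"]] <- malig; row[["hepatocyte"]] <- hep
    row[!names(row) %in% PARENCHYMAL_TYPES] <-
      nonpar / sum(nonpar) * (1 - malig - hep)
    row
  }
  m["-1", ] <- adjust(m["-1", ], 0.24, 0.01)
  m["+1", ] <- adjust(m["+1", ], 0.02, 0.58)
  composition_profile(m)
}

#' Default recurrence mixture over archetypes
#'
#' Recurrent patients over-represent archetype 3 (macrophage-dominant) and
#' non-recurrent patients archetype 1 (fibroblast-dominant); the planted odds
#' ratio for archetype 3 (recurrent vs non-recurrent) is 3.
#' @return list with `recurrent` and `nonrecurrent` probability vectors.
#' @export
default_recurrence_mixture <- function() {
  list(recurrent = c(P1 = 1, P2 = 1, P3 = 2, P4 = 1, P5 = 1) / 6,
       nonrecurrent = c(P1 = 3, P2 = 1, P3 = 1, P4 = 1, P5 = 1) / 7)
}

#' Generate a synthetic patient cohort
#'
#' Each patient contributes `slides_per_patient` margin slides; each slide's
#' invasive-zone tangential segments are planted with composition archetypes
#' drawn from the patient's recurrence-dependent mixture, in contiguous blocks
#' of `block` segments (emulating spatially autocorrelated niches).
#'
#' @param n_patients number of patients (default 16).
#' @param slides_per_patient margin slides per patient (default 2, giving
#'   16 x 2 x 100 candidate subregions).
#' @param archetypes archetype composition matrix
#'   ([default_pattern_archetypes()]).
#' @param recurrence_mixture list of per-class archetype probabilities
#'   ([default_recurrence_mixture()]); pass identical vectors for a null
#'   cohort.
#' @param recurrent_fraction fraction of recurrent patients (default 0.5).
#' @param seed integer master seed; per-slide seeds are derived.
#' @param config slide configuration for cohort slides (default 5 x 2.5 mm).
#' @param border border specification (default gentle sinusoid).
#' @param profile base layer composition.
#' @param model expression model.
#' @param block archetype block length in segments (default 10).
#' @param n_segments tangential segments per slide (default 100).
#' @param process optional `function(slide, slide_id, patient_id)`; when
#'   given, each generated slide is passed through it immediately and only
#'   the returned value is stored, so a full cohort can be processed in
#'   bounded memory (one slide held at a time).
#' @return a `synthetic_cohort`: list with `slides` (slide objects, or
#'   `process()` results), `patients` (data.table: patient_id, recurrence,
#'   slide_ids), `truth_labels` (patient, slide, segment, archetype),
#'   `archetypes`.
#' @export
generate_cohort <- function(n_patients = 16, slides_per_patient = 2,
                            archetypes = default_pattern_archetypes(),
                            recurrence_mixture = default_recurrence_mixture(),
                            recurrent_fraction = 0.5,
                            seed = 1L,
                            config = slide_config(slide_extent_um = c(6000, 2500)),
                            border = border_spec(amplitude_um = 300,
                                                 period_um = 6000,
                                                 center_um = 1250),
                            profile = cohort_composition_profile(),
                            model = default_expression_model(),
                            block = 10L, n_segments = 100L,
                            process = NULL) {
  if (nrow(archetypes) < 2)
    stop("config error: need at least 2 archetypes", call. = FALSE)
  set.seed(seed)
  n_rec <- round(recurrent_fraction * n_patients)
  recurrence <- sample(rep(c(TRUE, FALSE), c(n_rec, n_patients - n_rec)))
  slides <- list(); labels <- list(); meta <- list()
  slide_no <- 0L
  for (p in seq_len(n_patients)) {
    pid <- sprintf("patient%02d", p)
    mix <- if (recurrence[p]) recurrence_mixture$recurrent
           else recurrence_mixture$nonrecurrent
    mix <- mix / sum(mix)
    sids <- character(slides_per_patient)
    for (sl in seq_len(slides_per_patient)) {
      slide_no <- slide_no + 1L
      sid <- sprintf("%s_slide%d", pid, sl)
      sids[sl] <- sid
      n_blocks <- ceiling(n_segments / block)
      seg_labels <- rep(sample(rownames(archetypes), n_blocks, replace = TRUE,
                               prob = mix), each = block)[seq_len(n_segments)]
      slide_seed <- (seed * 10000L + slide_no * 131L) %% .Machine$integer.max
      slide <- generate_slide(
        config = config, border = border, profile = profile, model = model,
        seed = slide_seed,
        tangential_archetypes = list(labels = seg_labels,
                                     compositions = archetypes),
        n_segments = n_segments)
      if (is.null(process)) {
        slides[[sid]] <- slide
      } else {
        # shield the cohort's RNG stream from whatever process() draws
        rng <- get(".Random.seed", envir = globalenv())
        slides[[sid]] <- process(slide, sid, pid)
        assign(".Random.seed", rng, envir = globalenv())
      }
      rm(slide)
      labels[[sid]] <- data.table::data.table(
        patient_id = pid, slide_id = sid, segment = seq_len(n_segments),
        archetype = seg_labels)
    }
    meta[[pid]] <- data.table::data.table(
      patient_id = pid, recurrence = recurrence[p],
      slide_ids = paste(sids, collapse = ","))
  }
  structure(list(slides = slides,
                 patients = data.table::rbindlist(meta),
                 truth_labels = data.table::rbindlist(labels),
                 archetypes = archetypes),
            class = "synthetic_cohort")
}
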