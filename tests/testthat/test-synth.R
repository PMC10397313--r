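test_that("generation is deterministic under a fixed seed", {
  cfg <- slide_config(slide_extent_um = c(1000, 1000), rng_seed = 3L)
  bs <- border_spec("straight", center_um = 500)
  a <- generate_slide(config = cfg, border = bs, seed = 3)
  b <- generate_slide(config = cfg, border = bs, seed = 3)
  expect_identical(data.frame(a$gem), data.frame(b$gem))
  expect_identical(data.frame(a$truth), data.frame(b$truth))
})

test_that("a degenerate all-hepatocyte profile yields a single cell type", {
  m <- matrix(0, 8, 10, dimnames = list(
    c("-3", "-2", "-1", "+1", "+2", "+3", "distant-", "distant+"),
    c("malignant", "hepatocyte", "macrophage", "T/NK", "exhausted-T", "B",
      "plasma", "DC", "endothelial", "fibroblast")))
  m[, "hepatocyte"] <- 1
  sl <- generate_slide(config = slide_config(slide_extent_um = c(1000, 1000)),
                       border = border_spec("straight", center_um = 500),
                       profile = composition_profile(m), seed = 1)
  expect_equal(unique(sl$truth$truth_type), "hepatocyte")
})

test_that("profile and geometry validation raises config errors", {
  m <- unclass(default_composition_profile())
  m[1, 1] <- m[1, 1] + 0.05
  expect_error(composition_profile(m), "sum to 1")
  expect_error(
    generate_slide(config = slide_config(slide_extent_um = c(2000, 500)),
                   border = border_spec(amplitude_um = 400, center_um = 250)),
    "geometry error")
})

test_that("realized layer fractions match the profile within binomial CIs", {
  sl <- fx_slide()
  truth <- sl$truth
  prof <- default_composition_profile()
  n1 <- sum(truth$truth_layer == "-1")
  p_hat <- mean(truth$truth_type[truth$truth_layer == "-1"] == "macrophage")
  ci <- qbinom(c(0.005, 0.995), n1, 0.086) / n1
  expect_gte(p_hat, ci[1])
  expect_lte(p_hat, ci[2])
  # balanced allocation tracks every layer's profile closely
  for (lay in c("-3", "-2", "+1")) {
    idx <- truth$truth_layer == lay
    frac <- table(factor(truth$truth_type[idx],
                         levels = colnames(prof))) / sum(idx)
    expect_lt(max(abs(frac - prof[lay, ])), 0.005)
  }
})

test_that("per-spot depth sits in the observed per-spot range", {
  sl <- fx_slide()
  depth <- Matrix::rowSums(aggregate_bins(sl$gem, 50)$counts)
  expect_gt(median(depth), 589)
  expect_lt(median(depth), 4642)
})

test_that("truth layers agree with an independent distance oracle", {
  sl <- fx_slide()
  truth <- sl$truth[sample.int(nrow(sl$truth), 500), ]
  # brute force: nearest vertex on a densely resampled truth border
  dense <- invasiveZone:::resample_polyline(sl$border_xy, 0.5)
  d_bf <- vapply(seq_len(nrow(truth)), function(i) {
    dd <- sqrt((dense[, 1] - truth$x_um[i])^2 + (dense[, 2] - truth$y_um[i])^2)
    min(dd) * sign(truth$y_um[i] - dense[which.min(dd), 2])
  }, numeric(1))
  expect_lt(max(abs(abs(d_bf) - abs(truth$d_um))), 1)
  # spots within a micron of a band boundary may flip bands between the two
  # distance computations; compare the rest exactly
  away <- abs(abs(d_bf) %% 250 - 0) > 2 & abs(abs(d_bf) %% 250 - 250) > 2
  expect_gt(mean(away), 0.95)
  expect_equal(layer_from_distance(d_bf)[away], truth$truth_layer[away])
})

test_that("Hep1 spots are confined to the first paratumor layer", {
  truth <- fx_slide()$truth
  hep1 <- truth[truth$hep_class %in% "Hep1", ]
  expect_gt(nrow(hep1), 50)
  expect_equal(unique(hep1$truth_layer), "+1")
  expect_equal(mean(truth$hep_class[truth$truth_layer == "+1" &
                                      truth$truth_type == "hepatocyte"] == "Hep1"),
               0.5, tolerance = 0.01)
})

test_that("cohort generation plants archetypes with the requested structure", {
  co <- generate_cohort(n_patients = 4, slides_per_patient = 1, seed = 11,
                        config = slide_config(slide_extent_um = c(2000, 1500)),
                        border = border_spec(amplitude_um = 100,
                                             period_um = 2000,
                                             center_um = 750))
  expect_length(co$slides, 4)
  expect_equal(nrow(co$patients), 4)
  expect_equal(nrow(co$truth_labels), 400)
  expect_true(all(co$truth_labels$archetype %in% rownames(co$archetypes)))
  # truth labels recorded per tangential segment, one per (slide, t)
  expect_equal(unname(table(co$truth_labels$slide_id)), rep(100L, 4),
               ignore_attr = TRUE)
  expect_error(generate_cohort(n_patients = 2,
                               archetypes = default_pattern_archetypes()[1, ,
                                                                         drop = FALSE]),
               "at least 2 archetypes")
})

test_that("planted recurrence mixture skews archetype frequencies as designed", {
  co <- generate_cohort(n_patients = 10, slides_per_patient = 1, seed = 2,
                        config = slide_config(slide_extent_um = c(2000, 1500)),
                        border = border_spec(amplitude_um = 100,
                                             period_um = 2000,
                                             center_um = 750))
  lab <- merge(co$truth_labels, co$patients, by = "patient_id")
  p3_rec <- mean(lab$archetype[lab$recurrence] == "P3")
  p3_non <- mean(lab$archetype[!lab$recurrence] == "P3")
  or3 <- (p3_rec / (1 - p3_rec)) / (p3_non / (1 - p3_non))
  expect_gt(or3, 1.5) # planted odds ratio 3, allowing sampling noise
  p1_non <- mean(lab$archetype[!lab$recurrence] == "P1")
  p1_rec <- mean(lab$archetype[lab$recurrence] == "P1")
  expect_gt(p1_non, p1_rec)
})
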