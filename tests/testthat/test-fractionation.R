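test_that("fraction filter implements the inclusive conjunction rule", {
  cfg <- filter_config()
  expect_equal(classify_fraction(0.70, 1.2, 1e7, cfg), "fully_evolved_pellet")
  expect_equal(classify_fraction(0.20, 2.5, 1e5, cfg), "hyphae_or_clumps")
  # thresholds are inclusive
  expect_equal(classify_fraction(cfg$pellet_min_Mo, cfg$pellet_max_E,
                                 cfg$pellet_min_area_um2, cfg),
               "fully_evolved_pellet")
  # failing any one criterion demotes to hyphae/clumps
  expect_equal(classify_fraction(0.70, 2.5, 1e7, cfg), "hyphae_or_clumps")
  expect_equal(classify_fraction(0.70, 1.2, 5e3, cfg), "hyphae_or_clumps")

  expect_error(filter_config(pellet_min_Mo = 1.2), class = "mycomorph_parameter_error")
})

test_that("species attribution follows vessel, size split, review band and overrides", {
  cfg <- filter_config()
  # monoculture: vessel identity regardless of shape
  mono <- attribute_species(c("fully_evolved_pellet", "hyphae_or_clumps"),
                            c(1e7, 1e4), "monoB", cfg)
  expect_equal(mono$species, c("B", "B"))

  # coculture pellets split by size; hyphae/clumps undetermined
  co <- attribute_species(
    c("fully_evolved_pellet", "fully_evolved_pellet", "hyphae_or_clumps"),
    c(1.3e7, 2.9e5, 1e5), "coculture", cfg)
  expect_equal(co$species, c("A", "B", "undetermined"))
  expect_false(any(co$review))

  # within +/-20% of the size threshold the call is flagged for review
  edge <- attribute_species("fully_evolved_pellet", 1.1e6, "coculture", cfg)
  expect_true(edge$review)
  expect_equal(edge$species, "A")

  # operator override always wins and is recorded
  ov <- attribute_species("hyphae_or_clumps", 1e5, "coculture", cfg,
                          override_species = "B")
  expect_equal(ov$species, "B")
  expect_equal(ov$provenance, "operator")
})

test_that("classify_objects is exhaustive, order-preserving and deterministic", {
  expect_equal(nrow(classify_objects(measure_objects(
    mycomorph:::as_labeled_mask(matrix(0L, 16, 16),
                                calibrated_image(matrix(0.5, 16, 16), 1))))), 0)

  m <- tibble::tibble(
    experiment = "E", culture = "coculture", time_h = 24, label = 1:4,
    area_um2 = c(2e6, 3e5, 8e4, 5e3), perimeter_um = 1, feret_max_um = 2,
    feret_min_um = 1, circularity = 0.5,
    elongation = c(1.2, 1.4, 2.4, 3.0),
    morphology_number = c(0.6, 0.5, 0.2, 0.1),
    centroid_x_um = 0, centroid_y_um = 0, border_touching = FALSE)
  c1 <- classify_objects(m)
  expect_equal(c1$label, 1:4)
  expect_equal(c1$fraction, c("fully_evolved_pellet", "fully_evolved_pellet",
                              "hyphae_or_clumps", "hyphae_or_clumps"))
  expect_equal(c1$species, c("A", "B", "undetermined", "undetermined"))
  expect_true(all(!is.na(c1$fraction) & !is.na(c1$species)))
  expect_identical(c1, classify_objects(m))

  ov <- tibble::tibble(experiment = "E", time_h = 24, label = 3L, species = "B")
  c2 <- classify_objects(m, overrides = ov)
  expect_equal(c2$species[3], "B")
  expect_equal(c2$provenance[3], "operator")
  expect_error(classify_objects(m, overrides = dplyr::mutate(ov, label = 9L)),
               class = "mycomorph_edit_error")
})

test_that("auto-classification reaches 95% accuracy on band-separated populations", {
  pops <- dplyr::bind_rows(
    population_spec("pellet", count = 5, mean_area_um2 = 3e6, species = "A"),
    population_spec("pellet", count = 10, mean_area_um2 = 2e5, species = "B"),
    population_spec("clump", count = 8, mean_area_um2 = 3e4, species = "B"),
    population_spec("hypha", count = 7, species = "B"))
  res <- run_pipeline(pops, seed = 31, image_size = c(1280L, 1280L), scale_um = 8)
  cl <- res$classified
  # match measured objects to truth by centroid proximity via overlap table
  mt <- match_truth(res$rendered$mask, unclass(res$mask))
  truth <- res$rendered$truth
  joined <- dplyr::inner_join(mt, dplyr::select(truth, truth = label, kind,
                                                true_species),
                              by = "truth")
  joined <- dplyr::inner_join(joined, dplyr::select(cl, seg = label, fraction,
                                                    species),
                              by = "seg")
  truth_fraction <- ifelse(joined$kind == "pellet", "fully_evolved_pellet",
                           "hyphae_or_clumps")
  truth_species <- ifelse(truth_fraction == "fully_evolved_pellet",
                          joined$true_species, "undetermined")
  acc <- mean(joined$fraction == truth_fraction & joined$species == truth_species)
  expect_gte(acc, 0.95)
})

test_that("a coculture without species-A pellets yields zero (A, pellet) calls", {
  pops <- dplyr::bind_rows(
    population_spec("pellet", count = 12, mean_area_um2 = 1.9e4, species = "B"),
    population_spec("clump", count = 8, mean_area_um2 = 1e4, species = "B"))
  res <- run_pipeline(pops, seed = 37, image_size = c(1024L, 1024L))
  cl <- res$classified
  expect_equal(sum(cl$fraction == "fully_evolved_pellet" & cl$species == "A"), 0)
  expect_gt(sum(cl$fraction == "fully_evolved_pellet" & cl$species == "B"), 0)
})
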