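test_that("median preprocessing is identity at radius 0 and removes salt noise", {
  img <- calibrated_image(matrix(0.5, 32, 32), scale_um = 1)
  expect_identical(preprocess(img, 0)$pixels, img$pixels)

  salt <- img
  salt$pixels[16, 16] <- 1
  sm <- preprocess(salt, 2)
  expect_equal(sm$pixels[16, 16], 0.5, tolerance = 1e-4)
})

test_that("median filtering reduces noise against the noise-free twin", {
  o <- synthetic_object("pellet", area_um2 = 2e4, center_x_um = 128, center_y_um = 128)
  noisy <- render_scene(build_scene(o, image_size = c(128L, 128L), scale_um = 2,
                                    noise_sd = 0.05, seed = 3))
  clean <- render_scene(build_scene(o, image_size = c(128L, 128L), scale_um = 2,
                                    noise_sd = 0, seed = 3))
  before <- sd(noisy$image$pixels - clean$image$pixels)
  after <- sd(preprocess(noisy$image, 2)$pixels - clean$image$pixels)
  expect_lt(after, before)
})

test_that("Sobel gradient is zero on flat fields and peaks on edges", {
  flat <- calibrated_image(matrix(0.3, 24, 24), scale_um = 1)
  expect_true(all(abs(detect_edges(flat)) < 1e-12))

  step <- calibrated_image(cbind(matrix(0, 24, 12), matrix(1, 24, 12)), scale_um = 1)
  g <- detect_edges(step)
  expect_true(all(apply(g[3:22, ], 1, which.max) %in% 12:13))

  # ring response at the boundary radius of a smooth disk
  o <- synthetic_object("pellet", area_um2 = pi * 100^2,
                        center_x_um = 150, center_y_um = 150)
  r <- render_scene(build_scene(o, image_size = c(300L, 300L), scale_um = 1,
                                noise_sd = 0, halo = 0, seed = 1))
  g <- detect_edges(r$image)
  ray <- g[150, 150:300]
  expect_lt(abs(which.max(ray) - 1 - 100), 2.5)
})

test_that("segmentation recovers disjoint objects and filters specks", {
  expect_warning(
    mask <- segment_image(calibrated_image(matrix(0.5, 64, 64), scale_um = 2)),
    "uniform")
  expect_equal(max(mask), 0L)

  # noise-only scene -> zero objects after the area filter
  blank <- build_scene(mycomorph:::object_spec_tibble(), image_size = c(256L, 256L),
                       scale_um = 2, seed = 4)
  rb <- render_scene(blank)
  expect_warning(mb <- segment_image(rb$image), "zero objects")
  expect_equal(max(mb), 0L)

  two <- dplyr::bind_rows(
    synthetic_object("pellet", area_um2 = 3e4, center_x_um = 250, center_y_um = 250),
    synthetic_object("pellet", area_um2 = 3e4, center_x_um = 700, center_y_um = 700,
                     species = "B"))
  r <- render_scene(build_scene(two, image_size = c(512L, 512L), scale_um = 2,
                                seed = 2))
  mask <- segment_image(r$image)
  expect_equal(max(mask), 2L)
  sizes <- tabulate(mask[mask != 0]) * 4  # px -> um^2 at 2 um/px
  expect_true(all(abs(sort(sizes) / sort(r$truth$true_area_um2_raster) - 1) < 0.05))

  # a 100 um^2 speck dies under the default 500 um^2 area filter,
  # identically at 1 and 2 um/px (resolution-invariant physical filter)
  for (s in c(1, 2)) {
    o <- synthetic_object("pellet", area_um2 = 100, center_x_um = 100, center_y_um = 100)
    rs <- render_scene(build_scene(o, image_size = c(100L, 100L), scale_um = s,
                                   noise_sd = 0.02, seed = 1))
    expect_warning(ms <- segment_image(rs$image), "zero objects")
    expect_equal(max(ms), 0L)
  }
})

test_that("labels partition the foreground and segmentation is idempotent", {
  pops <- dplyr::bind_rows(
    population_spec("pellet", count = 4, mean_area_um2 = 4e4),
    population_spec("hypha", count = 3, length_range_um = c(100, 200)))
  res <- run_pipeline(pops, seed = 6, image_size = c(768L, 768L))
  mask <- res$mask
  seg_fg <- mask != 0
  expect_true(all(mask[seg_fg] >= 1))

  # re-segmenting a clean rendering of the mask reproduces its components
  binary <- calibrated_image(1 - 0.6 * (unclass(mask) > 0), scale_um = 2)
  again <- segment_image(binary, segmentation_params(median_radius = 0,
                                                     min_object_area_um2 = 0,
                                                     exclude_border = FALSE))
  expect_equal(max(again), max(mask))
  expect_true(all((again != 0) == seg_fg))
})

test_that("pipeline recall and per-object area error meet the QC bar", {
  pops <- dplyr::bind_rows(
    population_spec("pellet", count = 8, mean_area_um2 = 1e5),
    population_spec("clump", count = 6, mean_area_um2 = 3e4),
    population_spec("hypha", count = 6))
  res <- run_pipeline(pops, seed = 17)
  m <- match_truth(res$rendered$mask, unclass(res$mask))
  truth_px <- tabulate(res$rendered$mask[res$rendered$mask != 0])
  recovered <- m$overlap >= 0.5
  expect_gte(mean(recovered), 0.95)
  area_err <- abs(m$seg_px[recovered] / truth_px[m$truth[recovered]] - 1)
  expect_lte(mean(area_err), 0.05)
})

test_that("operator overrides edit masks reproducibly", {
  img <- calibrated_image(matrix(0.8, 20, 20), scale_um = 1)
  lab <- matrix(0L, 20, 20)
  lab[3:6, 3:6] <- 1L
  lab[3:6, 7:10] <- 2L   # abuts label 1
  lab[14:17, 14:17] <- 3L
  mask <- mycomorph:::as_labeled_mask(lab, img)

  expect_true(all(apply_overrides(mask, NULL) == lab))

  del <- apply_overrides(mask, tibble::tibble(label = 3L, action = "delete", arg = NA))
  expect_identical(sort(unique(as.vector(del[del != 0]))), c(1L, 2L))

  mg <- apply_overrides(mask, tibble::tibble(label = 1L, action = "merge", arg = "2"))
  expect_identical(sort(unique(as.vector(mg[mg != 0]))), c(1L, 3L))
  # the merged region is a single 8-connected component
  relab <- mycomorph:::label_components8(mg == 1L)
  expect_equal(max(relab), 1L)

  sp <- apply_overrides(mask, tibble::tibble(label = 1L, action = "split",
                                             arg = "3,3;6,6"))
  expect_equal(length(unique(sp[lab == 1L])), 2L)

  tagged <- apply_overrides(mask, tibble::tibble(label = 2L, action = "species",
                                                 arg = "B"))
  expect_equal(attr(tagged, "species_tags")$species, "B")

  expect_error(apply_overrides(mask, tibble::tibble(label = 99L, action = "delete",
                                                    arg = NA)),
               class = "mycomorph_edit_error")
})
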