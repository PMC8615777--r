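# Fixture builders shared across the suite.  Everything is generated in
# code; no binary fixtures on disk.

disk_mask <- function(r_px, pad = 6L) {
  n <- 2L * (r_px + pad)
  c0 <- n / 2
  x <- matrix(rep(seq_len(n), each = n), n, n)
  y <- matrix(rep(seq_len(n), times = n), n, n)
  matrix(as.integer((x - c0)^2 + (y - c0)^2 <= r_px^2), n, n)
}

rect_mask <- function(h_px, w_px, pad = 10L) {
  m <- matrix(0L, h_px + 2 * pad, w_px + 2 * pad)
  m[pad + seq_len(h_px), pad + seq_len(w_px)] <- 1L
  m
}

# one fully specified object row (bypasses random placement)
synthetic_object <- function(kind = "pellet", area_um2 = 1e5,
                             fringe_depth_um = 0, fringe_density = 0,
                             axis_ratio = 1, orientation = 0,
                             length_um = NA, thickness_um = NA,
                             tortuosity = 0, center_x_um = NA, center_y_um = NA,
                             species = "A", shape_seed = 42L) {
  tibble::tibble(
    kind = kind, true_species = species, true_area_um2 = area_um2,
    core_radius_um = if (kind == "hypha") NA_real_ else sqrt(area_um2 / pi),
    fringe_depth_um = fringe_depth_um, fringe_density = fringe_density,
    axis_ratio = axis_ratio, length_um = length_um, thickness_um = thickness_um,
    orientation = orientation, tortuosity = tortuosity,
    fringe_phase = 0.7, shape_seed = shape_seed,
    center_x_um = center_x_um, center_y_um = center_y_um
  )
}

# render -> segment -> measure -> classify in one go
run_pipeline <- function(populations, seed, image_size = c(1536L, 1536L),
                         scale_um = 2, culture = "coculture",
                         params = segmentation_params(),
                         cfg = filter_config()) {
  objs <- sample_population(populations, seed = seed)
  scene <- build_scene(objs, image_size = image_size, scale_um = scale_um,
                       seed = seed, culture = culture)
  rendered <- render_scene(scene)
  mask <- segment_image(rendered$image, params)
  measured <- measure_objects(mask)
  list(rendered = rendered, mask = mask,
       classified = classify_objects(measured, cfg))
}

# overlap-based matching of segmented labels to ground-truth labels;
# returns per-truth-object best overlap fraction and area of the match
match_truth <- function(truth_mask, seg_mask) {
  idx <- truth_mask != 0 | seg_mask != 0
  tab <- table(truth = truth_mask[idx], seg = seg_mask[idx])
  truth_ids <- setdiff(as.integer(rownames(tab)), 0L)
  truth_sizes <- tabulate(truth_mask[truth_mask != 0])
  seg_sizes <- tabulate(seg_mask[seg_mask != 0])
  purrr::map(truth_ids, function(tid) {
    row <- tab[as.character(tid), ]
    segs <- setdiff(as.integer(names(row)[row > 0]), 0L)
    if (length(segs) == 0)
      return(tibble::tibble(truth = tid, seg = NA_integer_,
                            overlap = 0, seg_px = NA_integer_))
    best <- segs[which.max(row[as.character(segs)])]
    tibble::tibble(truth = tid, seg = best,
                   overlap = row[as.character(best)] / truth_sizes[tid],
                   seg_px = seg_sizes[best])
  }) |> purrr::list_rbind()
}

# null / power simulation for the Welch machinery
simulate_welch_p <- function(n_sim, mean_x, mean_y, n = 30, cv = 0.3) {
  replicate(n_sim, {
    sdlog <- sqrt(log(1 + cv^2))
    x <- rlnorm(n, log(mean_x) - sdlog^2 / 2, sdlog)
    y <- rlnorm(n, log(mean_y) - sdlog^2 / 2, sdlog)
    welch_test(x, y)$p_value
  })
}

# swap the species labels of a classified-equivalent table (and vessels)
swap_species <- function(classified) {
  dplyr::mutate(classified,
    species = dplyr::recode(species, A = "B", B = "A"),
    culture = dplyr::recode(culture, monoA = "monoB", monoB = "monoA"))
}
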