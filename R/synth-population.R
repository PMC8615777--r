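#' Describe a synthetic object population
#'
#' A population spec is the sampling distribution for one class of mycelial
#' objects in a synthetic scene: fully evolved pellets (compact fringed
#' disks), clumps (unions of jittered ellipses) or hyphal fragments
#' (constant-thickness tubes along a smooth curve).  Projected areas are
#' drawn log-normally with the requested mean and coefficient of variation;
#' shape parameters are drawn from the distributions below.  The defaults
#' are calibrated so that, after rasterisation, segmentation and
#' measurement, pellets land in the morphology-number band typical of
#' compact pellets (roughly 0.36-0.77) and hyphae/clumps in the dispersed
#' band (Mo 0.1-0.35, elongation above 1.75).
#'
#' @param kind one of `"pellet"`, `"clump"`, `"hypha"`.
#' @param count number of objects to draw (>= 0).
#' @param mean_area_um2 target mean projected area in square micrometres.
#'   For hyphae `NA` means "draw length and thickness uniformly from
#'   `length_range_um` / `thickness_range_um`" instead of area-driven
#'   sampling.
#' @param cv_area log-normal coefficient of variation of the area (>= 0).
#' @param species true species label, `"A"` or `"B"`.
#' @param fringe_depth_frac pellet hair-fringe depth as a fraction of the
#'   core radius (0 gives a perfectly smooth boundary).
#' @param fringe_density angular density of the fringe in `[0, 1]`; scales
#'   the number of fringe lobes around the circumference.
#' @param axis_ratio_mean,axis_ratio_sd normal draw (truncated at 1) of the
#'   generative axis ratio, i.e. the target Feret elongation of the smooth
#'   shape.
#' @param tortuosity hypha curvature scale (radians of heading swing along
#'   the filament); 0 gives a straight rod.
#' @param length_range_um,thickness_range_um uniform ranges for hyphal
#'   length and thickness in micrometres (thickness must stay below length).
#' @return A one-row tibble; rows for several populations can be combined
#'   with [dplyr::bind_rows()] and fed to [sample_population()].
#' @seealso [sample_population()], [build_scene()]
#' @export
population_spec <- function(kind = c("pellet", "clump", "hypha"),
                            count = 30,
                            mean_area_um2 = switch(match.arg(kind),
                              pellet = 1e5, clump = 3e4, hypha = NA_real_),
                            cv_area = 0.3,
                            species = c("A", "B"),
                            fringe_depth_frac = if (match.arg(kind) == "pellet") 0.10 else 0.25,
                            fringe_density = 0.4,
                            axis_ratio_mean = switch(match.arg(kind),
                              pellet = 1.15, clump = 2.5, hypha = NA_real_),
                            axis_ratio_sd = switch(match.arg(kind),
                              pellet = 0.08, clump = 0.3, hypha = NA_real_),
                            tortuosity = 1.6,
                            length_range_um = c(150, 400),
                            thickness_range_um = c(8, 15)) {
  kind <- match.arg(kind)
  species <- match.arg(species)
  if (count < 0) abort("`count` must be >= 0.", class = "mycomorph_parameter_error")
  if (cv_area < 0) abort("`cv_area` must be >= 0.", class = "mycomorph_parameter_error")
  if (fringe_density < 0 || fringe_density > 1)
    abort("`fringe_density` must lie in [0, 1].", class = "mycomorph_parameter_error")
  if (!is.na(axis_ratio_mean) && axis_ratio_mean < 1)
    abort("`axis_ratio_mean` must be >= 1.", class = "mycomorph_parameter_error")
  if (kind == "hypha" && max(thickness_range_um) >= min(length_range_um))
    abort("hyphal thickness range must lie below the length range.",
          class = "mycomorph_parameter_error")
  tibble(
    kind = kind, count = as.integer(count),
    mean_area_um2 = mean_area_um2, cv_area = cv_area, species = species,
    fringe_depth_frac = fringe_depth_frac, fringe_density = fringe_density,
    axis_ratio_mean = axis_ratio_mean, axis_ratio_sd = axis_ratio_sd,
    tortuosity = tortuosity,
    length_min_um = length_range_um[1], length_max_um = length_range_um[2],
    thickness_min_um = thickness_range_um[1], thickness_max_um = thickness_range_um[2]
  )
}

# log-normal draw parameterised by arithmetic mean and CV
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

sample_one_population <- function(pop) {
  n <- pop$count
  if (n == 0) return(object_spec_tibble()[0, ])
  axis_ratio <- if (pop$kind == "hypha") rep(NA_real_, n) else
    pmax(1, rnorm(n, pop$axis_ratio_mean, pop$axis_ratio_sd))
  if (pop$kind == "hypha") {
    if (is.na(pop$mean_area_um2)) {
      length_um <- runif(n, pop$length_min_um, pop$length_max_um)
      thickness_um <- runif(n, pop$thickness_min_um, pop$thickness_max_um)
      area <- length_um * thickness_um
    } else {
      area <- rlnorm_mean_cv(n, pop$mean_area_um2, pop$cv_area)
      thickness_um <- runif(n, pop$thickness_min_um, pop$thickness_max_um)
      length_um <- pmax(area / thickness_um, thickness_um * 3)
    }
    core_radius_um <- rep(NA_real_, n)
    fringe_depth_um <- rep(0, n)
  } else {
    area <- rlnorm_mean_cv(n, pop$mean_area_um2, pop$cv_area)
    core_radius_um <- sqrt(area / pi)  # disk identity, before any fringe
    fringe_depth_um <- pop$fringe_depth_frac * core_radius_um
    length_um <- thickness_um <- rep(NA_real_, n)
  }
  tibble(
    kind = rep(pop$kind, n),
    true_species = rep(pop$species, n),
    true_area_um2 = area,
    core_radius_um = core_radius_um,
    fringe_depth_um = fringe_depth_um,
    fringe_density = rep(if (pop$kind == "hypha") 0 else pop$fringe_density, n),
    axis_ratio = axis_ratio,
    length_um = length_um,
    thickness_um = thickness_um,
    orientation = runif(n, 0, pi),
    tortuosity = rep(if (pop$kind == "hypha") pop$tortuosity else 0, n),
    fringe_phase = runif(n, 0, 2 * pi),
    shape_seed = sample.int(.Machine$integer.max - 1L, n),
    center_x_um = NA_real_, center_y_um = NA_real_
  )
}

object_spec_tibble <- function() {
  tibble(
    kind = character(), true_species = character(), true_area_um2 = double(),
    core_radius_um = double(), fringe_depth_um = double(), fringe_density = double(),
    axis_ratio = double(), length_um = double(), thickness_um = double(),
    orientation = double(), tortuosity = double(), fringe_phase = double(),
    shape_seed = integer(), center_x_um = double(), center_y_um = double()
  )
}

#' Sample object specs from population specs
#'
#' Draws the requested number of objects from each population row.  Areas
#' are log-normal with the specified mean and CV (so the sample mean of the
#' generative areas converges to `mean_area_um2` as the count grows);
#' pellet/clump core radii follow the disk identity `sqrt(area / pi)` before
#' the fringe is added.  Deterministic for a given `seed`.
#'
#' @param populations tibble of population rows from [population_spec()].
#' @param seed integer seed controlling every draw.
#' @return Tibble of object specs (one row per object); centres are left
#'   `NA` until placement by [build_scene()].
#' @export
sample_population <- function(populations, seed = 1L) {
  stopifnot(is.data.frame(populations))
  with_seed(as.integer(seed), {
    out <- seq_len(nrow(populations)) |>
      map(\(i) sample_one_population(populations[i, ])) |>
      list_rbind()
  })
  out
}
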