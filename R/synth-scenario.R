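#' Mono-/coculture time-course scenario templates
#'
#' A scenario prescribes, per vessel (coculture plus both monoculture
#' controls) and sampling time, the object populations present and their
#' statistical structure: mean projected area (log-normal, CV 0.3),
#' typical elongation and morphology number per stratum.  Three templates
#' mirror the characteristic outcomes of the three coculture initiation
#' strategies:
#'
#' * `"simultaneous"` (precultures introduced together, 0-168 h): the
#'   fungal partner A forms large pellets in monoculture (1.2e6 um^2
#'   rising to 1.3e7 um^2 at 24 h, then ~1.1e7) but an order of magnitude
#'   smaller pellets in coculture (2.1e6 declining to 7.3e5 um^2);
#'   actinomycete B pellets are essentially identical in mono- and
#'   coculture (5.1e5 / 2.9e5 um^2 at 24 h, converging to ~1.7e5);
#'   hyphae/clumps fluctuate at the 1e5 um^2 level.  Expected call:
#'   advantage to B.
#' * `"delayed"` (B introduced 24 h late, 0-192 h): B's preculture
#'   pellets (3.0e4 um^2) appear in the coculture only at 24 h and are
#'   destroyed afterwards while its monoculture forms pellets throughout;
#'   A's pellets persist (coculture 6.3e6 um^2 at 24 h vs monoculture
#'   1.4e7 um^2).  Expected call: domination by A.
#' * `"spores"` (spore-vs-spore start, 0-168 h): A's pellets never form
#'   in the coculture while its monoculture pelletises from 48 h; B's
#'   small pellets (1-2e4 um^2, Mo ~0.36) are near-identical across
#'   vessels.  Expected call: domination by B.
#'
#' @param template one of `"simultaneous"`, `"delayed"`, `"spores"`.
#' @param n_objects objects per stratum and timepoint (>= the min_n rule
#'   of the statistics stage if outcome calls are wanted).
#' @param experiment experiment identifier stored in every record.
#' @return A `scenario_spec` tibble (one row per vessel/time/stratum)
#'   with attributes `introduction_time_h` (when the second organism
#'   entered) and `recommended_window_start`.
#' @export
coculture_scenario <- function(template = c("simultaneous", "delayed", "spores"),
                               n_objects = 36L,
                               experiment = template) {
  template <- match.arg(template)
  experiment <- experiment[1]
  row <- function(culture, time_h, species, kind, mean_area, e_mean, mo_mean,
                  count = n_objects) {
    tibble(experiment = experiment, culture = culture, time_h = time_h,
           species = species, kind = kind, count = as.integer(count),
           mean_area_um2 = mean_area, cv_area = 0.3,
           e_mean = e_mean, e_sd = if (kind == "pellet") 0.12 else 0.4,
           mo_mean = mo_mean, mo_sd = if (kind == "pellet") 0.06 else 0.05)
  }
  # dispersed fraction (hyphal fragments and loose clumps pooled); rendered
  # as clump-type blobs so the prescribed projected area is honoured
  hyph <- function(culture, times, species, level = 1e5)
    map(times, \(t) row(culture, t, species, "clump", level, 2.5, 0.20)) |> list_rbind()

  if (template == "simultaneous") {
    times <- seq(0, 168, by = 24)
    a_mono <- c(1.2e6, 1.3e7, 1.1e7, 1.1e7, 1.05e7, 1.0e7, 1.0e7, 1.0e7)
    a_co <- c(2.1e6, 1.3e6, 1.15e6, 1.05e6, 9.5e5, 8.8e5, 8.0e5, 7.3e5)
    b_mono <- c(NA, 5.1e5, 4.0e5, 3.2e5, 2.6e5, 2.2e5, 1.9e5, 1.7e5)
    b_co <- c(NA, 2.9e5, 4.0e5, 3.2e5, 2.6e5, 2.2e5, 1.9e5, 1.7e5)
    spec <- bind_rows(
      map(seq_along(times), \(i) row("monoA", times[i], "A", "pellet",
                                     a_mono[i], 1.10, 0.65)) |> list_rbind(),
      map(seq_along(times), \(i) row("coculture", times[i], "A", "pellet",
                                     a_co[i], 1.56, 0.52)) |> list_rbind(),
      map(which(!is.na(b_mono)), \(i) row("monoB", times[i], "B", "pellet",
                                          b_mono[i], 1.29, 0.55)) |> list_rbind(),
      map(which(!is.na(b_co)), \(i) row("coculture", times[i], "B", "pellet",
                                        b_co[i], 1.36, 0.55)) |> list_rbind(),
      hyph("monoA", times[times >= 48], "A"),
      hyph("monoB", times[times >= 24], "B"),
      hyph("coculture", times[times >= 24], "A"),
      hyph("coculture", times[times >= 24], "B")
    )
    intro <- 0; window <- 48
  } else if (template == "delayed") {
    times <- seq(0, 192, by = 24)
    a_mono <- c(1.5e6, 1.4e7, 1.2e7, 1.1e7, 1.1e7, 1.1e7, 1.1e7, 1.1e7, 1.1e7)
    a_co <- c(1.5e6, 6.3e6, 5.6e6, 5.0e6, 4.2e6, 3.2e6, 2.4e6, 1.8e6, 1.4e6)
    b_mono <- c(NA, 3.0e4, 5.0e4, 1.0e5, 1.0e5, 9.0e4, 9.0e4, 8.5e4, 8.0e4)
    spec <- bind_rows(
      map(seq_along(times), \(i) row("monoA", times[i], "A", "pellet",
                                     a_mono[i], 1.12, 0.66)) |> list_rbind(),
      map(seq_along(times), \(i) row("coculture", times[i], "A", "pellet",
                                     a_co[i], 1.45, 0.55)) |> list_rbind(),
      map(which(!is.na(b_mono)), \(i) row("monoB", times[i], "B", "pellet",
                                          b_mono[i], 1.35, 0.50)) |> list_rbind(),
      row("coculture", 24, "B", "pellet", 3.0e4, 1.40, 0.45),
      hyph("monoA", times[times >= 48], "A", 9e4),
      hyph("monoB", times[times >= 48], "B", 6e4),
      hyph("coculture", times[times >= 48], "A", 6e4),
      hyph("coculture", times[times >= 48], "B", 5e4)
    )
    intro <- 24; window <- 72
  } else {
    times <- seq(0, 168, by = 24)
    a_mono <- c(NA, NA, 1.0e6, 2.0e6, 3.0e6, 3.0e6, 3.0e6, 3.0e6)
    b_mono <- c(NA, 1.4e4, 1.3e4, 1.0e4, 1.1e4, 1.2e4, 1.3e4, 1.4e4)
    b_co <- c(NA, 1.9e4, 1.4e4, 1.2e4, 1.2e4, 1.2e4, 1.25e4, 1.3e4)
    spec <- bind_rows(
      map(which(!is.na(a_mono)), \(i) row("monoA", times[i], "A", "pellet",
                                          a_mono[i], 1.25, 0.55)) |> list_rbind(),
      map(which(!is.na(b_mono)), \(i) row("monoB", times[i], "B", "pellet",
                                          b_mono[i], 1.45, 0.37)) |> list_rbind(),
      map(which(!is.na(b_co)), \(i) row("coculture", times[i], "B", "pellet",
                                        b_co[i], 1.45, 0.36)) |> list_rbind(),
      hyph("monoA", times[times >= 24], "A", 2e4),
      hyph("monoB", times[times >= 24], "B", 2e4),
      hyph("coculture", times[times >= 24], "A", 2e4),
      hyph("coculture", times[times >= 24], "B", 2e4)
    )
    intro <- 0; window <- 48
  }
  structure(spec, class = c("scenario_spec", class(spec)),
            template = template, introduction_time_h = intro,
            recommended_window_start = window)
}

# deterministic per-record seed scheme: master + fixed multipliers on the
# vessel / time / stratum indices, kept below 2^31
derive_seed <- function(master, i, j = 0L, k = 0L) {
  as.integer((as.numeric(master) + 7919 * i + 104729 * j + 1299709 * k) %%
               2147483629)
}

#' Sample a scenario at the object level (no rendering)
#'
#' Draws, for every scenario record, `count` objects with log-normal
#' projected areas and normal elongation / morphology-number draws around
#' the stratum's typical values, and applies the same fraction/species
#' semantics as the image pipeline (monoculture objects carry the
#' vessel's organism; coculture hyphae/clumps are species-undetermined).
#' This emulates the *statistical* structure of a classified object
#' table directly, which is what the population-statistics and outcome
#' stages consume; it bypasses rasterisation.
#'
#' @param scenario a `scenario_spec` from [coculture_scenario()].
#' @param seed master seed; per-record seeds are derived deterministically.
#' @return Classified-equivalent tibble (`experiment, culture, time_h,
#'   label, area_um2, elongation, morphology_number, fraction, species,
#'   provenance`).
#' @export
sample_scenario_truth <- function(scenario, seed = 1L) {
  out <- map(seq_len(nrow(scenario)), function(i) {
    rec <- scenario[i, ]
    n <- rec$count
    with_seed(derive_seed(seed, i), {
      area <- rlnorm_mean_cv(n, rec$mean_area_um2, rec$cv_area)
      e <- pmax(1, rnorm(n, rec$e_mean, rec$e_sd))
      mo <- pmin(1, pmax(0.02, rnorm(n, rec$mo_mean, rec$mo_sd)))
    })
    fraction <- if (rec$kind == "pellet") "fully_evolved_pellet" else "hyphae_or_clumps"
    species <- if (rec$culture == "coculture" && fraction == "hyphae_or_clumps")
      "undetermined" else rec$species
    tibble(experiment = rec$experiment, culture = rec$culture,
           time_h = rec$time_h, label = seq_len(n), area_um2 = area,
           elongation = e, morphology_number = mo,
           fraction = fraction, species = species, provenance = "truth")
  }) |> list_rbind()
  out
}

#' Render a scenario as a tree of synthetic scenes
#'
#' One scene per (vessel, time): populations are sampled, placed and
#' rendered with per-scene seeds derived deterministically from the
#' master seed.  The pixel calibration is chosen per scene (coarser for
#' scenes holding millimetre-size pellets) so every population fits the
#' frame; it is recorded in the manifest and in each image.  With
#' `out_dir` set, images/masks go to 16-bit TIFF and truth tables to CSV,
#' and the manifest is written as `manifest.csv`.
#'
#' @param scenario a `scenario_spec`.
#' @param seed master seed.
#' @param out_dir optional output directory.
#' @param image_size frame size in pixels.
#' @param count_override optional per-stratum object count replacing the
#'   scenario's counts (smaller counts render much faster).
#' @return List with `manifest` (tibble: experiment, culture, time_h,
#'   scale_um, seed, n_objects, true_mean_pellet_area_um2 and file paths
#'   when written) and `scenes` (named list of rendered `morph_scene`s).
#' @export
generate_timecourse <- function(scenario, seed = 1L, out_dir = NULL,
                                image_size = c(1024L, 1024L),
                                count_override = NULL) {
  # one scene per vessel and sampling time, including vessels that hold no
  # objects yet at a given time (an empty, noise-only frame)
  key <- crossing(culture = unique(scenario$culture),
                  time_h = unique(scenario$time_h))
  dup <- scenario |> count(.data$culture, .data$time_h, .data$species, .data$kind) |>
    filter(n > 1)
  if (nrow(dup) > 0)
    abort("duplicate (vessel, time, species, kind) scenario records.",
          class = "mycomorph_key_error")
  scenes <- list(); manifest <- list()
  for (i in seq_len(nrow(key))) {
    culture <- key$culture[i]; time_h <- key$time_h[i]
    experiment_id <- scenario$experiment[1]
    recs <- filter(scenario, .data$culture == !!culture, .data$time_h == !!time_h)
    pops <- map(seq_len(nrow(recs)), function(j) {
      r <- recs[j, ]
      population_spec(kind = r$kind,
                      count = if (is.null(count_override)) r$count else count_override,
                      mean_area_um2 = if (r$kind == "hypha") NA_real_ else r$mean_area_um2,
                      cv_area = r$cv_area, species = r$species,
                      axis_ratio_mean = if (r$kind == "pellet") r$e_mean else 2.5,
                      axis_ratio_sd = if (r$kind == "pellet") r$e_sd else 0.3)
    }) |> list_rbind()
    scene_seed <- derive_seed(seed, i)
    objs <- if (nrow(recs) == 0) object_spec_tibble() else
      sample_population(pops, seed = scene_seed)
    scale_um <- pick_scale(objs, image_size)
    scene <- build_scene(objs, image_size = image_size, scale_um = scale_um,
                         seed = scene_seed, experiment = experiment_id,
                         culture = culture, time_h = time_h)
    rendered <- render_scene(scene)
    nm <- sprintf("%s_%s_%03dh", experiment_id, culture, time_h)
    scenes[[nm]] <- rendered
    pel <- rendered$truth$true_area_um2[rendered$truth$kind == "pellet"]
    man <- tibble(experiment = experiment_id, culture = culture,
                  time_h = time_h, scale_um = scale_um, seed = scene_seed,
                  n_objects = nrow(objs),
                  true_mean_pellet_area_um2 = if (length(pel)) mean(pel) else NA_real_)
    if (!is.null(out_dir)) {
      paths <- write_scene(rendered, out_dir, nm)
      man$image_file <- basename(paths[1])
      man$mask_file <- basename(paths[2])
      man$truth_file <- basename(paths[3])
    }
    manifest[[nm]] <- man
  }
  manifest <- list_rbind(manifest)
  if (!is.null(out_dir))
    readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  list(manifest = manifest, scenes = scenes)
}

# smallest calibration from the dyadic ladder that packs the objects into
# the frame with headroom (bounding circles <= 30% of the frame area and
# the largest object under a quarter of the frame width)
pick_scale <- function(objects, image_size) {
  if (nrow(objects) == 0) return(2)
  for (scale_um in c(2, 4, 8, 16, 32, 64)) {
    rad_um <- object_bounding_radius_um(objects, scale_um)
    frame_um <- min(image_size) * scale_um
    if (sum(pi * (rad_um + 20)^2) <= 0.30 * (image_size[1] * image_size[2]) * scale_um^2 &&
        max(rad_um) <= frame_um / 4.5) return(scale_um)
  }
  abort("population too large for any supported calibration.",
        class = "mycomorph_placement_error")
}

#' Synthetic bioreactor process profiles
#'
#' Emulates dissolved-oxygen controller logs (air flowrate in
#' 1.5-5.5 L/min, stirring speed in 220-300 1/min) for a coculture and
#' its two monoculture controls.  In the `"early_peak"` pattern the
#' coculture and the B monoculture share an intense aeration/agitation
#' phase in the first 36 h (fast-growing actinomycete) while the A
#' monoculture stays low with a brief mid-time bump; in `"late_peak"`
#' the shared rise happens after 96 h (delayed carbon-source
#' consumption).  Either way the coculture profile tracks the B
#' monoculture, so the profile indicator selects species B.
#'
#' @param pattern `"early_peak"` or `"late_peak"`.
#' @param seed integer seed for the measurement noise.
#' @param t_end,by time grid (hours).
#' @return Named list of tibbles `co`, `monoA`, `monoB` with columns
#'   `time_h, air_flow_l_min, stirring_min1, vessel`.
#' @export
make_process_profiles <- function(pattern = c("early_peak", "late_peak"),
                                  seed = 1L, t_end = 168, by = 1) {
  pattern <- match.arg(pattern)
  t <- seq(0, t_end, by = by)
  ramp <- function(t, t_on, t_off, lo, hi, rise = 6, fall = 20) {
    lo + (hi - lo) * (plogis_((t - t_on) / rise) - plogis_((t - t_off) / fall))
  }
  if (pattern == "early_peak") {
    air_b <- ramp(t, 4, 45, 1.5, 5.5)
    stir_b <- ramp(t, 5, 70, 220, 300)
    air_a <- ramp(t, 17, 23, 1.5, 5.5, rise = 2, fall = 3)
    stir_a <- ramp(t, 25, 70, 220, 284, rise = 10)
  } else {
    air_b <- ramp(t, 100, 150, 1.5, 5.0, rise = 8, fall = 15)
    stir_b <- ramp(t, 105, 145, 220, 295, rise = 8)
    air_a <- rep(1.5, length(t))
    stir_a <- rep(220, length(t))
  }
  mk <- function(air, stir, vessel, sub_seed) {
    with_seed(derive_seed(seed, sub_seed), {
      tibble(time_h = t,
             air_flow_l_min = pmin(5.5, pmax(1.5, air + rnorm(length(t), 0, 0.05))),
             stirring_min1 = pmin(300, pmax(220, stir + rnorm(length(t), 0, 1.5))),
             vessel = vessel)
    })
  }
  list(co = mk(air_b, stir_b, "coculture", 1L),
       monoA = mk(air_a, stir_a, "monoA", 2L),
       monoB = mk(air_b, stir_b, "monoB", 3L))
}

plogis_ <- function(x) 1 / (1 + exp(-x))
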