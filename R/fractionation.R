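#' Shape/size filter configuration
#'
#' The two-fraction split ("fully evolved pellets" vs "hyphae and clumps")
#' and the coculture species attribution are rule-based shape and size
#' filters whose limits are operator-settable per experiment.  The
#' defaults are reconstructed from the typical descriptor bands of compact
#' pellets (Mo roughly 0.36-0.77, E up to ~1.9) versus dispersed objects
#' (Mo 0.1-0.35, E 1.75-3.25) and from the order-of-magnitude size
#' separation between the two species' pellets.
#'
#' @param pellet_min_Mo minimum morphology number of a pellet (in (0,1)).
#' @param pellet_max_E maximum elongation of a pellet (>= 1).
#' @param pellet_min_area_um2 minimum projected area of a pellet.
#' @param species_area_threshold_um2 coculture pellets at or above this
#'   area are attributed to species A (the large-pellet former), smaller
#'   ones to species B.
#' @param review_band relative half-width around the species threshold
#'   inside which coculture pellet calls are flagged for review.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(pellet_min_Mo = 0.35, pellet_max_E = 1.9,
                          pellet_min_area_um2 = 1e4,
                          species_area_threshold_um2 = 1e6,
                          review_band = 0.2) {
  if (pellet_min_Mo <= 0 || pellet_min_Mo >= 1)
    abort("`pellet_min_Mo` must lie in (0, 1).", class = "mycomorph_parameter_error")
  if (pellet_max_E < 1)
    abort("`pellet_max_E` must be >= 1.", class = "mycomorph_parameter_error")
  if (pellet_min_area_um2 <= 0 || species_area_threshold_um2 <= 0)
    abort("area thresholds must be positive.", class = "mycomorph_parameter_error")
  structure(list(pellet_min_Mo = pellet_min_Mo, pellet_max_E = pellet_max_E,
                 pellet_min_area_um2 = pellet_min_area_um2,
                 species_area_threshold_um2 = species_area_threshold_um2,
                 review_band = review_band),
            class = "filter_config")
}

#' Fraction call for measured objects
#'
#' An object is a fully evolved pellet iff `Mo >= pellet_min_Mo` AND
#' `E <= pellet_max_E` AND `A >= pellet_min_area_um2` (all thresholds
#' inclusive); everything else is hyphae/clumps.  Vectorised.
#'
#' @param morphology_number,elongation,area_um2 descriptor vectors.
#' @param cfg a [filter_config].
#' @return Character vector, `"fully_evolved_pellet"` or
#'   `"hyphae_or_clumps"`.
#' @export
classify_fraction <- function(morphology_number, elongation, area_um2,
                              cfg = filter_config()) {
  ifelse(morphology_number >= cfg$pellet_min_Mo &
           elongation <= cfg$pellet_max_E &
           area_um2 >= cfg$pellet_min_area_um2,
         "fully_evolved_pellet", "hyphae_or_clumps")
}

#' Species attribution
#'
#' Monoculture vessels trivially yield the cultured organism.  In
#' cocultures, pellets are attributed by the size filter (species A at or
#' above `species_area_threshold_um2`, species B below), while hyphae and
#' clumps remain `"undetermined"` unless an operator override names the
#' species.  Operator calls always win and are flagged in the provenance.
#'
#' @param fraction,area_um2 fraction call and projected area per object.
#' @param culture `"monoA"`, `"monoB"` or `"coculture"`.
#' @param cfg a [filter_config].
#' @param override_species optional character vector (NA where no
#'   override) of operator species calls per object.
#' @return Tibble with columns `species`, `provenance` (`"auto"` or
#'   `"operator"`) and `review` (coculture pellet within the review band
#'   of the species size threshold).
#' @export
attribute_species <- function(fraction, area_um2, culture,
                              cfg = filter_config(), override_species = NULL) {
  n <- length(fraction)
  if (!all(culture %in% .cultures))
    abort("`culture` must be monoA, monoB or coculture.",
          class = "mycomorph_parameter_error")
  culture <- rep_len(culture, n)
  species <- character(n)
  mono <- culture != "coculture"
  species[mono] <- substr(culture[mono], 5, 5)
  is_pellet <- fraction == "fully_evolved_pellet"
  co_pellet <- !mono & is_pellet
  species[co_pellet] <- ifelse(area_um2[co_pellet] >= cfg$species_area_threshold_um2,
                               "A", "B")
  species[!mono & !is_pellet] <- "undetermined"
  review <- co_pellet &
    abs(area_um2 - cfg$species_area_threshold_um2) <=
      cfg$review_band * cfg$species_area_threshold_um2
  provenance <- rep("auto", n)
  if (!is.null(override_species)) {
    ov <- !is.na(override_species)
    if (any(ov & !override_species %in% .species))
      abort("override species must be 'A' or 'B'.", class = "mycomorph_edit_error")
    species[ov] <- override_species[ov]
    provenance[ov] <- "operator"
  }
  tibble(species = species, provenance = provenance, review = review)
}

#' Classify a measurement table
#'
#' Adds `fraction`, `species`, `provenance` and `review` columns to a
#' [measure_objects()] table, preserving row order.  Overrides are
#' matched by `(experiment, time_h, label)`; rows referencing labels that
#' do not exist in the table raise an error.
#'
#' @param measurements tibble from [measure_objects()] with metadata
#'   columns `experiment`, `culture`, `time_h`.
#' @param cfg a [filter_config].
#' @param overrides optional tibble `experiment, time_h, label, species`
#'   of operator species calls.
#' @return The classified tibble; per-(fraction, species) counts are
#'   attached as attribute `"counts"`.
#' @export
classify_objects <- function(measurements, cfg = filter_config(), overrides = NULL) {
  m <- as_tibble(measurements)
  if (nrow(m) == 0) {
    out <- m |> mutate(fraction = character(), species = character(),
                       provenance = character(), review = logical())
    attr(out, "counts") <- count(out, .data$fraction, .data$species)
    return(out)
  }
  m$fraction <- classify_fraction(m$morphology_number, m$elongation, m$area_um2, cfg)
  ov_vec <- rep(NA_character_, nrow(m))
  if (!is.null(overrides) && nrow(overrides) > 0) {
    key <- paste(m$experiment, m$time_h, m$label, sep = "\r")
    okey <- paste(overrides$experiment, overrides$time_h, overrides$label, sep = "\r")
    hit <- match(okey, key)
    if (anyNA(hit))
      abort(sprintf("override(s) reference unknown objects: %s",
                    paste(okey[is.na(hit)], collapse = "; ")),
            class = "mycomorph_edit_error")
    ov_vec[hit] <- overrides$species
  }
  attr_res <- attribute_species(m$fraction, m$area_um2, m$culture, cfg, ov_vec)
  out <- bind_cols(m, attr_res)
  attr(out, "counts") <- count(out, .data$fraction, .data$species)
  out
}
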