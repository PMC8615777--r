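#' Call the coculture outcome: domination, advantage or none
#'
#' Encodes the decision rule of the mono-/coculture comparison.  A species
#' suffers *morphological domination* when its fully evolved pellets are
#' absent from the coculture at every evaluated timepoint while being
#' present in its own monoculture (at more than half of those timepoints);
#' the competitor is then the winner.  If no species is dominated, a
#' species concedes the *morphological advantage* when its coculture
#' pellets persist but their projected area is significantly smaller than
#' in its monoculture (tier at least p < alpha, coculture mean below the
#' monoculture mean) in a strict majority of the usable window
#' timepoints.  Domination globally outranks advantage (a winner by
#' domination may itself have smaller pellets than in its own
#' monoculture).  If both species qualify at the same level the call is
#' `none` with a conflict flag.
#'
#' The window excludes a settling period after the introduction of the
#' second organism (default: evaluate from 48 h, i.e. drop the first
#' 24 h sample after a simultaneous start).  A stratum present with fewer
#' than `min_n` objects counts as *present but unquantified*: presence
#' for the domination logic, unusable for the advantage test.
#'
#' @param timecourse a `morph_timecourse` from [assemble_timecourse()]
#'   covering one experiment (coculture + both monocultures).
#' @param comparisons comparison records from [compare_cocultures()] for
#'   the same experiment.
#' @param window_start evaluation window start in hours (inclusive).
#' @param cfg a [stat_config] (supplies `alpha` and `min_n`).
#' @return An `outcome_call` object with fields `experiment`, `winner`
#'   (`"A"`, `"B"` or `"none"`), `verdict` (`"domination"`,
#'   `"advantage"` or `"none"`), `conflict`, `window_start` and the
#'   per-timepoint `evidence` tibble.  Use [tidy()] / [glance()] for
#'   tabular views.
#' @export
call_outcome <- function(timecourse, comparisons, window_start = 48,
                         cfg = stat_config()) {
  tc <- filter(timecourse, .data$time_h >= window_start)
  window_times <- sort(unique(tc$time_h))
  if (length(window_times) < 2)
    abort("fewer than 2 usable window timepoints.",
          class = "mycomorph_insufficient_data")
  experiment <- unique(timecourse$experiment)
  if (length(experiment) != 1)
    abort("`timecourse` must cover exactly one experiment.",
          class = "mycomorph_parameter_error")

  pellet_n <- function(culture_, species_, t_) {
    r <- filter(tc, .data$culture == culture_, .data$species == species_,
                .data$fraction == "fully_evolved_pellet", .data$time_h == t_)
    if (nrow(r) == 0) 0L else sum(r$n)
  }
  cmp_area <- comparisons |>
    filter(.data$parameter == "area_um2",
           .data$fraction == "fully_evolved_pellet",
           .data$time_h >= window_start)

  evidence <- crossing(species = .species, time_h = window_times) |>
    mutate(
      co_pellets = map2_int_(.data$species, .data$time_h,
                             \(s, t) pellet_n("coculture", s, t)),
      mono_pellets = map2_int_(.data$species, .data$time_h,
                               \(s, t) pellet_n(mono_culture_of(s), s, t))
    ) |>
    left_join(select(cmp_area, "species", "time_h", "status", "mean_co",
                     "mean_mono", "p_value", "tier"),
              by = c("species", "time_h")) |>
    mutate(
      usable = !is.na(.data$status) & .data$status == "ok",
      significantly_smaller = .data$usable & !is.na(.data$p_value) &
        .data$p_value < cfg$alpha & .data$mean_co < .data$mean_mono
    )

  per_species <- evidence |>
    group_by(.data$species) |>
    summarise(
      dominated = all(.data$co_pellets == 0) &
        sum(.data$mono_pellets > 0) > dplyr::n() / 2,
      n_usable = sum(.data$usable),
      n_smaller = sum(.data$significantly_smaller),
      advantage_conceded = any(.data$co_pellets > 0) &
        n_usable > 0 & n_smaller > n_usable / 2,
      .groups = "drop"
    )

  dom <- per_species$species[per_species$dominated]
  adv <- per_species$species[per_species$advantage_conceded]
  conflict <- FALSE
  if (length(dom) == 2) {
    winner <- "none"; verdict <- "none"; conflict <- TRUE
  } else if (length(dom) == 1) {
    winner <- setdiff(.species, dom); verdict <- "domination"
  } else if (length(adv) == 2) {
    winner <- "none"; verdict <- "none"; conflict <- TRUE
  } else if (length(adv) == 1) {
    winner <- setdiff(.species, adv); verdict <- "advantage"
  } else {
    winner <- "none"; verdict <- "none"
  }
  structure(
    list(experiment = experiment, winner = winner, verdict = verdict,
         conflict = conflict, window_start = window_start,
         window_times = window_times, evidence = evidence,
         per_species = per_species),
    class = "outcome_call"
  )
}

map2_int_ <- function(x, y, f) vapply(seq_along(x), \(i) as.integer(f(x[i], y[i])), integer(1))

#' @export
print.outcome_call <- function(x, ...) {
  cat(sprintf("<outcome_call %s: %s%s, window >= %g h (%d timepoints)>\n",
              x$experiment,
              if (x$winner == "none") x$verdict
              else sprintf("%s by species %s", x$verdict, x$winner),
              if (x$conflict) " [conflict]" else "",
              x$window_start, length(x$window_times)))
  invisible(x)
}

#' Tidy an outcome call
#'
#' `tidy()` returns the per-timepoint evidence table; `glance()` the
#' one-row verdict.
#'
#' @param x an `outcome_call`.
#' @param ... unused.
#' @method tidy outcome_call
#' @export
tidy.outcome_call <- function(x, ...) {
  mutate(x$evidence, experiment = x$experiment, .before = 1)
}

#' @rdname tidy.outcome_call
#' @method glance outcome_call
#' @export
glance.outcome_call <- function(x, ...) {
  tibble(experiment = x$experiment, winner = x$winner, verdict = x$verdict,
         conflict = x$conflict, window_start = x$window_start,
         n_window_timepoints = length(x$window_times))
}

#' Process-profile similarity between two vessels
#'
#' The dissolved-oxygen controller logs (air flowrate and stirring speed
#' over time) fingerprint which monoculture the coculture behaved like.
#' Both profiles are linearly interpolated onto a common uniform grid
#' over their overlapping time range; the Pearson correlation is computed
#' per channel and averaged.  A constant channel carries no correlation
#' information and is skipped with a warning.
#'
#' @param co,mono profile tibbles with columns `time_h`,
#'   `air_flow_l_min`, `stirring_min1`.
#' @param n_grid number of interpolation nodes.
#' @return Similarity score in `[-1, 1]`.
#' @export
profile_similarity <- function(co, mono, n_grid = 200L) {
  t0 <- max(min(co$time_h), min(mono$time_h))
  t1 <- min(max(co$time_h), max(mono$time_h))
  if (t1 <= t0) abort("profiles do not overlap in time.",
                      class = "mycomorph_parameter_error")
  grid <- seq(t0, t1, length.out = n_grid)
  sims <- c()
  for (ch in c("air_flow_l_min", "stirring_min1")) {
    a <- approx(co$time_h, co[[ch]], grid)$y
    b <- approx(mono$time_h, mono[[ch]], grid)$y
    if (sd(a) < 1e-12 || sd(b) < 1e-12) {
      warn(sprintf("constant channel '%s' skipped.", ch))
      next
    }
    sims <- c(sims, cor(a, b))
  }
  if (length(sims) == 0)
    abort("no informative profile channel.", class = "mycomorph_parameter_error")
  mean(sims)
}

#' Pick the dominant organism from process profiles
#'
#' Compares the coculture profile against both monoculture profiles and
#' returns the species whose monoculture the coculture resembles most;
#' `"tie"` when the two similarity scores are within `tie_tol`.
#'
#' @param co,monoA,monoB profile tibbles (see [profile_similarity()]).
#' @param tie_tol absolute score difference treated as a tie.
#' @return `"A"`, `"B"` or `"tie"`.
#' @export
dominant_from_profiles <- function(co, monoA, monoB, tie_tol = 0.05) {
  sA <- profile_similarity(co, monoA)
  sB <- profile_similarity(co, monoB)
  if (abs(sA - sB) <= tie_tol) "tie" else if (sA > sB) "A" else "B"
}
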