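#' Statistics configuration
#'
#' @param alpha significance level of the Student-t confidence bands and
#'   comparison tiers (default 0.05).
#' @param min_n minimum number of objects per stratum for a summary to be
#'   considered reliable (default 30, matching the "at least 30 objects
#'   per mean" rule); smaller strata are still emitted but flagged and
#'   excluded from outcome calls.
#' @param tiers ordered p-value tier cut-offs for reporting.
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return A list of class `stat_config`.
#' @export
stat_config <- function(alpha = 0.05, min_n = 30L,
                        tiers = c(0.05, 0.01, 0.001), var_equal = FALSE) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).",
                                      class = "mycomorph_parameter_error")
  if (min_n < 2) abort("`min_n` must be >= 2.", class = "mycomorph_parameter_error")
  structure(list(alpha = alpha, min_n = as.integer(min_n),
                 tiers = sort(tiers, decreasing = TRUE), var_equal = var_equal),
            class = "stat_config")
}

p_tier <- function(p, tiers = c(0.05, 0.01, 0.001)) {
  tiers <- sort(tiers, decreasing = TRUE)
  vapply(p, function(pv) {
    if (is.na(pv)) return(NA_character_)
    hit <- tiers[pv < tiers]
    if (length(hit) == 0) "n.s." else sprintf("p<%g", min(hit))
  }, character(1))
}

#' Per-stratum summaries with Student-t confidence bands
#'
#' Groups classified objects by (experiment, culture, time, species,
#' fraction) and reports, per stratum, the object count and the mean of
#' each descriptor with its confidence half-width
#' `t(1 - alpha/2, n - 1) * s / sqrt(n)` (sample SD `s`).  Strata with
#' `n < min_n` are flagged `below_min_n` (they are still emitted; the
#' outcome stage ignores their comparisons).  A single-object stratum has
#' an undefined half-width (`NA`).
#'
#' @param classified tibble from [classify_objects()].
#' @param cfg a [stat_config].
#' @return Tibble with one row per stratum: `n`, `mean_area_um2`,
#'   `ci_area_um2`, `mean_elongation`, `ci_elongation`, `mean_mo`,
#'   `ci_mo`, `below_min_n`.
#' @export
summarize_strata <- function(classified, cfg = stat_config()) {
  ci <- function(x) {
    n <- length(x)
    if (n < 2) return(NA_real_)
    qt(1 - cfg$alpha / 2, n - 1) * sd(x) / sqrt(n)
  }
  classified |>
    group_by(.data$experiment, .data$culture, .data$time_h,
             .data$species, .data$fraction) |>
    summarise(
      n = dplyr::n(),
      mean_area_um2 = mean(.data$area_um2), ci_area_um2 = ci(.data$area_um2),
      mean_elongation = mean(.data$elongation), ci_elongation = ci(.data$elongation),
      mean_mo = mean(.data$morphology_number), ci_mo = ci(.data$morphology_number),
      .groups = "drop"
    ) |>
    mutate(below_min_n = .data$n < cfg$min_n)
}

#' Two-sample t-test (Welch by default)
#'
#' Hand-computed unequal-variance t statistic with Welch-Satterthwaite
#' degrees of freedom and a two-sided p-value; the pooled-variance
#' variant is available via `var_equal`.  If both samples have zero
#' variance the comparison degenerates: p = 1 when the means are equal,
#' p = 0 otherwise, with a warning.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @param var_equal pooled-variance mode.
#' @return One-row tibble `t_statistic, df, p_value`.
#' @export
welch_test <- function(x, y, var_equal = FALSE) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) abort("each sample needs n >= 2.",
                              class = "mycomorph_parameter_error")
  vx <- var(x); vy <- var(y)
  if (vx == 0 && vy == 0) {
    warn("both samples have zero variance; exact comparison fallback.")
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    return(tibble(t_statistic = if (eq) 0 else Inf,
                  df = NA_real_, p_value = if (eq) 1 else 0))
  }
  if (var_equal) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  t <- (mean(x) - mean(y)) / se
  tibble(t_statistic = t, df = df, p_value = 2 * pt(-abs(t), df))
}

#' Compare one coculture stratum against its monoculture control
#'
#' Applies [welch_test()] to the chosen descriptor's per-object values.
#' If either stratum is empty the result is an `"absent"` record (used
#' downstream as pellet-disappearance evidence); if either side is
#' below `min_n`, the record is flagged `"below_min_n"` and no test is
#' computed.
#'
#' @param co,mono per-object classified tibbles for the same
#'   (experiment, time, species, fraction) stratum in coculture and
#'   monoculture.
#' @param parameter one of `"area_um2"`, `"elongation"`,
#'   `"morphology_number"`.
#' @param cfg a [stat_config].
#' @return One-row tibble: `parameter, status, n_co, n_mono, mean_co,
#'   mean_mono, t_statistic, df, p_value, tier`.
#' @export
compare_timepoint <- function(co, mono,
                              parameter = c("area_um2", "elongation",
                                            "morphology_number"),
                              cfg = stat_config()) {
  parameter <- match.arg(parameter)
  x <- co[[parameter]]; y <- mono[[parameter]]
  base <- tibble(parameter = parameter, status = "ok",
                 n_co = length(x), n_mono = length(y),
                 mean_co = if (length(x)) mean(x) else NA_real_,
                 mean_mono = if (length(y)) mean(y) else NA_real_,
                 t_statistic = NA_real_, df = NA_real_, p_value = NA_real_,
                 tier = NA_character_)
  if (length(x) == 0 || length(y) == 0) {
    base$status <- "absent"
    return(base)
  }
  if (length(x) < cfg$min_n || length(y) < cfg$min_n) {
    base$status <- "below_min_n"
    return(base)
  }
  w <- welch_test(x, y, var_equal = cfg$var_equal)
  base$t_statistic <- w$t_statistic
  base$df <- w$df
  base$p_value <- w$p_value
  base$tier <- p_tier(w$p_value, cfg$tiers)
  base
}

#' All coculture-vs-monoculture comparisons of an experiment
#'
#' For every (experiment, time, species, fraction, parameter) stratum
#' present in either the coculture or the matching monoculture vessel,
#' runs [compare_timepoint()].  Undetermined-species coculture objects
#' have no monoculture counterpart and are skipped.
#'
#' @param classified classified object table covering the coculture and
#'   monoculture vessels of the experiment(s).
#' @param cfg a [stat_config].
#' @param parameters descriptors to compare.
#' @return Tidy tibble of comparison records.
#' @export
compare_cocultures <- function(classified, cfg = stat_config(),
                               parameters = c("area_um2", "elongation",
                                              "morphology_number")) {
  cls <- filter(classified, .data$species %in% .species)
  strata <- cls |>
    filter(.data$culture == "coculture" |
             .data$culture == mono_culture_of(.data$species)) |>
    distinct(.data$experiment, .data$time_h, .data$species, .data$fraction)
  pmap(strata, function(experiment, time_h, species, fraction) {
    co <- filter(cls, .data$experiment == !!experiment, .data$time_h == !!time_h,
                 .data$species == !!species, .data$fraction == !!fraction,
                 .data$culture == "coculture")
    mono <- filter(cls, .data$experiment == !!experiment, .data$time_h == !!time_h,
                   .data$species == !!species, .data$fraction == !!fraction,
                   .data$culture == mono_culture_of(!!species))
    map(parameters, \(p) compare_timepoint(co, mono, p, cfg)) |>
      list_rbind() |>
      mutate(experiment = !!experiment, time_h = !!time_h,
             species = !!species, fraction = !!fraction, .before = 1)
  }) |>
    list_rbind() |>
    arrange(.data$experiment, .data$time_h, .data$species,
            .data$fraction, .data$parameter)
}

#' Assemble per-stratum summaries into a tidy time course
#'
#' Sorts summaries by key, errors on duplicate keys, and makes absences
#' explicit: every stratum observed anywhere in an experiment gets a row
#' at every sampling time of that experiment, with `n = 0` and
#' `present = FALSE` where it was not observed (an absence is evidence,
#' not a zero mean).
#'
#' @param summaries tibble from [summarize_strata()].
#' @return A `morph_timecourse` tibble keyed by (experiment, culture,
#'   time_h, species, fraction).
#' @export
assemble_timecourse <- function(summaries) {
  key <- summaries |> count(.data$experiment, .data$culture, .data$time_h,
                            .data$species, .data$fraction)
  if (any(key$n > 1))
    abort("duplicate (experiment, culture, time, species, fraction) keys.",
          class = "mycomorph_key_error")
  out <- summaries |>
    mutate(present = TRUE) |>
    group_by(.data$experiment) |>
    complete(time_h = unique(time_h), nesting(culture, species, fraction),
             fill = list(n = 0L, present = FALSE, below_min_n = TRUE)) |>
    ungroup() |>
    arrange(.data$experiment, .data$culture, .data$time_h,
            .data$species, .data$fraction)
  class(out) <- c("morph_timecourse", class(out))
  out
}
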