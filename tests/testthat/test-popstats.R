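strata_table <- function(values, n = length(values), experiment = "E",
                         culture = "monoA", time_h = 24, species = "A",
                         fraction = "fully_evolved_pellet") {
  tibble::tibble(experiment = experiment, culture = culture, time_h = time_h,
                 species = species, fraction = fraction,
                 label = seq_len(n), area_um2 = values,
                 elongation = rep(1.2, n), morphology_number = rep(0.5, n))
}

test_that("stratum summaries reproduce the Student-t confidence band", {
  # zero variance: mean exact, half-width zero
  s0 <- summarize_strata(strata_table(rep(5, 30)))
  expect_equal(s0$mean_area_um2, 5)
  expect_equal(s0$ci_area_um2, 0)
  expect_false(s0$below_min_n)

  # frozen oracle: values 1..31, alpha 0.05; sample SD of 1..31 is
  # sqrt(31 * 32 / 12) = 9.0921, so qt(0.975, 30) * 9.0921 / sqrt(31) = 3.33502
  s1 <- summarize_strata(strata_table(as.numeric(1:31)))
  expect_equal(s1$mean_area_um2, 16)
  expect_equal(s1$ci_area_um2, 3.33502, tolerance = 1e-5)

  # the >= 30 objects rule
  s2 <- summarize_strata(strata_table(rnorm(29, 10)))
  expect_true(s2$below_min_n)
  s3 <- summarize_strata(strata_table(c(7)))
  expect_true(is.na(s3$ci_area_um2))
  expect_true(s3$below_min_n)
})

test_that("confidence half-width shrinks as 1/sqrt(n)", {
  base <- rnorm(40, 100, 10)
  s40 <- summarize_strata(strata_table(base))
  s160 <- summarize_strata(strata_table(rep(base, 4)))
  # same sample SD, 4x the n: half-width ratio approaches 1/2
  expect_equal(s160$ci_area_um2 / s40$ci_area_um2, 0.5, tolerance = 0.05)
})

test_that("hand-built Welch test agrees with the reference implementation", {
  withr::with_seed(11, {
    x <- rnorm(30, 10, 1)
    y <- rnorm(25, 12, 1)
  })
  w <- welch_test(x, y)
  ref <- t.test(x, y)
  expect_equal(w$t_statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(w$df, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(w$p_value, ref$p.value, tolerance = 1e-10)
  expect_lt(w$p_value, 0.001)

  wp <- welch_test(x, y, var_equal = TRUE)
  refp <- t.test(x, y, var.equal = TRUE)
  expect_equal(wp$t_statistic, unname(refp$statistic), tolerance = 1e-10)
  expect_equal(wp$p_value, refp$p.value, tolerance = 1e-10)

  # degenerate cases
  expect_equal(welch_test(x, x)$t_statistic, 0)
  expect_equal(welch_test(x, x)$p_value, 1)
  expect_warning(z <- welch_test(rep(1, 5), rep(1, 5)), "zero variance")
  expect_equal(z$p_value, 1)
  expect_warning(z2 <- welch_test(rep(1, 5), rep(2, 5)), "zero variance")
  expect_equal(z2$p_value, 0)
  expect_error(welch_test(1, 1:5), class = "mycomorph_parameter_error")
})

test_that("Welch p-values are uniform under the null and powerful under 10x shifts", {
  withr::with_seed(101, {
    null_p <- simulate_welch_p(2000, 1e5, 1e5)
    power_p <- simulate_welch_p(500, 1.3e6, 1.3e7)
  })
  expect_gte(mean(null_p < 0.05), 0.03)
  expect_lte(mean(null_p < 0.05), 0.07)
  expect_gte(mean(power_p < 0.001), 0.99)
})

test_that("timepoint comparisons report tiers, below-min-n and absences", {
  cfg <- stat_config()
  x <- strata_table(rnorm(30, 100, 5), culture = "coculture")
  same <- compare_timepoint(x, x |> dplyr::mutate(culture = "monoA"), "area_um2", cfg)
  expect_equal(same$tier, "n.s.")
  expect_equal(same$status, "ok")

  small <- compare_timepoint(strata_table(rnorm(10, 100)), x, "area_um2", cfg)
  expect_equal(small$status, "below_min_n")
  expect_true(is.na(small$p_value))

  absent <- compare_timepoint(strata_table(numeric(0), n = 0), x, "area_um2", cfg)
  expect_equal(absent$status, "absent")

  withr::with_seed(5, {
    co <- strata_table(mycomorph:::rlnorm_mean_cv(30, 1.3e6, 0.3),
                       culture = "coculture")
    mono <- strata_table(mycomorph:::rlnorm_mean_cv(30, 1.3e7, 0.3))
  })
  big <- compare_timepoint(co, mono, "area_um2", cfg)
  expect_equal(big$tier, "p<0.001")
  expect_lt(big$mean_co, big$mean_mono)
})

test_that("coculture comparison tables cover every stratum and parameter", {
  sc <- coculture_scenario("simultaneous", n_objects = 32)
  tr <- sample_scenario_truth(sc, seed = 2)
  cmp <- compare_cocultures(tr)
  expect_setequal(unique(cmp$parameter),
                  c("area_um2", "elongation", "morphology_number"))
  a24 <- dplyr::filter(cmp, species == "A", time_h == 24,
                       fraction == "fully_evolved_pellet", parameter == "area_um2")
  expect_equal(a24$tier, "p<0.001")
  # B pellets never existed at 0 h: absent record, not an error
  b0 <- dplyr::filter(cmp, species == "B", time_h == 0,
                      fraction == "fully_evolved_pellet", parameter == "area_um2")
  expect_true(nrow(b0) == 0 || all(b0$status == "absent"))
})

test_that("timecourse assembly sorts, rejects duplicates and records absences", {
  one <- summarize_strata(strata_table(rnorm(30, 10)))
  expect_equal(nrow(assemble_timecourse(one)), 1)
  expect_error(assemble_timecourse(dplyr::bind_rows(one, one)),
               class = "mycomorph_key_error")

  # a stratum that vanishes mid-course keeps explicit absence rows
  sc <- coculture_scenario("delayed", n_objects = 31)
  tc <- assemble_timecourse(summarize_strata(sample_scenario_truth(sc, seed = 3)))
  bco <- dplyr::filter(tc, culture == "coculture", species == "B",
                       fraction == "fully_evolved_pellet")
  expect_true(all(bco$present[bco$time_h == 24]))
  expect_true(all(!bco$present[bco$time_h >= 48]))
  expect_true(all(bco$n[bco$time_h >= 48] == 0))
})

test_that("p-value tiers map onto the reporting thresholds", {
  expect_equal(mycomorph:::p_tier(c(0.2, 0.04, 0.009, 1e-5, NA)),
               c("n.s.", "p<0.05", "p<0.01", "p<0.001", NA))
})
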