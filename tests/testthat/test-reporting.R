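# A deterministic census panel: sampling the whole eligible population
# makes every weighted estimate exactly equal to its population value.
census_world <- function() {
  cached("census_world", {
    pop <- synthetic_population(n_counties = 3, total_population = 400,
                                years = 2006, seed = 17)
    plan <- build_allocation_plan(pop, total_target = 400, county_min = 500,
                                  race_min = 250)
    panel <- draw_baseline(pop, plan, seed = 17)
    list(pop = pop, panel = panel)
  })
}

test_that("a single-year panel yields a one-cell retention matrix at 100%", {
  w <- census_world()
  rm <- retention_matrix(w$panel)
  expect_identical(nrow(as.data.frame(rm)), 1L)
  expect_equal(rm$pct, 100)
  expect_identical(rm$n, nrow(as.data.frame(w$panel)))
})

test_that("retention percentages match a hand-scripted panel", {
  # wave of 100 members losing 10 per year over 3 years
  rows <- function(ids, year, wave) {
    tibble::tibble(beneficiary_id = ids, year = year, county = "A",
                   race_group = "white", entry_wave = wave, weight = 1,
                   stratum_pop = 100L, retained = year > wave)
  }
  panel <- dplyr::bind_rows(
    rows(1:100, 2006L, 2006L), rows(1:90, 2007L, 2006L),
    rows(1:80, 2008L, 2006L),
    rows(201:210, 2007L, 2007L), rows(201:209, 2008L, 2007L))
  rm <- dplyr::as_tibble(retention_matrix(panel))
  w1 <- rm[rm$entry_wave == 2006, ]
  expect_equal(w1$pct, c(100, 90, 80))
  expect_equal(rm$pct[rm$entry_wave == 2007], c(100, 90))
  # diagonal cells are always 100%
  expect_true(all(rm$pct[rm$follow_up_year == rm$entry_wave] == 100))
})

test_that("wave retention columns are non-increasing on a synthetic run", {
  w <- small_world()
  rm <- dplyr::as_tibble(retention_matrix(w$panel))
  for (wv in unique(rm$entry_wave)) {
    col <- rm$pct[rm$entry_wave == wv][order(rm$follow_up_year[rm$entry_wave == wv])]
    expect_true(all(diff(col) <= 0))
  }
  # row totals equal annual sample sizes
  tot <- dplyr::summarise(dplyr::group_by(rm, follow_up_year),
                          n = sum(n), .groups = "drop")
  ann <- dplyr::count(dplyr::as_tibble(w$panel), year)
  expect_identical(tot$n, ann$n)
})

test_that("a census sample reproduces the population exactly in every report", {
  w <- census_world()
  cs <- cross_sectional_report(w$panel, w$pop, 2006)
  expect_equal(cs$difference, rep(0, 3))
  expect_equal(cs$p_value, rep(1, 3))
  pr <- prevalence_report(w$panel, w$pop, 2006)
  expect_identical(nrow(pr), 21L)
  expect_equal(pr$difference, rep(0, 21))
  expect_equal(pr$p_value, rep(1, 21))
  ov <- age_distribution_overlay(w$panel, w$pop, 2006)
  expect_equal(ov$sample_weighted_n, ov$population_n)
})

test_that("a condition absent from the population compares 0% to 0%", {
  prev <- default_condition_prevalences()
  prev[["endometrial_cancer"]] <- 0
  cty <- generate_counties(3, 400, seed = 19)
  pop <- generate_baseline_population(cty, condition_prevalences = prev,
                                      seed = 19)
  plan <- build_allocation_plan(pop, total_target = 200, county_min = 30,
                                race_min = 15)
  panel <- draw_baseline(pop, plan, seed = 19)
  pr <- prevalence_report(panel, pop, 2006,
                          conditions = "endometrial_cancer")
  expect_equal(pr$population_value, 0)
  expect_equal(pr$estimate, 0)
  expect_equal(pr$p_value, 1)
})

test_that("the baseline race composition difference is zero to machine precision", {
  w <- small_world()
  cs <- cross_sectional_report(w$panel, w$pop, 2006)
  expect_lt(abs(cs$difference[cs$variable == "pct_white"]), 1e-12)
  expect_equal(attr(cs, "weighted_n"),
               nrow(eligible_population(w$pop, 2006)))
})

test_that("follow-up-year comparisons use the estimation module's p-values", {
  w <- small_world()
  cs <- suppressWarnings(cross_sectional_report(w$panel, w$pop, 2008))
  d <- sample_analysis_table(w$panel, w$pop, 2008)
  d$.v_age <- d$age
  est <- suppressWarnings(
    compare_estimate(weighted_mean(d, .v_age),
                     mean(eligible_population(w$pop, 2008)$age)))
  expect_equal(cs$p_value[cs$variable == "age_mean"], est$p_value)
  expect_equal(cs$estimate[cs$variable == "age_mean"], est$point)
})

test_that("cohort comparison is exact when the window has length one", {
  w <- census_world()
  cc <- cohort_comparison(w$panel, w$pop, 2006, 2006)
  expect_equal(cc$estimate[cc$variable == "retention_pct"], 100)
  expect_equal(cc$population_value[cc$variable == "retention_pct"], 100)
  stats <- cc[cc$variable != "retention_pct", ]
  expect_equal(stats$difference, rep(0, nrow(stats)))
})

test_that("cohort retention matches a hand count on a scripted population", {
  # 10 people; 2 die in 2007, 1 moves in 2007, the rest stay eligible
  p06 <- mk_rows(1:10, 2006, county = "A")
  p07 <- dplyr::bind_rows(
    mk_rows(1:7, 2007, county = "A"),
    mk_rows(8, 2007, county = "B"),                     # mover, excluded
    mk_rows(9:10, 2007, county = "A", alive_all_year = FALSE))
  pop <- dplyr::bind_rows(p06, p07)
  panel <- dplyr::bind_rows(
    new_panel_sample_for_test(pop, 1:10, 2006),
    new_panel_sample_for_test(pop, 1:7, 2007))
  cc <- cohort_comparison(panel, pop, 2006, 2007)
  # population: 9 non-movers at baseline, 7 continuously eligible
  expect_equal(cc$population_value[cc$variable == "retention_pct"], 100 * 7 / 9)
  expect_equal(cc$estimate[cc$variable == "retention_pct"], 100 * 7 / 9)
})

test_that("cohort retention gap between sample and population stays small", {
  pop <- synthetic_population(n_counties = 8, total_population = 20000,
                              years = 2006:2010, seed = 43)
  panel <- suppressWarnings(
    run_panel(pop, total_target = 8000, county_min = 300, race_min = 150,
              min_fill = 10, seed = 43))
  cc <- suppressWarnings(cohort_comparison(panel, pop, 2006, 2010))
  gap <- cc$difference[cc$variable == "retention_pct"]
  expect_lt(abs(gap), 3)
})

test_that("age-distribution overlays conserve both totals", {
  w <- small_world()
  ov <- age_distribution_overlay(w$panel, w$pop, 2009)
  expect_equal(sum(ov$population_n),
               nrow(eligible_population(w$pop, 2009)))
  expect_equal(sum(ov$sample_weighted_n),
               sum(w$panel$weight[w$panel$year == 2009]))
  expect_true(all(ov$age_lo >= 65))
})

test_that("report plots build without error", {
  w <- small_world()
  p1 <- ggplot2::autoplot(retention_matrix(w$panel))
  expect_s3_class(p1, "ggplot")
  p2 <- ggplot2::autoplot(age_distribution_overlay(w$panel, w$pop, 2008))
  expect_s3_class(p2, "ggplot")
})
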