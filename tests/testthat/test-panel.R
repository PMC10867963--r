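test_that("baseline weights are N_h/n_h and sum to the stratum populations", {
  w <- replicate_world()
  smp <- draw_baseline(w$pop, w$plan, seed = 1)
  per <- dplyr::count(dplyr::as_tibble(smp), county, race_group,
                      wt = weight, name = "wsum")
  plan <- dplyr::as_tibble(w$plan)
  m <- dplyr::left_join(plan, per, by = c("county", "race_group"))
  expect_equal(m$wsum, as.numeric(m$population_size))
  # summing over all strata reproduces the eligible population total exactly
  expect_equal(sum(smp$weight), nrow(w$pop))
  # per-row weight is the stratum population over the stratum sample size
  chk <- dplyr::count(dplyr::as_tibble(smp), county, race_group,
                      stratum_pop, weight)
  expect_equal(chk$weight, chk$stratum_pop / chk$n)
  # census strata have weight exactly 1
  census <- chk[chk$n == chk$stratum_pop, ]
  if (nrow(census) > 0) expect_true(all(census$weight == 1))
})

test_that("baseline draws are seed-reproducible and match their plan", {
  w <- replicate_world()
  expect_identical(draw_baseline(w$pop, w$plan, seed = 5),
                   draw_baseline(w$pop, w$plan, seed = 5))
  expect_false(identical(draw_baseline(w$pop, w$plan, seed = 5),
                         draw_baseline(w$pop, w$plan, seed = 6)))
  per <- dplyr::count(dplyr::as_tibble(draw_baseline(w$pop, w$plan, seed = 2)),
                      county, race_group)
  expect_identical(per$n, dplyr::as_tibble(w$plan)$target_n)
  # a plan built from a different population errors
  other <- generate_baseline_population(generate_counties(8, 2400, seed = 99),
                                        seed = 99)
  expect_error(draw_baseline(other, w$plan, seed = 1), "does not match")
})

test_that("retention classification distinguishes every exit reason", {
  pop <- two_year_pop()
  smp <- new_panel_sample_for_test(pop, ids = 1:6)
  ret <- classify_retention(smp, pop[pop$year == 2007, ],
                            pop[pop$year == 2006, ])
  got <- setNames(ret$reason, ret$beneficiary_id)
  expect_true(all(ret$retained[ret$beneficiary_id %in% c(1, 6)]))
  expect_identical(got[["2"]], "moved")
  expect_identical(got[["3"]], "lost_ffs")
  expect_identical(got[["4"]], "died")
  expect_identical(got[["5"]], "died")
  # corrupt input: sampled id absent from both year tables
  ghost <- smp; ghost$beneficiary_id[1] <- 999L
  expect_error(classify_retention(ghost, pop[pop$year == 2007, ],
                                  pop[pop$year == 2006, ]), "absent")
})

test_that("the fill-in frame is the newly eligible plus in-movers", {
  pop <- two_year_pop()
  frame <- build_fillin_frame(pop[pop$year == 2007, ], pop[pop$year == 2006, ])
  # continuously eligible same-county members are excluded
  expect_false(any(frame$beneficiary_id %in% c(1, 6)))
  # newly eligible (e.g. first diagnosed this year) are included
  expect_true(7 %in% frame$beneficiary_id)
  # new-but-ineligible (HMO) are not
  expect_false(8 %in% frame$beneficiary_id)
  # the in-set mover enters the frame of the destination county
  expect_identical(frame$county[frame$beneficiary_id == 2], "B")
  expect_error(build_fillin_frame(pop[pop$year == 2006, ],
                                  pop[pop$year == 2007, ]), "consecutive")
})

test_that("fill-in allocation tops strata up to target with a floor of min_fill", {
  pop07 <- mk_rows(1:1000, 2007, county = "A", race_group = "white")
  frame200 <- pop07[1:200, ]
  ret <- tibble::tibble(county = "A", race_group = "white", retained_n = 350L)
  fp <- allocate_fillin(pop07, ret, frame200, total_target = 400,
                        min_fill = 10, county_min = 0, race_min = 0)
  expect_identical(fp$fill_n, 50L)          # max(10, 400 - 350)
  ret$retained_n <- 398L
  fp2 <- allocate_fillin(pop07, ret, frame200, total_target = 400,
                         min_fill = 10, county_min = 0, race_min = 0)
  expect_identical(fp2$fill_n, 10L)         # the per-stratum floor
  # a frame smaller than the required fill is taken whole, with a warning
  expect_warning(
    fp3 <- allocate_fillin(pop07, tibble::tibble(county = "A",
                                                 race_group = "white",
                                                 retained_n = 350L),
                           frame200[1:4, ], total_target = 400,
                           min_fill = 10, county_min = 0, race_min = 0),
    "smaller")
  expect_identical(fp3$fill_n, 4L)
})

test_that("fill-in weights are frame size over fill size", {
  frame <- mk_rows(1:80, 2007, county = "A", race_group = "white")
  pop07 <- dplyr::bind_rows(frame, mk_rows(81:400, 2007, county = "A",
                                           race_group = "white"))
  ret <- tibble::tibble(county = "A", race_group = "white", retained_n = 390L)
  fp <- allocate_fillin(pop07, ret, frame, total_target = 400, min_fill = 10,
                        county_min = 0, race_min = 0)
  smp <- draw_fillin(frame, fp, seed = 3)
  expect_identical(nrow(as.data.frame(smp)), 10L)
  expect_true(all(smp$weight == 8))
  expect_identical(smp$entry_wave, rep(2007L, 10))
  expect_identical(draw_fillin(frame, fp, seed = 3),
                   draw_fillin(frame, fp, seed = 3))
  # weights over a fill-in wave stratum sum exactly to the frame size
  expect_equal(sum(smp$weight), nrow(frame))
  # taking the whole frame gives weight 1
  ret0 <- tibble::tibble(county = "A", race_group = "white", retained_n = 320L)
  fp_all <- allocate_fillin(pop07, ret0, frame, total_target = 400,
                            min_fill = 10, county_min = 0, race_min = 0)
  expect_identical(fp_all$fill_n, 80L)
  expect_true(all(draw_fillin(frame, fp_all, seed = 1)$weight == 1))
})

test_that("the multi-year panel keeps waves disjoint with original weights", {
  w <- small_world()
  panel <- dplyr::as_tibble(w$panel)
  for (yr in unique(panel$year)) {
    expect_identical(anyDuplicated(panel$beneficiary_id[panel$year == yr]), 0L)
  }
  # retained members keep their original weight and wave stratum
  first <- panel[panel$entry_wave == 2006, ]
  traj <- dplyr::summarise(dplyr::group_by(first, beneficiary_id),
                           w = dplyr::n_distinct(weight),
                           cty = dplyr::n_distinct(county), .groups = "drop")
  expect_true(all(traj$w == 1))
  expect_true(all(traj$cty == 1))
  # every sampled person-year is eligible that year
  joined <- dplyr::inner_join(panel, dplyr::as_tibble(w$pop),
                              by = c("beneficiary_id", "year", "county",
                                     "race_group"))
  expect_identical(nrow(joined), nrow(panel))
  expect_true(all(is_eligible(joined)))
  # determinism of the whole pipeline
  again <- suppressWarnings(
    run_panel(w$pop, total_target = 1200, county_min = 80,
              race_min = 40, min_fill = 5, seed = 11))
  expect_identical(as.data.frame(w$panel), as.data.frame(again))
})

test_that("with no exits the fill-in is only the per-stratum floor", {
  cty <- generate_counties(3, 600, seed = 31)
  pop1 <- generate_baseline_population(cty, year = 2006, seed = 31)
  pop2 <- evolve_year(pop1, exit_rate_base = 0, hmo_switch_rate = 0,
                      hmo_return_rate = 0, move_rate = 0, entry_rate = 0.3,
                      incident_diabetes_rate = 0, condition_incidence = 0,
                      seed = 31)
  pop <- dplyr::bind_rows(pop1, pop2)
  panel <- suppressWarnings(
    run_panel(pop, total_target = 300, county_min = 40, race_min = 20,
              min_fill = 5, seed = 31))
  p2 <- dplyr::as_tibble(panel)[panel$year == 2007, ]
  fplan <- attr(panel, "plans")[["2007"]]
  # forced arithmetic: fill = min(frame, max(min_fill, target - retained))
  expect_identical(fplan$fill_n,
                   pmin(fplan$frame_n,
                        pmax(5L, fplan$target_n - fplan$retained_n)))
  # all of last year's sample is retained
  expect_identical(sum(p2$retained),
                   nrow(as.data.frame(panel[panel$year == 2006, ])))
})

test_that("replicate baseline draws are unbiased for the population mean age", {
  w <- replicate_world()
  pop_age <- mean(w$pop$age)
  ests <- vapply(1:200, function(s) {
    smp <- draw_baseline(w$pop, w$plan, seed = s)
    d <- dplyr::left_join(dplyr::as_tibble(smp),
                          w$pop[c("beneficiary_id", "age")],
                          by = "beneficiary_id")
    sum(d$weight * d$age) / sum(d$weight)
  }, 0)
  mc_se <- stats::sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - pop_age), 3 * mc_se)
})

test_that("weighted year totals track the eligible population in every year", {
  pop <- synthetic_population(n_counties = 5, total_population = 2500,
                              years = 2006:2011, seed = 41)
  pop_totals <- vapply(2006:2011,
                       function(y) nrow(eligible_population(pop, y)), 0)
  reps <- lapply(1:12, function(s) {
    panel <- suppressWarnings(
      run_panel(pop, total_target = 1000, county_min = 60, race_min = 30,
                min_fill = 5, seed = 100 + s))
    vapply(2006:2011, function(y) {
      sum(panel$weight[panel$year == y])
    }, 0)
  })
  m <- do.call(rbind, reps)
  for (j in seq_along(pop_totals)) {
    se <- stats::sd(m[, j]) / sqrt(nrow(m))
    tol <- max(3 * se, 1e-6)   # baseline year is exact
    expect_lt(abs(mean(m[, j]) - pop_totals[j]), tol)
  }
})

test_that("panel samples round-trip through CSV", {
  w <- small_world()
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel_sample(w$panel, path)
  back <- read_panel_sample(path)
  expect_equal(strip_attrs(back), strip_attrs(w$panel))
})
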