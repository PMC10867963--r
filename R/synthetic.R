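# Seeded synthetic multi-year beneficiary populations.
#
# Emulates the statistical structure of an aged fee-for-service diabetes
# population observed through annual beneficiary summary files: a few
# hundred counties of very unequal size, ~80% white with county-level
# minority shares, mean age ~75, high chronic-condition prevalences, and
# roughly 84% year-over-year eligibility retention driven by mortality and
# HMO switching.

local_seed <- function(seed, env = parent.frame()) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  expr <- if (had) {
    bquote(assign(".Random.seed", .(old), globalenv()))
  } else {
    quote(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  do.call(on.exit, list(expr, add = TRUE), envir = env)
  set.seed(seed)
}

#' Generate a synthetic county table
#'
#' County populations are drawn from a heavy-tailed log-normal distribution
#' (so a handful of populous counties coexist with many small ones, as in
#' real county systems) and rescaled to sum exactly to `total_population`.
#' Each county receives a minority share drawn from a Beta distribution.
#'
#' @param n_counties Number of counties (>= 2).
#' @param total_population Total eligible beneficiaries across counties.
#' @param size_dispersion Log-scale standard deviation of county sizes; 0
#'   gives equal-sized counties.
#' @param minority_shape_a,minority_shape_b Beta shape parameters for the
#'   county minority share; the default mean is `a / (a + b) = 0.2`.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return Tibble with columns `county`, `eligible_count`, `minority_share`.
#' @export
#' @examples
#' generate_counties(5, 5000, seed = 1)
generate_counties <- function(n_counties, total_population,
                              size_dispersion = 1.1,
                              minority_shape_a = 2, minority_shape_b = 8,
                              seed = 1) {
  stopifnot(n_counties >= 2, total_population >= n_counties,
            size_dispersion >= 0, minority_shape_a > 0, minority_shape_b > 0)
  local_seed(child_seed(seed, "counties"))
  raw <- rlnorm(n_counties, meanlog = 0, sdlog = size_dispersion)
  sizes <- largest_remainder(total_population, raw)
  # guarantee every county is populated
  while (any(sizes == 0)) {
    i <- which.min(sizes); j <- which.max(sizes)
    sizes[i] <- sizes[i] + 1L; sizes[j] <- sizes[j] - 1L
  }
  tibble(
    county = sprintf("c%0*d", nchar(n_counties), seq_len(n_counties)),
    eligible_count = sizes,
    minority_share = rbeta(n_counties, minority_shape_a, minority_shape_b)
  )
}

# Underlying normal mean such that the mean of the left-truncated (at
# `lower`) normal hits `target_mean`.
truncnorm_location <- function(target_mean, sd, lower = 65) {
  f <- function(mu) {
    a <- (lower - mu) / sd
    mu + sd * dnorm(a) / (1 - pnorm(a)) - target_mean
  }
  uniroot(f, c(target_mean - 4 * sd, target_mean + sd))$root
}

rtruncnorm_left <- function(n, mean, sd, lower = 65) {
  mu <- truncnorm_location(mean, sd, lower)
  p_low <- pnorm(lower, mu, sd)
  qnorm(p_low + runif(n) * (1 - p_low), mu, sd)
}

#' Generate a synthetic baseline beneficiary-year table
#'
#' One row per eligible beneficiary in the baseline year: every row has the
#' diabetes flag set, 12 months of fee-for-service enrollment, and survives
#' the year. Race is assigned per person from the county minority share;
#' ages come from a truncated (>= 65) normal whose post-truncation mean
#' matches `age_mean`; sex and the 21 condition flags are independent
#' Bernoulli draws at their target rates.
#'
#' @param counties County table from [generate_counties()].
#' @param year Baseline calendar year.
#' @param age_mean,age_sd Target mean and (pre-truncation) SD of age.
#' @param pct_male Proportion male.
#' @param condition_prevalences Named vector of 21 proportions; defaults to
#'   [default_condition_prevalences()].
#' @param seed Integer seed.
#' @return Beneficiary-year tibble (see [validate_population()] for schema).
#' @export
generate_baseline_population <- function(counties, year = 2006,
                                         age_mean = 75.09, age_sd = 7.5,
                                         pct_male = 0.429,
                                         condition_prevalences =
                                           default_condition_prevalences(),
                                         seed = 1) {
  stopifnot(all(condition_prevalences >= 0), all(condition_prevalences <= 1),
            pct_male >= 0, pct_male <= 1, age_sd > 0)
  prev <- condition_prevalences[condition_names()]
  if (anyNA(prev)) abort("condition_prevalences must name all 21 conditions")
  local_seed(child_seed(seed, "baseline", year))
  n_total <- sum(counties$eligible_count)
  pop <- tibble(
    beneficiary_id = seq_len(n_total),
    year = as.integer(year),
    county = rep(counties$county, counties$eligible_count),
    race_group = ifelse(
      runif(n_total) < rep(counties$minority_share, counties$eligible_count),
      "minority", "white"),
    age = as.integer(round(rtruncnorm_left(n_total, age_mean, age_sd))),
    sex = ifelse(runif(n_total) < pct_male, "male", "female"),
    ffs_months = 12L,
    has_diabetes = TRUE,
    alive_all_year = TRUE
  )
  for (cond in condition_names()) {
    pop[[cond]] <- runif(n_total) < prev[[cond]]
  }
  pop
}

#' Advance a synthetic population by one year
#'
#' Applies the annual transitions a beneficiary population undergoes:
#' mid-year decedents of year `t` leave the table; each survivor may die
#' during year `t+1` (probability logistic in age, `exit_rate_base` at age
#' 75, increasing with `mortality_age_slope` per year of age), switch into
#' an HMO (fewer than 12 FFS months), return from an HMO, or move to a
#' county drawn proportional to county size; survivors age by one year and
#' may accrue new condition flags (which never revert). New eligibles enter
#' as new FFS enrollees around age 65 (`entry_rate`) or as newly diagnosed
#' diabetics at population ages (`incident_diabetes_rate`); their ids are
#' disjoint from existing ones.
#'
#' Default rates are calibrated so that roughly 84% of one year's eligibles
#' are still eligible in the same county the next year, and the eligible
#' population grows slowly.
#'
#' @param population Beneficiary-year table for year `t` (one year only).
#' @param exit_rate_base Death probability at age 75.
#' @param mortality_age_slope Log-odds increase in death risk per year of age.
#' @param hmo_switch_rate Annual probability an FFS enrollee switches to an HMO.
#' @param hmo_return_rate Annual probability an HMO enrollee returns to FFS.
#' @param move_rate Annual probability of moving county.
#' @param entry_rate New-enrollee entries as a fraction of current eligibles.
#' @param incident_diabetes_rate Newly diagnosed entries as a fraction of
#'   current eligibles.
#' @param condition_incidence Annual per-condition accrual probability.
#' @param seed Integer seed.
#' @return Beneficiary-year tibble for year `t+1`, with an `exits` attribute
#'   recording each exit reason (`died`, `lost_ffs`, `moved`) for audit.
#' @export
evolve_year <- function(population,
                        exit_rate_base = 0.07,
                        mortality_age_slope = 0.08,
                        hmo_switch_rate = 0.07,
                        hmo_return_rate = 0.30,
                        move_rate = 0.02,
                        entry_rate = 0.07,
                        incident_diabetes_rate = 0.07,
                        condition_incidence = 0.02,
                        seed = 1) {
  rates <- c(exit_rate_base, hmo_switch_rate, hmo_return_rate, move_rate,
             entry_rate, incident_diabetes_rate, condition_incidence)
  stopifnot(all(rates >= 0), all(rates <= 1), mortality_age_slope >= 0)
  yr <- unique(population$year)
  if (length(yr) != 1) abort("evolve_year() expects a single-year table")
  local_seed(child_seed(seed, "evolve", yr))

  n_elig <- sum(is_eligible(population))
  nxt <- population[as.logical(population$alive_all_year), , drop = FALSE]
  n <- nrow(nxt)
  nxt$year <- as.integer(yr + 1)
  nxt$age <- nxt$age + 1L

  # mortality during year t+1: logistic-in-age hazard
  p_die <- if (exit_rate_base == 0) rep(0, n) else
    plogis(qlogis(exit_rate_base) + mortality_age_slope * (nxt$age - 75))
  dies <- runif(n) < p_die
  nxt$alive_all_year <- !dies

  # HMO transitions (survivors only keep evolving; decedents keep status)
  was_ffs <- nxt$ffs_months == 12
  to_hmo <- was_ffs & !dies & runif(n) < hmo_switch_rate
  back_ffs <- !was_ffs & !dies & runif(n) < hmo_return_rate
  nxt$ffs_months[to_hmo] <- sample(0:11, sum(to_hmo), replace = TRUE)
  nxt$ffs_months[back_ffs] <- 12L

  # moves: destination proportional to county size
  county_sizes <- table(population$county)
  moves <- !dies & runif(n) < move_rate
  if (any(moves)) {
    dest <- sample(names(county_sizes), sum(moves), replace = TRUE,
                   prob = as.numeric(county_sizes))
    nxt$county[moves] <- dest
  }

  # condition accrual (ever-flags only gain)
  if (condition_incidence > 0) {
    for (cond in condition_names()) {
      nxt[[cond]] <- nxt[[cond]] | (runif(n) < condition_incidence)
    }
  }

  # entrants
  base_id <- max(population$beneficiary_id)
  n_new <- round(entry_rate * n_elig)
  n_inc <- round(incident_diabetes_rate * n_elig)
  entrants <- NULL
  if (n_new + n_inc > 0) {
    surv_ages <- nxt$age[!dies]
    if (length(surv_ages) == 0) surv_ages <- 75L
    prev_now <- vapply(condition_names(),
                       function(cond) mean(population[[cond]]), 0)
    entrants <- tibble(
      beneficiary_id = base_id + seq_len(n_new + n_inc),
      year = as.integer(yr + 1),
      county = sample(names(county_sizes), n_new + n_inc, replace = TRUE,
                      prob = as.numeric(county_sizes)),
      race_group = sample(population$race_group, n_new + n_inc, replace = TRUE),
      age = c(65L + rbinom(n_new, 4, 0.15),
              as.integer(sample(surv_ages, n_inc, replace = TRUE))),
      sex = sample(population$sex, n_new + n_inc, replace = TRUE),
      ffs_months = 12L,
      has_diabetes = TRUE,
      alive_all_year = TRUE
    )
    for (cond in condition_names()) {
      # entrants are younger / newly diagnosed: thinner condition history
      entrants[[cond]] <- runif(n_new + n_inc) < 0.5 * prev_now[[cond]]
    }
  }
  out <- bind_rows(nxt, entrants)

  reasons <- dplyr::case_when(
    dies ~ "died",
    to_hmo ~ "lost_ffs",
    moves ~ "moved",
    TRUE ~ NA_character_
  )
  attr(out, "exits") <- tibble(beneficiary_id = nxt$beneficiary_id,
                               reason = reasons)[!is.na(reasons), ]
  out
}

#' Simulate a multi-year synthetic beneficiary population
#'
#' Convenience wrapper: generates counties, draws the baseline year, and
#' evolves the population through `years`, returning one combined
#' beneficiary-year table. All randomness derives from `seed`.
#'
#' @param n_counties,total_population,size_dispersion,minority_shape_a,minority_shape_b
#'   Passed to [generate_counties()].
#' @param years Vector of consecutive calendar years; the first is the
#'   baseline.
#' @param seed Integer master seed.
#' @param ... Further arguments passed to [generate_baseline_population()]
#'   and [evolve_year()] (matched by name).
#' @return Multi-year beneficiary-year tibble, with the county table in the
#'   `counties` attribute.
#' @export
#' @examples
#' pop <- synthetic_population(n_counties = 4, total_population = 1000,
#'                             years = 2006:2008, seed = 7)
#' dplyr::count(pop, year)
synthetic_population <- function(n_counties = 600,
                                 total_population = 1900000,
                                 years = 2006,
                                 size_dispersion = 1.1,
                                 minority_shape_a = 2,
                                 minority_shape_b = 8,
                                 seed = 1, ...) {
  dots <- list(...)
  pick <- function(f, extra) {
    ok <- intersect(names(dots), setdiff(names(formals(f)), names(extra)))
    c(extra, dots[ok])
  }
  counties <- generate_counties(n_counties, total_population,
                                size_dispersion, minority_shape_a,
                                minority_shape_b, seed = seed)
  base <- do.call(generate_baseline_population,
                  pick(generate_baseline_population,
                       list(counties = counties, year = years[1], seed = seed)))
  out <- vector("list", length(years))
  out[[1]] <- base
  cur <- base
  for (i in seq_along(years)[-1]) {
    cur <- do.call(evolve_year,
                   pick(evolve_year, list(population = cur,
                                          seed = child_seed(seed, years[i]))))
    out[[i]] <- cur
  }
  res <- bind_rows(out)
  attr(res, "counties") <- counties
  res
}
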