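# Validation reports: retention matrix, cross-sectional demographic and
# prevalence comparisons, longitudinal cohort comparison, age-distribution
# overlay. Every report is a pure function of (panel, population); the
# p-values come from the estimation module's single code path.

#' Longitudinal retention matrix
#'
#' Counts sampled members by follow-up year and entry wave, with each cell
#' also expressed as a percent of its wave's initial size. Diagonal cells
#' (follow-up year equal to entry wave) are 100% by construction and each
#' wave's column is non-increasing down follow-up years.
#'
#' @param panel A `panel_sample`.
#' @return A `retention_matrix` tibble: `follow_up_year, entry_wave, n,
#'   pct` (percent of the wave's initial size).
#' @export
retention_matrix <- function(panel) {
  counts <- count(as_tibble(panel), follow_up_year = .data$year,
                  entry_wave = .data$entry_wave, name = "n")
  initial <- counts |>
    filter(.data$follow_up_year == .data$entry_wave) |>
    select("entry_wave", initial_n = "n")
  out <- counts |>
    left_join(initial, by = "entry_wave") |>
    mutate(pct = 100 * .data$n / .data$initial_n) |>
    select("follow_up_year", "entry_wave", "n", "pct") |>
    arrange(.data$follow_up_year, .data$entry_wave)
  structure(out, class = c("retention_matrix", class(out)))
}

#' @export
print.retention_matrix <- function(x, ...) {
  wide <- as_tibble(x) |>
    mutate(cell = sprintf("%d (%.1f%%)", .data$n, .data$pct)) |>
    select("follow_up_year", "entry_wave", "cell") |>
    tidyr::pivot_wider(names_from = "entry_wave", values_from = "cell")
  cat("<retention_matrix> count (% of wave's initial size)\n")
  print(as_tibble(wide), n = Inf)
  invisible(x)
}

compare_rows <- function(data, pop, vars) {
  purrr::map_dfr(vars, function(v) {
    est <- compare_estimate(
      weighted_mean(data, !!rlang::sym(paste0(".v_", v$name))),
      v$pop_value)
    tibble(variable = v$label,
           population_value = v$pop_value,
           estimate = est$point,
           se = est$se,
           difference = est$point - v$pop_value,
           p_value = est$p_value)
  })
}

#' Cross-sectional comparison of the weighted sample to the population
#'
#' For one calendar year, compares weighted sample estimates of mean age,
#' percent male and percent white against the corresponding eligible
#' population values, with design-based standard errors and one-sample
#' Wald p-values. Race composition matches the population exactly in the
#' baseline year because race is a stratification variable.
#'
#' @param panel A `panel_sample`.
#' @param population Beneficiary-year table covering `year`.
#' @param year Calendar year to compare.
#' @return Tibble with one row per variable: `variable, population_value,
#'   estimate, se, difference, p_value`, plus attributes `population_n`
#'   and `weighted_n`.
#' @export
cross_sectional_report <- function(panel, population, year) {
  elig <- eligible_population(population, year = year)
  data <- sample_analysis_table(panel, population, year)
  data$.v_age <- data$age
  data$.v_male <- data$sex == "male"
  data$.v_white <- data$race_group == "white"
  vars <- list(
    list(name = "age", label = "age_mean", pop_value = mean(elig$age)),
    list(name = "male", label = "pct_male",
         pop_value = mean(elig$sex == "male")),
    list(name = "white", label = "pct_white",
         pop_value = mean(elig$race_group == "white"))
  )
  out <- compare_rows(data, elig, vars)
  attr(out, "population_n") <- nrow(elig)
  attr(out, "weighted_n") <- sum(data$weight)
  out
}

#' Chronic-condition prevalence comparison
#'
#' Weighted sample prevalence of each chronic condition versus the
#' eligible-population prevalence for one year, with design-based SEs and
#' one-sample p-values.
#'
#' @inheritParams cross_sectional_report
#' @param conditions Condition columns to compare (default all 21).
#' @return Tibble with one row per condition (same columns as
#'   [cross_sectional_report()]).
#' @export
prevalence_report <- function(panel, population, year,
                              conditions = condition_names()) {
  elig <- eligible_population(population, year = year)
  data <- sample_analysis_table(panel, population, year)
  vars <- list()
  for (cond in conditions) {
    data[[paste0(".v_", cond)]] <- as.logical(data[[cond]])
    vars <- c(vars, list(list(name = cond, label = cond,
                              pop_value = mean(as.logical(elig[[cond]])))))
  }
  compare_rows(data, elig, vars)
}

# ids with >1 distinct county among their rows in [baseline, end]
mover_ids <- function(population, ids, baseline_year, end_year) {
  rows <- population[population$beneficiary_id %in% ids &
                       population$year >= baseline_year &
                       population$year <= end_year, , drop = FALSE]
  moved <- rows |>
    group_by(.data$beneficiary_id) |>
    summarise(n_county = dplyr::n_distinct(.data$county), .groups = "drop") |>
    filter(.data$n_county > 1)
  moved$beneficiary_id
}

#' Longitudinal cohort comparison
#'
#' Defines matching cohorts in the sample and the population at
#' `baseline_year` and follows both to `end_year`: cohort members are
#' eligible at baseline and continuously eligible through the end year.
#' Beneficiaries who move between counties during follow-up are removed
#' from both cohorts (numerator and denominator) symmetrically. The
#' retained cohorts are compared at `end_year` on retention percent, mean
#' age, percent male, percent white, and the 21 condition prevalences.
#'
#' @param panel A `panel_sample`.
#' @param population Multi-year beneficiary-year table.
#' @param baseline_year,end_year Follow-up window (inclusive).
#' @return Tibble: a `retention_pct` row (population vs weighted-sample
#'   retention) followed by one row per compared variable.
#' @export
cohort_comparison <- function(panel, population, baseline_year, end_year) {
  stopifnot(baseline_year <= end_year)
  population <- as_tibble(population)
  n_years <- end_year - baseline_year + 1

  elig_base <- eligible_population(population, year = baseline_year)
  pop_movers <- mover_ids(population, elig_base$beneficiary_id,
                          baseline_year, end_year)
  base_ids <- setdiff(elig_base$beneficiary_id, pop_movers)
  window <- population[population$year >= baseline_year &
                         population$year <= end_year, , drop = FALSE]
  elig_window <- window[is_eligible(window) &
                          window$beneficiary_id %in% base_ids, , drop = FALSE]
  kept_ids <- elig_window |>
    count(.data$beneficiary_id, name = "n_y") |>
    filter(.data$n_y == n_years) |>
    pull("beneficiary_id")
  pop_retention <- 100 * length(kept_ids) / length(base_ids)

  smp_base <- as_tibble(panel)[panel$year == baseline_year, , drop = FALSE]
  smp_movers <- mover_ids(population, smp_base$beneficiary_id,
                          baseline_year, end_year)
  smp_base <- smp_base[!smp_base$beneficiary_id %in% smp_movers, , drop = FALSE]
  smp_end <- as_tibble(panel)[panel$year == end_year &
                                panel$beneficiary_id %in%
                                  smp_base$beneficiary_id, , drop = FALSE]
  smp_retention <- 100 * sum(smp_end$weight) / sum(smp_base$weight)

  pop_cohort <- population[population$year == end_year &
                             population$beneficiary_id %in% kept_ids, ,
                           drop = FALSE]
  data <- sample_analysis_table(new_panel_sample(smp_end), population,
                                end_year)
  data$.v_age <- data$age
  data$.v_male <- data$sex == "male"
  data$.v_white <- data$race_group == "white"
  vars <- list(
    list(name = "age", label = "age_mean", pop_value = mean(pop_cohort$age)),
    list(name = "male", label = "pct_male",
         pop_value = mean(pop_cohort$sex == "male")),
    list(name = "white", label = "pct_white",
         pop_value = mean(pop_cohort$race_group == "white"))
  )
  for (cond in condition_names()) {
    data[[paste0(".v_", cond)]] <- as.logical(data[[cond]])
    vars <- c(vars, list(list(name = cond, label = cond,
                              pop_value = mean(as.logical(pop_cohort[[cond]])))))
  }
  stats <- compare_rows(data, pop_cohort, vars)
  bind_rows(
    tibble(variable = "retention_pct", population_value = pop_retention,
           estimate = smp_retention, se = NA_real_,
           difference = smp_retention - pop_retention, p_value = NA_real_),
    stats)
}

#' Weighted sample versus population age distribution
#'
#' Bins ages and contrasts the weighted sample frequencies with the
#' population frequencies for one year. The weighted histogram sums to the
#' weighted sample total and the population histogram to the eligible
#' population count.
#'
#' @inheritParams cross_sectional_report
#' @param bin_width Age bin width in years (default 5).
#' @return An `age_overlay` tibble: `age_lo, age_hi, population_n,
#'   sample_weighted_n`.
#' @export
age_distribution_overlay <- function(panel, population, year, bin_width = 5) {
  elig <- eligible_population(population, year = year)
  data <- sample_analysis_table(panel, population, year)
  lo <- 65
  hi <- max(elig$age, data$age) + 1
  breaks <- seq(lo, hi + bin_width, by = bin_width)
  cut_bin <- function(a) findInterval(a, breaks, rightmost.closed = TRUE)
  pop_n <- tapply(rep(1, nrow(elig)), cut_bin(elig$age), sum)
  smp_n <- tapply(data$weight, cut_bin(data$age), sum)
  bins <- seq_len(length(breaks) - 1)
  out <- tibble(
    age_lo = breaks[bins],
    age_hi = breaks[bins + 1],
    population_n = as.numeric(pop_n[as.character(bins)]),
    sample_weighted_n = as.numeric(smp_n[as.character(bins)])
  ) |>
    tidyr::replace_na(list(population_n = 0, sample_weighted_n = 0)) |>
    filter(.data$population_n > 0 | .data$sample_weighted_n > 0)
  structure(out, class = c("age_overlay", class(out)), year = year)
}
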