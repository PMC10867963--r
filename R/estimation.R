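# Design-based estimation for the stratified without-replacement design:
# Horvitz-Thompson totals, ratio means/proportions with Taylor-series
# (linearization) variance, finite-population correction, and one-sample
# comparisons against known population values.

new_design_estimate <- function(statistic, point, se, n, n_strata,
                                singletons, conf_level = 0.95) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(statistic = statistic, point = point, se = se,
         ci_low = point - z * se, ci_high = point + z * se,
         n = n, n_strata = n_strata, singleton_strata = singletons,
         conf_level = conf_level,
         population_value = NULL, p_value = NULL),
    class = "design_estimate")
}

#' @export
print.design_estimate <- function(x, ...) {
  cat(sprintf("<design_estimate> %s = %.6g (SE %.4g, %g%% CI %.6g to %.6g, n = %d)\n",
              x$statistic, x$point, x$se, 100 * x$conf_level,
              x$ci_low, x$ci_high, x$n))
  if (!is.null(x$p_value)) {
    cat(sprintf("  vs population value %.6g: p = %.4g\n",
                x$population_value, x$p_value))
  }
  invisible(x)
}

#' @export
tidy.design_estimate <- function(x, ...) {
  tibble(statistic = x$statistic, estimate = x$point, std.error = x$se,
         conf.low = x$ci_low, conf.high = x$ci_high,
         population.value = x$population_value %||% NA_real_,
         p.value = x$p_value %||% NA_real_)
}

#' @export
glance.design_estimate <- function(x, ...) {
  tibble(n = x$n, n.strata = x$n_strata,
         singleton.strata = x$singleton_strata,
         conf.level = x$conf_level)
}

# Shared variance machinery: stratum summaries of an analysis variable.
# Strata are the design strata (county x race x entry wave by default);
# N_h comes from the per-row fpc column, n_h from the observed rows.
stratum_summaries <- function(data, y, strata, fpc) {
  strata <- intersect(strata, names(data))
  if (length(strata) == 0) abort("no stratum columns found in data")
  key <- do.call(paste, c(data[strata], sep = "\r"))
  tibble(y = y, N = data[[fpc]], key = key) |>
    group_by(.data$key) |>
    summarise(n_h = n(), N_h = max(.data$N), s2_h = var(.data$y),
              .groups = "drop")
}

variance_total <- function(ss) {
  singletons <- sum(ss$n_h == 1 & ss$N_h > 1)
  if (singletons > 0) {
    warn(sprintf(
      "%d singleton stratum(s) (n_h = 1 < N_h) contribute zero variance; SEs are conservative-low",
      singletons))
  }
  s2 <- ifelse(is.na(ss$s2_h), 0, ss$s2_h)
  v <- sum(ss$N_h^2 * (1 - ss$n_h / ss$N_h) * s2 / ss$n_h)
  list(variance = v, singletons = singletons)
}

#' Design-based estimate of a population total
#'
#' Horvitz-Thompson total `sum(w_i * y_i)` with the stratified
#' without-replacement variance
#' \deqn{\widehat{V} = \sum_h N_h^2 (1 - n_h/N_h)\, s_h^2 / n_h,}
#' where `s_h^2` is the within-stratum sample variance of `y`. The
#' `(1 - n_h/N_h)` finite-population correction makes census strata
#' (weights 1) contribute no variance. Confidence intervals are
#' normal-based.
#'
#' @param data Sampled rows: a `panel_sample` slice (possibly joined to
#'   analysis variables) carrying `weight`, the stratum columns and the
#'   stratum population sizes.
#' @param y Analysis variable: a column name or expression evaluated in
#'   `data` (logicals are treated as 0/1).
#' @param strata Character vector of stratum columns (defaults to the
#'   design strata: county, race group, entry wave; columns absent from
#'   `data` are ignored).
#' @param weight,fpc Names of the weight and stratum-population columns.
#' @param conf_level Confidence level for the normal-based interval.
#' @return A `design_estimate`; see [tidy.design_estimate()].
#' @export
#' @examples
#' pop <- synthetic_population(n_counties = 3, total_population = 900,
#'                             years = 2006, seed = 3)
#' plan <- build_allocation_plan(pop, total_target = 400, county_min = 50,
#'                               race_min = 25)
#' smp <- draw_baseline(pop, plan, seed = 3)
#' smp2 <- dplyr::left_join(smp, pop[c("beneficiary_id", "age")],
#'                          by = "beneficiary_id")
#' weighted_total(smp2, age >= 85)
weighted_total <- function(data, y,
                           strata = c("county", "race_group", "entry_wave"),
                           weight = "weight", fpc = "stratum_pop",
                           conf_level = 0.95) {
  yv <- as.numeric(rlang::eval_tidy(rlang::enquo(y), data))
  if (length(yv) == 0) abort("empty sample")
  if (any(!is.finite(yv))) abort("y must be finite")
  w <- data[[weight]]
  point <- sum(w * yv)
  ss <- stratum_summaries(data, yv, strata, fpc)
  v <- variance_total(ss)
  new_design_estimate("total", point, sqrt(v$variance), length(yv),
                      nrow(ss), v$singletons, conf_level)
}

#' Design-based estimate of a population mean or proportion
#'
#' Ratio mean `sum(w_i y_i) / sum(w_i)` with Taylor-series linearization:
#' the variance of the total estimator is applied to the residuals
#' `z_i = (y_i - mean) / Nhat`, `Nhat = sum(w_i)`. A proportion is the mean
#' of a 0/1 (or logical) variable.
#'
#' @inheritParams weighted_total
#' @return A `design_estimate`.
#' @export
weighted_mean <- function(data, y,
                          strata = c("county", "race_group", "entry_wave"),
                          weight = "weight", fpc = "stratum_pop",
                          conf_level = 0.95) {
  yv <- as.numeric(rlang::eval_tidy(rlang::enquo(y), data))
  if (length(yv) == 0) abort("empty sample")
  if (any(!is.finite(yv))) abort("y must be finite")
  w <- data[[weight]]
  n_hat <- sum(w)
  point <- sum(w * yv) / n_hat
  z <- (yv - point) / n_hat
  ss <- stratum_summaries(data, z, strata, fpc)
  v <- variance_total(ss)
  new_design_estimate("mean", point, sqrt(v$variance), length(yv),
                      nrow(ss), v$singletons, conf_level)
}

#' @rdname weighted_mean
#' @export
weighted_proportion <- function(data, y, ...) {
  est <- weighted_mean(data, {{ y }}, ...)
  est$statistic <- "proportion"
  est
}

#' One-sample comparison of a design estimate to a known population value
#'
#' Wald test with the design-based standard error:
#' `z = (estimate - population_value) / SE`, two-sided normal p-value.
#' A zero SE (census) gives p = 1 when the values agree exactly and p = 0
#' otherwise.
#'
#' @param estimate A `design_estimate`.
#' @param population_value The known population quantity.
#' @return The two-sided p-value (numeric scalar).
#' @export
one_sample_test <- function(estimate, population_value) {
  stopifnot(inherits(estimate, "design_estimate"))
  if (estimate$se == 0) {
    return(if (isTRUE(all.equal(estimate$point, population_value))) 1 else 0)
  }
  z <- (estimate$point - population_value) / estimate$se
  2 * pnorm(-abs(z))
}

#' @describeIn one_sample_test Return the estimate with `population_value`
#'   and `p_value` filled in (used by the reporting functions).
#' @export
compare_estimate <- function(estimate, population_value) {
  estimate$population_value <- population_value
  estimate$p_value <- one_sample_test(estimate, population_value)
  estimate
}

#' Join sampled rows to their analysis variables for one year
#'
#' The panel sample carries only design columns; analyses need the
#' population table's covariates (age, sex, condition flags). This joins
#' the year-`t` sample rows to the year-`t` population rows by beneficiary.
#'
#' @param panel A `panel_sample`.
#' @param population Beneficiary-year table containing year `year`.
#' @param year Calendar year to analyse.
#' @return Tibble of sampled rows with design and analysis columns.
#' @export
sample_analysis_table <- function(panel, population, year) {
  smp <- as_tibble(panel)[panel$year == year, , drop = FALSE]
  pop <- as_tibble(population)
  pop <- pop[pop$year == year, , drop = FALSE]
  keep <- setdiff(names(pop), c("county", "race_group", "year"))
  out <- left_join(smp, pop[keep], by = "beneficiary_id")
  if (anyNA(out$age)) abort("sampled beneficiaries missing from population table")
  out
}
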