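# Per-stratum target sample sizes for one year: county minimums,
# proportional remainder to a fixed total, and the white/minority split
# with smooth oversampling of the smaller group.

#' Smooth minority oversampling fraction
#'
#' Maps the minority proportion `p_r` of a county's unsampled population to
#' the minority proportion `p_s` of the remaining sample allocated to that
#' county, via the cubic
#' \deqn{p_s = 2\,(p_r - 1/2)^3 + (p_r - 1/2)/2 + 1/2.}
#' The curve fixes 0 to 0, 1/2 to 1/2 and 1 to 1, is strictly increasing,
#' and has slope 2 at both endpoints, so whichever group is locally smaller
#' is oversampled at roughly two-to-one when it is rare, transitioning
#' smoothly to equal sampling as the groups approach parity. The symmetry
#' `p_s(1 - x) = 1 - p_s(x)` means the white population is oversampled by
#' the same rule in counties where it is the smaller group.
#'
#' @param p_r Minority proportion(s) of the unsampled population, in `[0, 1]`.
#' @return Sampling proportion(s) `p_s` in `[0, 1]`.
#' @export
#' @examples
#' cubic_split_fraction(c(0, 0.1, 0.5, 0.9, 1))
cubic_split_fraction <- function(p_r) {
  if (any(is.na(p_r)) || any(p_r < 0 | p_r > 1)) {
    abort("p_r must lie in [0, 1]")
  }
  x <- p_r - 0.5
  2 * x^3 + x / 2 + 0.5
}

#' Allocate a fixed total sample across counties
#'
#' Every county first receives `min(county_min, N_c)` (small counties are
#' fully enumerated). The remainder `R = total_target - sum(minimums)` is
#' then apportioned proportionally to each county's unsampled population
#' `N_c - min(county_min, N_c)` using largest-remainder rounding, so the
#' county targets sum exactly to `min(total_target, sum(N_c))` and never
#' exceed any county population. Fractional ties are broken by larger
#' population, then lexicographic county id.
#'
#' @param county_pops Data frame with columns `county` and `eligible_count`
#'   (the county eligible population `N_c`).
#' @param total_target Total sample size to hit.
#' @param county_min Minimum per-county sample (default 500).
#' @return Tibble `county, eligible_count, target_n`, with the realized
#'   remainder sampling rate in attribute `rate`.
#' @export
#' @examples
#' allocate_counties(
#'   tibble::tibble(county = c("a", "b"), eligible_count = c(1000, 3000)),
#'   total_target = 1400)
allocate_counties <- function(county_pops, total_target, county_min = 500) {
  stopifnot(all(c("county", "eligible_count") %in% names(county_pops)),
            all(county_pops$eligible_count >= 0), total_target >= 0)
  cp <- as_tibble(county_pops)
  base <- pmin(county_min, cp$eligible_count)
  if (total_target < sum(base)) {
    abort(paste0("total_target (", total_target,
                 ") is below the sum of county minimums (", sum(base),
                 "); minimums are a hard constraint"))
  }
  avail <- cp$eligible_count - base
  R <- min(total_target - sum(base), sum(avail))
  extra <- largest_remainder(R, avail,
                             tie_size = cp$eligible_count,
                             tie_id = cp$county)
  out <- tibble(county = cp$county,
                eligible_count = cp$eligible_count,
                target_n = as.integer(base + extra))
  attr(out, "rate") <- if (sum(avail) > 0) R / sum(avail) else 0
  out
}

#' Split a county target between the white and minority strata
#'
#' Each group first receives `min(race_min, N_g)`. The remaining county
#' target is split by [cubic_split_fraction()] applied to the minority
#' proportion of the still-unsampled county population, rounding the
#' minority share to the nearest integer and capping at the group
#' populations (overflow is reassigned to the other group), so the two
#' stratum targets always sum to `target_c`.
#'
#' If `target_c` is smaller than the two feasible minimums combined, the
#' minimums are scaled back proportionally with a warning.
#'
#' @param target_c County target sample size.
#' @param n_white,n_minority Group populations in the county.
#' @param race_min Minimum per-group sample (default 250).
#' @return Named integer vector `c(white = ..., minority = ...)`.
#' @export
#' @examples
#' allocate_within_county(1250, n_white = 4000, n_minority = 1000)
allocate_within_county <- function(target_c, n_white, n_minority,
                                   race_min = 250) {
  stopifnot(target_c >= 0, n_white >= 0, n_minority >= 0)
  if (target_c > n_white + n_minority) {
    abort("county target exceeds county population")
  }
  base_w <- min(race_min, n_white)
  base_m <- min(race_min, n_minority)
  if (target_c < base_w + base_m) {
    warn(paste0("county target ", target_c, " below combined race minimums ",
                base_w + base_m, "; scaling minimums back proportionally"))
    scaled <- largest_remainder(target_c, c(base_w, base_m),
                                tie_size = c(n_white, n_minority))
    base_w <- scaled[1]; base_m <- scaled[2]
  }
  remainder <- target_c - base_w - base_m
  avail_w <- n_white - base_w
  avail_m <- n_minority - base_m
  p_r <- if (avail_w + avail_m > 0) avail_m / (avail_w + avail_m) else 0
  n_m <- base_m + round(cubic_split_fraction(p_r) * remainder)
  n_m <- min(n_m, n_minority)
  n_w <- target_c - n_m
  if (n_w > n_white) {         # overflow reassigned symmetrically
    n_w <- n_white
    n_m <- target_c - n_w
  }
  c(white = as.integer(n_w), minority = as.integer(n_m))
}

#' Build the full stratified allocation plan for one year
#'
#' Composes [allocate_counties()] and [allocate_within_county()] over the
#' eligible population of one year: county minimums (default 500) with the
#' proportional remainder towards `total_target`, then race minimums
#' (default 250) and the smooth oversampling split within each county. The
#' plan is deterministic: the same population and parameters always yield
#' the same plan.
#'
#' @param population Beneficiary-year table (a single year; rows are
#'   filtered to eligible beneficiary-years).
#' @param total_target Overall annual sample-size target (default 900000).
#' @param county_min,race_min Stratum minimums.
#' @return An `allocation_plan`: a tibble with one row per
#'   (county, race_group) stratum of positive population, columns
#'   `county, race_group, population_size, target_n`, and attributes `year`,
#'   `total_target` and `rate` (the realized remainder sampling rate).
#' @export
build_allocation_plan <- function(population, total_target = 900000,
                                  county_min = 500, race_min = 250) {
  elig <- eligible_population(population)
  if (nrow(elig) == 0) abort("no eligible beneficiaries in population table")
  yr <- unique(elig$year)
  if (length(yr) != 1) {
    abort("population spans several years; filter to one year first")
  }
  strata <- elig |>
    count(.data$county, .data$race_group, name = "population_size")
  county_pops <- strata |>
    group_by(.data$county) |>
    summarise(eligible_count = sum(.data$population_size), .groups = "drop")
  county_alloc <- allocate_counties(county_pops, total_target, county_min)

  wide <- strata |>
    tidyr::pivot_wider(names_from = "race_group",
                       values_from = "population_size", values_fill = 0L)
  if (!"white" %in% names(wide)) wide$white <- 0L
  if (!"minority" %in% names(wide)) wide$minority <- 0L
  wide <- left_join(wide, county_alloc[c("county", "target_n")], by = "county")

  split <- purrr::pmap(
    list(wide$target_n, wide$white, wide$minority),
    function(t, w, m) allocate_within_county(t, w, m, race_min)
  )
  plan <- tibble(
    county = rep(wide$county, each = 2),
    race_group = rep(c("white", "minority"), nrow(wide)),
    population_size = as.integer(rbind(wide$white, wide$minority)),
    target_n = as.integer(unlist(split))
  ) |>
    filter(.data$population_size > 0) |>
    arrange(.data$county, .data$race_group)

  structure(plan,
            class = c("allocation_plan", class(plan)),
            year = as.integer(yr),
            total_target = as.integer(total_target),
            rate = attr(county_alloc, "rate"))
}

#' @export
print.allocation_plan <- function(x, ...) {
  cat(sprintf(
    "<allocation_plan> year %d: %d strata in %d counties, total n = %d (target %d), remainder rate %.3f\n",
    attr(x, "year"), nrow(x), length(unique(x$county)), sum(x$target_n),
    attr(x, "total_target"), attr(x, "rate")))
  NextMethod()
}

#' Write or read an allocation plan as CSV
#'
#' The realized remainder rate, year and target are stored in `# key: value`
#' header comments above the column header.
#'
#' @param plan An `allocation_plan`.
#' @param path File path.
#' @return `write_allocation_plan()` returns `path` invisibly;
#'   `read_allocation_plan()` returns the plan.
#' @export
write_allocation_plan <- function(plan, path) {
  hdr <- sprintf("# %s: %s", c("year", "total_target", "rate"),
                 c(attr(plan, "year"), attr(plan, "total_target"),
                   format(attr(plan, "rate"), digits = 15)))
  writeLines(c(hdr, readr::format_csv(as_tibble(plan))), path)
  invisible(path)
}

#' @rdname write_allocation_plan
#' @export
read_allocation_plan <- function(path) {
  hdr <- grep("^#", readLines(path, n = 10), value = TRUE)
  meta <- strsplit(sub("^# ", "", hdr), ": ")
  meta <- setNames(vapply(meta, `[`, "", 2), vapply(meta, `[`, "", 1))
  plan <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                          progress = FALSE)
  structure(plan,
            class = c("allocation_plan", class(plan)),
            year = as.integer(meta[["year"]]),
            total_target = as.integer(meta[["total_target"]]),
            rate = as.numeric(meta[["rate"]]))
}
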