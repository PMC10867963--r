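# Drawing and maintaining the multi-year panel: baseline draw, retention,
# fill-in frames, fill-in allocation and draws, weights.

new_panel_sample <- function(rows) {
  rows <- as_tibble(rows)
  for (a in setdiff(names(attributes(rows)),
                    c("names", "row.names", "class"))) {
    attr(rows, a) <- NULL
  }
  structure(rows, class = c("panel_sample", setdiff(class(rows), "panel_sample")))
}

#' @export
print.panel_sample <- function(x, ...) {
  yrs <- sort(unique(x$year))
  cat(sprintf("<panel_sample> %d sampled person-years, years %s-%s\n",
              nrow(x), min(yrs), max(yrs)))
  NextMethod()
}

stratum_key <- function(df) paste(df$county, df$race_group, sep = "\r")

# SRS without replacement within each stratum of `frame_rows`, taking
# `take$n` members of each stratum in `take` (county, race_group, n).
# Per-stratum child seeds make the draw reproducible and order-independent.
draw_within_strata <- function(frame_rows, take, seed, year, tag) {
  key <- stratum_key(frame_rows)
  idx <- split(seq_len(nrow(frame_rows)), key)
  take <- take[take$n > 0, , drop = FALSE]
  picked <- vector("list", nrow(take))
  for (i in seq_len(nrow(take))) {
    k <- paste(take$county[i], take$race_group[i], sep = "\r")
    rows <- idx[[k]]
    if (is.null(rows) || length(rows) < take$n[i]) {
      abort(sprintf("stratum %s/%s: cannot draw %d from %d frame members",
                    take$county[i], take$race_group[i], take$n[i],
                    length(rows)))
    }
    set.seed(child_seed(seed, tag, year, take$county[i], take$race_group[i]))
    picked[[i]] <- sample_exact(rows, take$n[i])
  }
  frame_rows[sort(unlist(picked)), , drop = FALSE]
}

#' Draw the baseline stratified sample
#'
#' Simple random sampling without replacement within each (county, race)
#' stratum, taking exactly the plan's `target_n` members. Sampling weights
#' are the Horvitz-Thompson weights of the design: stratum population size
#' divided by stratum sample size, so weights over any stratum sum exactly
#' to its population size.
#'
#' @param population Beneficiary-year table containing the plan's year.
#' @param plan An [build_allocation_plan()] result built from the same
#'   population (stratum population sizes are cross-checked).
#' @param seed Integer master seed; per-stratum child seeds are derived from
#'   (seed, year, county, race group).
#' @return A `panel_sample` tibble with columns `beneficiary_id, year,
#'   county, race_group, entry_wave, weight, stratum_pop, retained`
#'   (`retained = FALSE` for a baseline draw; `stratum_pop` is the stratum
#'   population size `N_h` used for finite-population-corrected variances).
#' @export
draw_baseline <- function(population, plan, seed = 1) {
  yr <- attr(plan, "year")
  elig <- eligible_population(population, year = yr)
  counts <- count(elig, .data$county, .data$race_group, name = "pop_n")
  chk <- left_join(as_tibble(plan), counts, by = c("county", "race_group"))
  if (anyNA(chk$pop_n) || any(chk$pop_n != chk$population_size)) {
    abort("plan does not match population: stratum sizes differ")
  }
  take <- tibble(county = plan$county, race_group = plan$race_group,
                 n = plan$target_n)
  picked <- draw_within_strata(elig, take, seed, yr, "baseline")
  wt <- tibble(county = plan$county, race_group = plan$race_group,
               stratum_pop = plan$population_size,
               weight = plan$population_size / plan$target_n)
  out <- picked |>
    select("beneficiary_id", "year", "county", "race_group") |>
    left_join(wt, by = c("county", "race_group")) |>
    mutate(entry_wave = as.integer(yr), retained = FALSE)
  new_panel_sample(out[c("beneficiary_id", "year", "county", "race_group",
                         "entry_wave", "weight", "stratum_pop", "retained")])
}

#' Classify year-over-year retention of a sample
#'
#' A sampled beneficiary is retained into year `t+1` when still eligible
#' (alive all year, 12 months fee-for-service, diabetes flag) *and* still in
#' the same county; everyone else exits with a reason. Beneficiaries absent
#' from the year `t+1` table are classified as deaths (the population table
#' drops beneficiaries after their death year); a beneficiary absent from
#' the year `t` population as well indicates corrupt input and errors.
#'
#' @param sample_t `panel_sample` rows for year `t`.
#' @param population_next Beneficiary-year table for year `t+1`.
#' @param population_t Optional year-`t` table used only for the
#'   data-integrity check.
#' @return Tibble `beneficiary_id, retained, reason` with reason one of
#'   `died, lost_ffs, moved, other_ineligible` (`NA` when retained).
#' @export
classify_retention <- function(sample_t, population_next, population_t = NULL) {
  yr <- unique(sample_t$year)
  if (length(yr) != 1) abort("sample_t must contain a single year")
  nxt <- population_next[population_next$year == yr + 1, , drop = FALSE]
  m <- left_join(
    as_tibble(sample_t)[c("beneficiary_id", "county")],
    nxt[c("beneficiary_id", "county", "ffs_months", "has_diabetes",
          "alive_all_year")],
    by = "beneficiary_id", suffix = c("", "_next"))
  if (!is.null(population_t)) {
    missing_both <- !(m$beneficiary_id %in% population_t$beneficiary_id) &
      is.na(m$ffs_months)
    if (any(missing_both)) {
      abort("sampled beneficiaries absent from both year tables")
    }
  }
  elig_next <- !is.na(m$ffs_months) & as.logical(m$has_diabetes) &
    as.logical(m$alive_all_year) & m$ffs_months == 12
  retained <- elig_next & m$county_next == m$county
  reason <- dplyr::case_when(
    retained ~ NA_character_,
    is.na(m$ffs_months) | !as.logical(m$alive_all_year) ~ "died",
    m$ffs_months < 12 ~ "lost_ffs",
    elig_next & m$county_next != m$county ~ "moved",
    TRUE ~ "other_ineligible"
  )
  tibble(beneficiary_id = m$beneficiary_id, retained = retained,
         reason = reason)
}

#' Build the newly-eligible fill-in frame for a follow-up year
#'
#' The frame for year `t+1` contains the beneficiaries eligible in `t+1` who
#' could not have been sampled in year `t`: those ineligible in `t` (not yet
#' enrolled, in an HMO, not yet diagnosed) plus in-county movers, who enter
#' the frame of their destination county. This is exactly the complement of
#' the retained set within the year `t+1` eligible population.
#'
#' @param population_next,population_t Beneficiary-year tables for `t+1`
#'   and `t` (may be slices of one multi-year table).
#' @return Tibble of eligible year `t+1` rows forming the frame.
#' @export
build_fillin_frame <- function(population_next, population_t) {
  yr_next <- unique(population_next$year)
  yr_t <- unique(population_t$year)
  if (length(yr_next) != 1 || length(yr_t) != 1 || yr_next != yr_t + 1) {
    abort("build_fillin_frame() expects single-year tables for consecutive years")
  }
  elig_next <- eligible_population(population_next)
  elig_t <- eligible_population(population_t)
  prev <- tibble(beneficiary_id = elig_t$beneficiary_id,
                 county_prev = elig_t$county)
  m <- left_join(elig_next, prev, by = "beneficiary_id")
  new_or_moved <- is.na(m$county_prev) | m$county_prev != m$county
  elig_next[new_or_moved, , drop = FALSE]
}

#' Allocate the fill-in sample across wave strata
#'
#' Re-runs the baseline allocation procedure on the *full* year `t+1`
#' eligible population to obtain what each (county, race) stratum's target
#' would have been, then fills each stratum up from its newly-eligible
#' frame: at least `min_fill` members per stratum (so new beneficiaries
#' enter every county every year), more where retention fell short of the
#' target, capped by the frame size. Strata whose frame is empty receive 0
#' with a warning.
#'
#' @param population_next Beneficiary-year table for year `t+1`.
#' @param retained `panel_sample` rows retained into year `t+1` (their
#'   county/race strata are counted), or a pre-counted tibble
#'   `county, race_group, retained_n`.
#' @param frame Fill-in frame from [build_fillin_frame()].
#' @param total_target,county_min,race_min Passed to
#'   [build_allocation_plan()].
#' @param min_fill Minimum fill-in per stratum with a nonempty frame
#'   (default 10).
#' @return A `fillin_plan` tibble: `county, race_group, population_size,
#'   target_n, retained_n, frame_n, fill_n`, with attribute `year`.
#' @export
allocate_fillin <- function(population_next, retained, frame,
                            total_target = 900000, min_fill = 10,
                            county_min = 500, race_min = 250) {
  target_plan <- build_allocation_plan(population_next, total_target,
                                       county_min, race_min)
  ret_counts <- if (all(c("retained_n") %in% names(retained))) {
    as_tibble(retained)
  } else {
    count(as_tibble(retained), .data$county, .data$race_group,
          name = "retained_n")
  }
  frame_counts <- count(as_tibble(frame), .data$county, .data$race_group,
                        name = "frame_n")
  plan <- as_tibble(target_plan) |>
    left_join(ret_counts, by = c("county", "race_group")) |>
    left_join(frame_counts, by = c("county", "race_group")) |>
    mutate(
      retained_n = dplyr::coalesce(.data$retained_n, 0L),
      frame_n = dplyr::coalesce(.data$frame_n, 0L),
      fill_n = as.integer(pmin(.data$frame_n,
                               pmax(min_fill,
                                    .data$target_n - .data$retained_n)))
    )
  n_short <- sum(plan$fill_n < pmax(min_fill,
                                    plan$target_n - plan$retained_n))
  if (n_short > 0) {
    warn(sprintf(
      "%d stratum(s) have fill-in frames smaller than the required fill (empty frames get 0)",
      n_short))
  }
  structure(plan, class = c("fillin_plan", class(plan)),
            year = attr(target_plan, "year"))
}

#' Draw the fill-in sample from the newly-eligible frame
#'
#' Simple random sampling without replacement within each (county, race)
#' stratum of the frame. Fill-in weights are the frame size divided by the
#' fill-in sample size, so weights over a fill-in wave stratum sum exactly
#' to the frame size; the wave stratum is (county, race group, entry year).
#'
#' @param frame Frame table from [build_fillin_frame()].
#' @param fillin_plan Plan from [allocate_fillin()].
#' @param seed Integer master seed.
#' @return `panel_sample` rows for year `t+1` with `entry_wave = t+1`.
#' @export
draw_fillin <- function(frame, fillin_plan, seed = 1) {
  yr <- attr(fillin_plan, "year")
  take <- tibble(county = fillin_plan$county,
                 race_group = fillin_plan$race_group,
                 n = fillin_plan$fill_n)
  picked <- draw_within_strata(frame, take, seed, yr, "fillin")
  wt <- tibble(county = fillin_plan$county,
               race_group = fillin_plan$race_group,
               stratum_pop = fillin_plan$frame_n,
               weight = ifelse(fillin_plan$fill_n > 0,
                               fillin_plan$frame_n / fillin_plan$fill_n, NA))
  out <- picked |>
    select("beneficiary_id", "year", "county", "race_group") |>
    left_join(wt, by = c("county", "race_group")) |>
    mutate(entry_wave = as.integer(yr), retained = FALSE)
  new_panel_sample(out[c("beneficiary_id", "year", "county", "race_group",
                         "entry_wave", "weight", "stratum_pop", "retained")])
}

#' Run the full multi-year panel
#'
#' Draws the baseline sample in the first year, then for each subsequent
#' year keeps every retained member (original weight, original wave
#' stratum) and tops the sample up with a weighted fill-in draw from that
#' year's newly-eligible frame. Each year's sample is therefore
#' simultaneously a valid cross-sectional sample of that year's population
#' and the continuation of all earlier waves.
#'
#' @param population Multi-year beneficiary-year table with consecutive
#'   years.
#' @param total_target Annual sample-size target.
#' @param county_min,race_min,min_fill Allocation parameters.
#' @param seed Integer master seed (all per-year, per-stratum seeds derive
#'   from it).
#' @param years Years to run (default: all years present).
#' @return A `panel_sample` covering all years; the baseline and fill-in
#'   plans are kept in the `plans` attribute.
#' @export
#' @examples
#' pop <- synthetic_population(n_counties = 4, total_population = 2000,
#'                             years = 2006:2008, seed = 2)
#' panel <- run_panel(pop, total_target = 800, county_min = 50,
#'                    race_min = 25, seed = 2)
#' dplyr::count(panel, year, entry_wave)
run_panel <- function(population, total_target = 900000, county_min = 500,
                      race_min = 250, min_fill = 10, seed = 1,
                      years = NULL) {
  population <- as_tibble(population)
  yrs <- sort(unique(population$year))
  if (!is.null(years)) yrs <- intersect(yrs, years)
  if (any(diff(yrs) != 1)) abort("population years must be consecutive")
  pop_by_year <- split(population, population$year)[as.character(yrs)]

  plan0 <- build_allocation_plan(pop_by_year[[1]], total_target,
                                 county_min, race_min)
  cur <- draw_baseline(pop_by_year[[1]], plan0, seed = seed)
  out <- vector("list", length(yrs))
  out[[1]] <- cur
  plans <- list(plan0)

  for (i in seq_along(yrs)[-1]) {
    pop_t <- pop_by_year[[i - 1]]
    pop_next <- pop_by_year[[i]]
    ret <- classify_retention(cur, pop_next, pop_t)
    kept <- cur[ret$retained[match(cur$beneficiary_id, ret$beneficiary_id)], ,
                drop = FALSE]
    kept$year <- as.integer(yrs[i])
    kept$retained <- TRUE
    frame <- build_fillin_frame(pop_next, pop_t)
    fplan <- allocate_fillin(pop_next, kept, frame, total_target,
                             min_fill, county_min, race_min)
    fill <- draw_fillin(frame, fplan, seed = seed)
    cur <- new_panel_sample(bind_rows(kept, fill))
    if (anyDuplicated(cur$beneficiary_id) > 0) {
      abort("internal error: beneficiary sampled twice in one year")
    }
    out[[i]] <- cur
    plans[[i]] <- fplan
  }
  res <- new_panel_sample(bind_rows(out))
  attr(res, "plans") <- setNames(plans, yrs)
  res
}

#' Write or read a panel sample as CSV
#'
#' @param panel A `panel_sample`.
#' @param path File path.
#' @return `write_panel_sample()` returns `path` invisibly;
#'   `read_panel_sample()` the panel.
#' @export
write_panel_sample <- function(panel, path) {
  out <- as_tibble(panel)
  out$retained <- as.integer(out$retained)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_panel_sample
#' @export
read_panel_sample <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  x$retained <- as.logical(x$retained)
  new_panel_sample(x)
}
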