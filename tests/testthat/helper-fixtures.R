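# Fixtures are built in code. `mk_rows()` builds minimal valid
# beneficiary-year rows; the cached worlds below are shared across files.

mk_rows <- function(beneficiary_id, year, county = "A",
                    race_group = "white", age = 70L, sex = "female",
                    ffs_months = 12L, has_diabetes = TRUE,
                    alive_all_year = TRUE, ...) {
  df <- tibble::tibble(beneficiary_id = beneficiary_id, year = as.integer(year),
                       county = county, race_group = race_group,
                       age = as.integer(age), sex = sex,
                       ffs_months = as.integer(ffs_months),
                       has_diabetes = has_diabetes,
                       alive_all_year = alive_all_year)
  flags <- list(...)
  for (cond in condition_names()) {
    df[[cond]] <- if (is.null(flags[[cond]])) FALSE else flags[[cond]]
  }
  df
}

# Two consecutive years exercising every retention / frame rule.
two_year_pop <- function() {
  y2006 <- mk_rows(1:6, 2006, county = c("A", "A", "A", "A", "B", "B"))
  y2007 <- dplyr::bind_rows(
    mk_rows(1, 2007, county = "A"),                       # retained
    mk_rows(2, 2007, county = "B"),                       # moved A -> B
    mk_rows(3, 2007, county = "A", ffs_months = 6),       # lost FFS
    mk_rows(4, 2007, county = "A", alive_all_year = FALSE), # died mid-year
    # id 5 absent: died in 2006 follow-through
    mk_rows(6, 2007, county = "B"),                       # retained
    mk_rows(7, 2007, county = "A"),                       # newly eligible
    mk_rows(8, 2007, county = "B", ffs_months = 0)        # new but HMO
  )
  dplyr::bind_rows(y2006, y2007)
}

# Drop non-structural attributes (simulator metadata, plans) before
# comparing round-tripped tables.
strip_attrs <- function(x) {
  x <- as.data.frame(x)
  for (a in setdiff(names(attributes(x)), c("names", "row.names", "class"))) {
    attr(x, a) <- NULL
  }
  x
}

# Wrap population rows as a minimal panel-sample slice (weight 1).
new_panel_sample_for_test <- function(pop, ids, year = 2006) {
  rows <- pop[pop$year == year & pop$beneficiary_id %in% ids, ]
  tibble::tibble(beneficiary_id = rows$beneficiary_id, year = rows$year,
                 county = rows$county, race_group = rows$race_group,
                 entry_wave = as.integer(year), weight = 1,
                 stratum_pop = nrow(rows), retained = FALSE)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

# Small multi-year synthetic world used by panel / reporting tests.
small_world <- function() {
  cached("small_world", {
    pop <- synthetic_population(n_counties = 6, total_population = 3000,
                                years = 2006:2009, seed = 11)
    panel <- suppressWarnings(
      run_panel(pop, total_target = 1200, county_min = 80,
                race_min = 40, min_fill = 5, seed = 11))
    list(pop = pop, panel = panel)
  })
}

# Fixed single-year population for replicate-draw properties.
replicate_world <- function() {
  cached("replicate_world", {
    cty <- generate_counties(8, 2400, seed = 21)
    pop <- generate_baseline_population(cty, year = 2006, seed = 21)
    plan <- build_allocation_plan(pop, total_target = 900, county_min = 60,
                                  race_min = 30)
    list(pop = pop, plan = plan)
  })
}
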