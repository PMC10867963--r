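# Beneficiary-year tables: schema, validation, eligibility.

#' Names of the 21 tracked chronic conditions
#'
#' Flag columns carried by every beneficiary-year table, one per chronic
#' condition tracked in annual beneficiary summary files (acute myocardial
#' infarction through hypothyroidism). Flags have ever-diagnosed semantics:
#' once set for a beneficiary they stay set in all later years.
#'
#' @return Character vector of 21 column names.
#' @export
#' @examples
#' condition_names()
condition_names <- function() {
  c("ami", "atrial_fibrillation", "ckd", "copd", "chf", "hip_fracture",
    "ihd", "depression", "ra_oa", "stroke", "breast_cancer",
    "prostate_cancer", "colorectal_cancer", "lung_cancer",
    "endometrial_cancer", "anemia", "asthma", "hyperlipidemia", "bph",
    "hypertension", "hypothyroidism")
}

#' Default population prevalences for the 21 chronic conditions
#'
#' Baseline-year prevalences used by the synthetic-population generator,
#' matching the chronic-condition mix of an aged fee-for-service diabetes
#' population (hypertension near 93%, endometrial cancer near 1%).
#'
#' @return Named numeric vector of proportions, one per condition.
#' @export
default_condition_prevalences <- function() {
  setNames(
    c(0.0748, 0.1788, 0.2607, 0.3176, 0.4147, 0.0442, 0.6006, 0.2691,
      0.5216, 0.2103, 0.0483, 0.0564, 0.0367, 0.0184, 0.0080, 0.5588,
      0.1209, 0.7990, 0.1650, 0.9294, 0.2232),
    condition_names()
  )
}

pop_core_columns <- function() {
  c("beneficiary_id", "year", "county", "race_group", "age", "sex",
    "ffs_months", "has_diabetes", "alive_all_year")
}

pop_columns <- function() c(pop_core_columns(), condition_names())

#' Validate a beneficiary-year population table
#'
#' Checks the schema and the invariants every downstream stage relies on:
#' required columns present, `ffs_months` in 0..12, ages at least 65 (only
#' the aged population is modelled), race group dichotomized to
#' white/minority, no duplicate beneficiary-years, and ever-diagnosed
#' monotonicity of the diabetes and condition flags across years.
#'
#' @param population A beneficiary-year data frame (one row per
#'   beneficiary-year; may span several years).
#' @param check_monotone Also check flag monotonicity across years (requires
#'   sorting by beneficiary; skip for very large single-year tables).
#' @return The table, invisibly, as a tibble; aborts on violation.
#' @export
validate_population <- function(population, check_monotone = TRUE) {
  population <- as_tibble(population)
  missing_cols <- setdiff(pop_columns(), names(population))
  if (length(missing_cols) > 0) {
    abort(paste0("population table is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(population$ffs_months < 0 | population$ffs_months > 12)) {
    abort("ffs_months must lie in [0, 12]")
  }
  if (any(population$age < 65)) {
    abort("age must be >= 65: only the aged population is modelled")
  }
  if (!all(population$race_group %in% c("white", "minority"))) {
    abort("race_group must be dichotomized to 'white'/'minority' at load time")
  }
  if (!all(population$sex %in% c("male", "female"))) {
    abort("sex must be 'male'/'female'")
  }
  if (anyDuplicated(population[c("beneficiary_id", "year")]) > 0) {
    abort("duplicate beneficiary-year rows")
  }
  if (check_monotone && length(unique(population$year)) > 1) {
    flags <- c("has_diabetes", condition_names())
    ord <- order(population$beneficiary_id, population$year)
    id <- population$beneficiary_id[ord]
    same <- id[-1] == id[-length(id)]
    for (fl in flags) {
      v <- as.logical(population[[fl]])[ord]
      if (any(same & v[-length(v)] & !v[-1])) {
        abort(paste0("condition flag '", fl,
                     "' reverts across years; flags are ever-diagnosed"))
      }
    }
  }
  invisible(population)
}

#' Eligibility of a beneficiary-year for the study population
#'
#' A beneficiary-year is eligible when the beneficiary has an (ever)
#' diabetes diagnosis, was alive for the whole calendar year, was enrolled
#' in fee-for-service for all 12 months of the year, and resides in a study
#' county. Beneficiaries who die mid-year are ineligible that year,
#' consistent with the 12-month enrollment rule.
#'
#' @param population Beneficiary-year data frame.
#' @param counties Optional character/integer vector of study counties
#'   (closed set). If supplied, a county outside the set signals a
#'   configuration error; if `NULL` every county in the table is in scope.
#' @return Logical vector, one element per row.
#' @export
#' @examples
#' pop <- synthetic_population(n_counties = 3, total_population = 300,
#'                             years = 2006, seed = 1)
#' all(is_eligible(pop))
is_eligible <- function(population, counties = NULL) {
  if (!is.null(counties)) {
    unknown <- setdiff(unique(population$county), counties)
    if (length(unknown) > 0) {
      abort(paste0("unknown county identifier(s): ",
                   paste(utils::head(unknown, 5), collapse = ", ")))
    }
  }
  as.logical(population$has_diabetes) &
    as.logical(population$alive_all_year) &
    population$ffs_months == 12
}

#' Restrict a population table to eligible beneficiary-years
#'
#' @inheritParams is_eligible
#' @param year Optional calendar year to filter to.
#' @return Tibble of eligible rows.
#' @export
eligible_population <- function(population, year = NULL, counties = NULL) {
  population <- as_tibble(population)
  if (!is.null(year)) {
    population <- population[population$year == year, , drop = FALSE]
  }
  population[is_eligible(population, counties = counties), , drop = FALSE]
}

#' Read or write a beneficiary-year table as CSV
#'
#' The on-disk schema is one row per beneficiary-year with boolean columns
#' encoded 0/1; either one file per year or a single file spanning years (a
#' `year` column is always present). `read_population()` accepts several
#' paths and validates the combined table.
#'
#' @param path CSV path(s) to read, or the path to write.
#' @param population Table to write.
#' @return `read_population()` returns a validated tibble;
#'   `write_population()` returns `path` invisibly.
#' @export
read_population <- function(path) {
  tabs <- lapply(path, readr::read_csv, show_col_types = FALSE, progress = FALSE)
  population <- bind_rows(tabs)
  flags <- intersect(c("has_diabetes", "alive_all_year", condition_names()),
                     names(population))
  population[flags] <- lapply(population[flags], function(x) as.logical(as.integer(x)))
  validate_population(population)
  population
}

#' @rdname read_population
#' @export
write_population <- function(population, path) {
  out <- as_tibble(population)
  flags <- intersect(c("has_diabetes", "alive_all_year", condition_names()),
                     names(out))
  out[flags] <- lapply(out[flags], as.integer)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
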