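# ggplot2 views of the validation reports.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_step
#'   labs scale_y_continuous theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot wave retention curves
#'
#' One line per entry wave: percent of the wave's initial size still in the
#' sample at each follow-up year.
#'
#' @param object A `retention_matrix` from [retention_matrix()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.retention_matrix <- function(object, ...) {
  df <- as_tibble(object)
  df$entry_wave <- factor(df$entry_wave)
  ggplot(df, aes(x = .data$follow_up_year, y = .data$pct,
                 colour = .data$entry_wave, group = .data$entry_wave)) +
    geom_line() +
    geom_point(size = 0.8) +
    labs(x = "Follow-up year", y = "% of wave retained",
         colour = "Entry wave") +
    theme_minimal()
}

#' Plot the weighted sample age distribution against the population
#'
#' Step overlays of the two (count-scaled) age histograms from
#' [age_distribution_overlay()]; if the fill-in weighting is sound the two
#' outlines coincide even in late follow-up years.
#'
#' @param object An `age_overlay`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.age_overlay <- function(object, ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(c("population_n", "sample_weighted_n"),
                        names_to = "source", values_to = "n") |>
    mutate(source = ifelse(.data$source == "population_n",
                           "population", "weighted sample"))
  ggplot(df, aes(x = .data$age_lo, y = .data$n, colour = .data$source)) +
    geom_step(linewidth = 0.6) +
    labs(x = "Age (years)", y = "Beneficiaries",
         colour = NULL,
         title = sprintf("Age distribution, %s", attr(object, "year"))) +
    theme_minimal()
}
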