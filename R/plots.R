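#' @importFrom ggplot2 ggplot aes geom_col geom_histogram geom_vline labs
#'   facet_wrap position_dodge2 autoplot
NULL

#' @export
ggplot2::autoplot

#' Plot the procedure step distribution
#'
#' Bar chart of the share of items per decision step, added and free sugars
#' side by side; steps 1-6 are the objective part of the procedure.
#'
#' @param object A `step_distribution` (or anything [step_distribution()]
#'   accepts).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.step_distribution <- function(object, ...) {
  if (!inherits(object, "step_distribution")) {
    object <- step_distribution(object)
  }
  ggplot(object, aes(x = factor(.data$step), y = .data$pct,
                     fill = .data$sugar_type)) +
    geom_col(position = position_dodge2(preserve = "single")) +
    labs(x = "procedure step", y = "% of food items", fill = "sugar type")
}

#' @export
autoplot.sugar_estimates <- function(object, ...) {
  autoplot(step_distribution(object), ...)
}

#' Histogram of habitual energy-percent intakes
#'
#' Distribution of E% from a sugars type across participants, with the 10%
#' (and optionally 5%) guideline thresholds marked.
#'
#' @param usual Habitual-intake tibble (`participant_id`, nutrient columns
#'   incl. `energy_kJ`), e.g. from [usual_intakes()].
#' @param value Sugars column to show; default `"added_g"`.
#' @param energy_factor kJ per g of sugars; default 17.
#' @param thresholds Vertical guideline lines; default `c(10, 5)`.
#' @return A ggplot.
#' @export
plot_energy_share <- function(usual, value = "added_g", energy_factor = 17,
                              thresholds = c(10, 5)) {
  dat <- tibble(E = energy_percent(usual[[value]], usual$energy_kJ,
                                   energy_factor))
  ggplot(dat, aes(x = .data$E)) +
    geom_histogram(bins = 40) +
    geom_vline(xintercept = thresholds, linetype = "dashed") +
    labs(x = paste0(value, " as % of energy"), y = "participants")
}
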