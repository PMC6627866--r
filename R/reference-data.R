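#' Published step-count distribution of a national food list
#'
#' The step-number distribution reported for the 1483-item Swedish food list
#' (844 single plus 639 composite items) to which the ten-step procedure was
#' applied: counts of items per step, separately for added and free sugars.
#' Useful as a desk check of [step_distribution()] and [objective_fraction()].
#'
#' @return Tibble `step, added_n, free_n` (steps 1-10).
#' @export
reference_step_counts <- function() {
  readr::read_csv(
    system.file("extdata", "step_counts_reference.csv",
                package = "sugarsteps", mustWork = TRUE),
    col_types = readr::cols(step = "i", added_n = "i", free_n = "i"),
    progress = FALSE)
}

#' Published sugar-containing item counts of the same food list
#'
#' @return Tibble `n_items, n_with_added, n_with_free`
#'   (1483 items of which 521 contained added and 585 free sugars).
#' @export
reference_item_counts <- function() {
  readr::read_csv(
    system.file("extdata", "item_counts_reference.csv",
                package = "sugarsteps", mustWork = TRUE),
    col_types = readr::cols(n_items = "i", n_with_added = "i",
                            n_with_free = "i"),
    progress = FALSE)
}
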