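#' Per-participant-day sugars and energy intake
#'
#' Joins recall records (grams consumed per food) to the item-level sugar
#' estimates and resolved nutrient profiles: each daily nutrient is
#' `sum(amount_g * per-100 g value / 100)` over the day's foods.
#'
#' @param records Tibble `participant_id, day_index, day_class, food_id,
#'   amount_g` (see [read_records()]).
#' @param estimates A `sugar_estimates` table covering every consumed food.
#' @param db The `food_db` (supplies total sugars and energy via
#'   [resolve_profiles()]).
#' @return Tibble `participant_id, day_index, day_class, added_g, free_g,
#'   total_g, energy_kJ` with one row per reported day.
#' @export
daily_intake <- function(records, estimates, db) {
  records <- as_tibble(records)
  unknown <- setdiff(records$food_id, estimates$item_id)
  if (length(unknown) > 0) {
    abort(paste0("records reference food ids missing from estimates: ",
                 paste(unique(unknown), collapse = ", ")))
  }
  prof <- resolve_profiles(db)
  unknown_db <- setdiff(records$food_id, prof$item_id)
  if (length(unknown_db) > 0) {
    abort(paste0("records reference food ids missing from the database: ",
                 paste(unique(unknown_db), collapse = ", ")))
  }
  per100 <- left_join(
    select(estimates, "item_id", "added_g", "free_g"),
    select(prof, "item_id", "total_sugars_g", "energy_kJ"),
    by = "item_id")
  joined <- left_join(records, per100, by = c(food_id = "item_id"))
  out <- group_by(joined, .data$participant_id, .data$day_index, .data$day_class)
  out <- summarise(out,
    added_g = sum(.data$amount_g * .data$added_g / 100),
    free_g = sum(.data$amount_g * .data$free_g / 100),
    total_g = sum(.data$amount_g * .data$total_sugars_g / 100),
    energy_kJ = sum(.data$amount_g * .data$energy_kJ / 100),
    .groups = "drop")
  arrange(out, .data$participant_id, .data$day_index)
}

#' Percent of energy from sugars
#'
#' @param sugars_g Sugars intake, g/day.
#' @param energy_kJ Total energy intake, kJ/day.
#' @param factor Metabolisable energy of sugars, kJ/g; default 17 (the EU/NNR
#'   carbohydrate convention).
#' @return E% values; `NA` (with a warning) where energy is not positive.
#' @export
energy_percent <- function(sugars_g, energy_kJ, factor = 17) {
  out <- sugars_g * factor / energy_kJ * 100
  bad <- !is.na(energy_kJ) & energy_kJ <= 0
  if (any(bad)) {
    warn(sprintf("%d value(s) with non-positive energy: E%% undefined, set to NA",
                 sum(bad)))
    out[bad] <- NA_real_
  }
  out
}

#' Mann-Whitney U test between two groups
#'
#' Two-sided test of a location difference. With both groups of size at most
#' 20 and no ties the exact null distribution of U is used; otherwise the
#' normal approximation with tie correction (and continuity correction).
#'
#' @param x,y Numeric vectors.
#' @return Tibble `u, p_value, method`.
#' @export
mann_whitney <- function(x, y) {
  has_ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- length(x) <= 20 && length(y) <= 20 && !has_ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = !use_exact))
  tibble(u = unname(wt$statistic), p_value = wt$p.value,
         method = if (use_exact) "exact" else "normal approximation")
}

q25 <- function(x) unname(stats::quantile(x, 0.25, type = 7))
q75 <- function(x) unname(stats::quantile(x, 0.75, type = 7))

stratum_row <- function(dat, school_year, sex, thresholds) {
  measures <- c("added_g", "free_g", "total_g", "added_E", "free_E", "total_E")
  row <- tibble(school_year = school_year, sex = sex, n = nrow(dat))
  for (m in measures) {
    v <- dat[[m]]
    row[[paste0(m, "_median")]] <- stats::median(v)
    row[[paste0(m, "_p25")]] <- q25(v)
    row[[paste0(m, "_p75")]] <- q75(v)
    row[[paste0(m, "_label")]] <-
      sprintf("%.1f (%.1f; %.1f)", stats::median(v), q25(v), q75(v))
  }
  row$pct_added_E_below_10 <- round(mean(dat$added_E < thresholds[[1]]) * 100)
  row$pct_free_E_below_10 <- round(mean(dat$free_E < thresholds[[1]]) * 100)
  row$pct_free_E_below_5 <- round(mean(dat$free_E < thresholds[[2]]) * 100)
  row
}

#' Stratified summary of habitual intakes
#'
#' Builds the survey-style summary table: median (p25; p75) of g/day and E%
#' for added, free and total sugars by school year and sex, plus rows pooling
#' sexes per school year and an overall row; guideline adherence as the
#' rounded percent of participants strictly below the 10% (added and free)
#' and 5% (free) energy thresholds; and a two-sided Mann-Whitney p-value for
#' the girl/boy comparison within each school-year stratum. Quantiles use
#' linear interpolation between order statistics (R type 7).
#'
#' @param usual Tibble `participant_id, added_g, free_g, total_g, energy_kJ`
#'   of habitual intakes (one row per participant), e.g. from
#'   [usual_intakes()].
#' @param participants Roster tibble `participant_id, sex, school_year`.
#' @param energy_factor kJ per g of sugars for E%; default 17.
#' @param thresholds E% guideline thresholds, `c(10, 5)`.
#' @return Tibble with one row per stratum (each school year: all/girl/boy;
#'   plus overall), medians/quantiles both machine-readable and as
#'   `"median (p25; p75)"` labels, adherence percentages, and
#'   `p_added_E, p_free_E, p_total_E` on the pooled rows.
#' @export
summarize_intakes <- function(usual, participants, energy_factor = 17,
                              thresholds = c(10, 5)) {
  missing_p <- setdiff(usual$participant_id, participants$participant_id)
  if (length(missing_p) > 0) {
    abort(paste0("participants missing from roster: ",
                 paste(missing_p, collapse = ", ")))
  }
  dat <- left_join(usual, participants, by = "participant_id")
  dat <- mutate(dat,
    added_E = energy_percent(.data$added_g, .data$energy_kJ, energy_factor),
    free_E = energy_percent(.data$free_g, .data$energy_kJ, energy_factor),
    total_E = energy_percent(.data$total_g, .data$energy_kJ, energy_factor))

  rows <- list()
  for (yr in c("5", "8", "11")) {
    ydat <- filter(dat, .data$school_year == yr)
    if (nrow(ydat) == 0) {
      warn(paste0("school year ", yr, " has no participants; row omitted"))
      next
    }
    all_row <- stratum_row(ydat, yr, "All", thresholds)
    g <- filter(ydat, .data$sex == "girl")
    b <- filter(ydat, .data$sex == "boy")
    if (nrow(g) > 0 && nrow(b) > 0) {
      all_row$p_added_E <- mann_whitney(g$added_E, b$added_E)$p_value
      all_row$p_free_E <- mann_whitney(g$free_E, b$free_E)$p_value
      all_row$p_total_E <- mann_whitney(g$total_E, b$total_E)$p_value
    }
    rows[[length(rows) + 1]] <- all_row
    for (sx in c("girl", "boy")) {
      sdat <- filter(ydat, .data$sex == sx)
      if (nrow(sdat) == 0) {
        warn(paste0("stratum year ", yr, " / ", sx, " is empty; row omitted"))
        next
      }
      rows[[length(rows) + 1]] <- stratum_row(sdat, yr, sx, thresholds)
    }
  }
  overall <- stratum_row(dat, "All", "All", thresholds)
  g <- filter(dat, .data$sex == "girl")
  b <- filter(dat, .data$sex == "boy")
  if (nrow(g) > 0 && nrow(b) > 0) {
    overall$p_added_E <- mann_whitney(g$added_E, b$added_E)$p_value
    overall$p_free_E <- mann_whitney(g$free_E, b$free_E)$p_value
    overall$p_total_E <- mann_whitney(g$total_E, b$total_E)$p_value
  }
  rows[[length(rows) + 1]] <- overall
  out <- bind_rows(rows)
  attr(out, "quantile_convention") <- "linear interpolation (R type 7)"
  attr(out, "energy_factor_kJ_per_g") <- energy_factor
  out
}
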