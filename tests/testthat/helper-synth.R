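# Shared fixtures, built in code.

# A hand-built toy database: sucrose, water, and a 50/50 syrup-water mix.
toy_db <- function() {
  foods <- tibble::tibble(
    item_id = c("sugar", "water", "syrupmix"),
    name = c("white sugar", "tap water", "sugar-water mix"),
    kind = c("single", "single", "composite"),
    category = c("confectionery", "other_single", "other_single"),
    monosaccharides_g = c(0, 0, NA),
    disaccharides_g = c(100, 0, NA),
    total_sugars_g = c(100, 0, NA),
    fructose_g = NA_real_,
    energy_kJ = c(1700, 0, NA),
    sugars_all_added = c(TRUE, FALSE, FALSE),
    sugars_all_free = FALSE,
    contains_fruit_or_veg = FALSE,
    unsweetened_counterpart_id = NA_character_,
    provenance = "toy")
  recipes <- tibble::tibble(
    composite_id = "syrupmix", ingredient_id = c("sugar", "water"),
    raw_weight_g = c(50, 50))
  food_db(foods, recipes)
}

# One single item row with sensible defaults, overridable per field.
single_item <- function(item_id, category = "other_single", total = 10,
                        mono = NULL, fructose = NA_real_, energy = 500,
                        all_added = FALSE, all_free = FALSE,
                        fruitveg = FALSE, counterpart = NA_character_) {
  if (is.null(mono)) mono <- total / 2
  tibble::tibble(
    item_id = item_id, name = item_id, kind = "single", category = category,
    monosaccharides_g = mono, disaccharides_g = total - mono,
    total_sugars_g = total, fructose_g = fructose, energy_kJ = energy,
    sugars_all_added = all_added, sugars_all_free = all_free,
    contains_fruit_or_veg = fruitveg, unsweetened_counterpart_id = counterpart,
    provenance = "test")
}

# A two-stage nested db: remoulade-style sauce built on a mayonnaise-style
# base of single leaf ingredients.
nested_db <- function() {
  foods <- dplyr::bind_rows(
    single_item("oil", "fat_oil", total = 0, energy = 3700),
    single_item("vinegar", "other_single", total = 1, energy = 90),
    single_item("eggyolk", "meat_fish_plain", total = 0, energy = 1300),
    single_item("pickles", "pickled_sweetened", total = 8, energy = 150),
    single_item("parsley", "vegetable_raw", total = 1, energy = 150),
    tibble::tibble(
      item_id = c("mayonnaise", "remoulade"), name = c("mayo", "remoulade"),
      kind = "composite", category = "other_single",
      monosaccharides_g = NA_real_, disaccharides_g = NA_real_,
      total_sugars_g = NA_real_, fructose_g = NA_real_, energy_kJ = NA_real_,
      sugars_all_added = FALSE, sugars_all_free = FALSE,
      contains_fruit_or_veg = FALSE,
      unsweetened_counterpart_id = NA_character_, provenance = "test"))
  recipes <- tibble::tibble(
    composite_id = c(rep("mayonnaise", 3), rep("remoulade", 3)),
    ingredient_id = c("oil", "vinegar", "eggyolk",
                      "mayonnaise", "pickles", "parsley"),
    raw_weight_g = c(150, 20, 30, 160, 30, 10))
  food_db(foods, recipes)
}

# Small synthetic-study config for fast tests.
small_config <- function(seed = 1L, n_single = 40, n_composite = 20, ...) {
  synth_config(
    n_single = n_single, n_composite = n_composite,
    participants = tibble::tibble(
      school_year = rep(c("5", "8", "11"), each = 2),
      sex = rep(c("girl", "boy"), 3),
      n = rep(30L, 6)),
    seed = seed, ...)
}

# Independent brute-force two-sided Mann-Whitney p over all group labellings.
brute_force_mw_p <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x)
  u_of <- function(idx) {
    a <- pooled[idx]
    b <- pooled[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_of(seq_len(m))
  all_idx <- utils::combn(length(pooled), m)
  us <- apply(all_idx, 2, u_of)
  mu <- m * (length(y)) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}
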