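#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr mutate filter select arrange left_join group_by summarise
#'   ungroup across bind_rows distinct pull n rename row_number if_else
#' @importFrom tibble tibble as_tibble
NULL

# Tolerance for the total-sugars = mono + di consistency check (g/100 g).
SUGARS_TOL <- 1e-6

#' Food categories recognised by the estimation procedure
#'
#' The category drives the objective steps of the decision procedure: plain
#' (intrinsic-sugars-only) groups, the free-sugars sources (fruit juice, honey,
#' syrup), vegetable juice, plain bread (batch-weight discount rule), and the
#' all-added groups (soft drinks, confectionery, sweetened pickled products).
#'
#' @return Character vector of allowed `category` values.
#' @export
food_categories <- function() {
  c("beverage_soft", "juice_fruit", "juice_vegetable", "honey", "syrup",
    "fruit_raw", "vegetable_raw", "dairy_plain", "dairy_sweetened",
    "bread_plain", "baked_sweet", "cereal_breakfast", "confectionery",
    "pickled_sweetened", "pseudocereal", "meat_fish_plain", "fat_oil",
    "other_single")
}

# Categories whose sugars are entirely intrinsic: added = free = 0.
INTRINSIC_CATEGORIES <- c("fruit_raw", "vegetable_raw", "dairy_plain",
                          "meat_fish_plain", "fat_oil", "pseudocereal")

# Free-sugars sources: natural sugars count as free but not as added.
FREE_SOURCE_CATEGORIES <- c("juice_fruit", "honey", "syrup")

# Categories treated as all-added-sugars even without an explicit flag.
# (Sweet baked goods are NOT listed: fruit-containing ones must stay eligible
# for the fructose-subtraction step; plain ones carry the explicit flag.)
ALL_ADDED_CATEGORIES <- c("confectionery", "beverage_soft")

FOODS_COLUMNS <- c("item_id", "name", "kind", "category",
                   "monosaccharides_g", "disaccharides_g", "total_sugars_g",
                   "fructose_g", "energy_kJ",
                   "sugars_all_added", "sugars_all_free",
                   "contains_fruit_or_veg", "unsweetened_counterpart_id",
                   "provenance")

RECIPES_COLUMNS <- c("composite_id", "ingredient_id", "raw_weight_g")
RECIPE_META_COLUMNS <- c("composite_id", "batch_post_weight_g")

#' Construct a validated food database
#'
#' A food database bundles the item table (single and composite foods, with
#' per-100 g edible-portion nutrient values for the singles), the recipe table
#' (composite -> ingredient raw weights per batch) and optional per-recipe
#' post-cooking batch weights. All structural invariants are checked on
#' construction; composite foods carry no nutrient values of their own (they
#' are derived by [resolve_profiles()]).
#'
#' @param foods Data frame with columns
#'   `item_id,name,kind,category,monosaccharides_g,disaccharides_g,
#'   total_sugars_g,fructose_g,energy_kJ,sugars_all_added,sugars_all_free,
#'   contains_fruit_or_veg,unsweetened_counterpart_id,provenance`.
#' @param recipes Data frame with columns `composite_id,ingredient_id,raw_weight_g`.
#' @param recipe_meta Optional data frame `composite_id,batch_post_weight_g`;
#'   composites without a row default to post-weight = sum of raw weights.
#' @return An object of class `food_db`: a list with tibbles `foods`,
#'   `recipes`, `recipe_meta`.
#' @export
food_db <- function(foods, recipes = NULL, recipe_meta = NULL) {
  foods <- as_tibble(foods)
  recipes <- if (is.null(recipes)) {
    tibble(composite_id = character(), ingredient_id = character(),
           raw_weight_g = double())
  } else {
    as_tibble(recipes)
  }
  recipe_meta <- if (is.null(recipe_meta)) {
    tibble(composite_id = character(), batch_post_weight_g = double())
  } else {
    as_tibble(recipe_meta)
  }

  missing_cols <- setdiff(FOODS_COLUMNS, names(foods))
  if (length(missing_cols) > 0) {
    abort(paste0("foods table is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  foods <- foods[FOODS_COLUMNS]
  foods <- mutate(foods,
    across(c("item_id", "name", "kind", "category",
             "unsweetened_counterpart_id", "provenance"), as.character),
    across(c("monosaccharides_g", "disaccharides_g", "total_sugars_g",
             "fructose_g", "energy_kJ"), as.double),
    across(c("sugars_all_added", "sugars_all_free", "contains_fruit_or_veg"),
           as.logical))
  recipes <- recipes[RECIPES_COLUMNS]
  recipes <- mutate(recipes,
    across(c("composite_id", "ingredient_id"), as.character),
    raw_weight_g = as.double(.data$raw_weight_g))
  recipe_meta <- recipe_meta[RECIPE_META_COLUMNS]
  recipe_meta <- mutate(recipe_meta,
    composite_id = as.character(.data$composite_id),
    batch_post_weight_g = as.double(.data$batch_post_weight_g))

  db <- structure(list(foods = foods, recipes = recipes,
                       recipe_meta = recipe_meta),
                  class = "food_db")
  validate_food_db(db)
  db
}

#' Validate a food database
#'
#' Checks the invariants of the food and recipe tables: unique ids, known
#' categories, nutrient consistency (`total = mono + di` within 1e-6 g,
#' `0 <= fructose <= mono <= total <= 100`, energy >= 0) for single items,
#' referential integrity of recipe links and counterpart ids, positive raw and
#' post-batch weights, and category/flag consistency (natural free-sugars
#' sources are never flagged all-added).
#'
#' @param db A `food_db`.
#' @return `db`, invisibly, if valid; otherwise an error listing every
#'   violated item and field.
#' @export
validate_food_db <- function(db) {
  foods <- db$foods
  recipes <- db$recipes
  meta <- db$recipe_meta
  problems <- character()
  prob <- function(...) problems[[length(problems) + 1L]] <<- paste0(...)

  if (anyDuplicated(foods$item_id)) {
    prob("duplicate item_id: ",
         paste(unique(foods$item_id[duplicated(foods$item_id)]), collapse = ", "))
  }
  bad_kind <- foods$item_id[!foods$kind %in% c("single", "composite")]
  if (length(bad_kind) > 0) prob("unknown kind for: ", paste(bad_kind, collapse = ", "))
  bad_cat <- foods$item_id[!foods$category %in% food_categories()]
  if (length(bad_cat) > 0) prob("unknown category for: ", paste(bad_cat, collapse = ", "))

  singles <- filter(foods, .data$kind == "single")
  for (i in seq_len(nrow(singles))) {
    s <- singles[i, ]
    id <- s$item_id
    if (anyNA(c(s$monosaccharides_g, s$disaccharides_g, s$total_sugars_g,
                s$energy_kJ))) {
      prob(id, ": single item must have monosaccharides, disaccharides, ",
           "total sugars and energy")
      next
    }
    if (abs(s$monosaccharides_g + s$disaccharides_g - s$total_sugars_g) > SUGARS_TOL) {
      prob(id, ": total_sugars_g (", s$total_sugars_g,
           ") != monosaccharides_g + disaccharides_g (",
           s$monosaccharides_g + s$disaccharides_g, ")")
    }
    if (s$monosaccharides_g < 0 || s$disaccharides_g < 0 ||
        s$total_sugars_g > 100 + SUGARS_TOL) {
      prob(id, ": sugar values must lie in [0, 100] g/100 g")
    }
    if (!is.na(s$fructose_g) &&
        (s$fructose_g < -SUGARS_TOL || s$fructose_g > s$monosaccharides_g + SUGARS_TOL)) {
      prob(id, ": fructose_g must satisfy 0 <= fructose <= monosaccharides")
    }
    if (s$energy_kJ < 0) prob(id, ": energy_kJ must be >= 0")
  }

  comps <- filter(foods, .data$kind == "composite")
  no_recipe <- setdiff(comps$item_id, recipes$composite_id)
  if (length(no_recipe) > 0) {
    prob("composite items without recipe components: ",
         paste(no_recipe, collapse = ", "))
  }
  orphan_comp <- setdiff(recipes$composite_id, comps$item_id)
  if (length(orphan_comp) > 0) {
    prob("recipe rows for non-composite or unknown composite_id: ",
         paste(unique(orphan_comp), collapse = ", "))
  }
  missing_ing <- setdiff(recipes$ingredient_id, foods$item_id)
  if (length(missing_ing) > 0) {
    prob("recipe ingredient id not in food table: ",
         paste(unique(missing_ing), collapse = ", "))
  }
  if (any(recipes$raw_weight_g <= 0)) {
    bad <- recipes$composite_id[recipes$raw_weight_g <= 0]
    prob("non-positive raw_weight_g in recipes of: ",
         paste(unique(bad), collapse = ", "))
  }
  self_ref <- recipes$composite_id[recipes$composite_id == recipes$ingredient_id]
  if (length(self_ref) > 0) {
    prob("recipe contains itself as ingredient: ",
         paste(unique(self_ref), collapse = ", "))
  }
  if (any(meta$batch_post_weight_g <= 0)) {
    bad <- meta$composite_id[meta$batch_post_weight_g <= 0]
    prob("non-positive batch_post_weight_g for: ", paste(bad, collapse = ", "))
  }
  orphan_meta <- setdiff(meta$composite_id, comps$item_id)
  if (length(orphan_meta) > 0) {
    prob("recipe_meta rows for unknown composite: ",
         paste(orphan_meta, collapse = ", "))
  }

  bad_flag <- foods$item_id[foods$category %in%
                              c("honey", "juice_fruit", "juice_vegetable") &
                            foods$sugars_all_added %in% TRUE]
  if (length(bad_flag) > 0) {
    prob("natural free-sugars sources cannot be flagged sugars_all_added: ",
         paste(bad_flag, collapse = ", "))
  }
  cp <- foods$unsweetened_counterpart_id
  missing_cp <- setdiff(cp[!is.na(cp)], foods$item_id)
  if (length(missing_cp) > 0) {
    prob("unsweetened_counterpart_id not in food table: ",
         paste(missing_cp, collapse = ", "))
  }

  if (length(problems) > 0) {
    abort(paste0("invalid food database:\n- ",
                 paste(problems, collapse = "\n- ")))
  }
  invisible(db)
}

#' @export
print.food_db <- function(x, ...) {
  n_single <- sum(x$foods$kind == "single")
  n_comp <- sum(x$foods$kind == "composite")
  cat("<food_db> ", nrow(x$foods), " items (", n_single, " single, ",
      n_comp, " composite), ", nrow(x$recipes), " recipe components\n",
      sep = "")
  invisible(x)
}

fmt_num <- function(x) if_else(is.na(x), "", sprintf("%.6f", x))
fmt_lgl <- function(x) if_else(is.na(x), "", if_else(x, "true", "false"))
fmt_chr <- function(x) if_else(is.na(x), "", x)

#' Write a food database to CSV files
#'
#' Output is byte-stable for identical input: fixed column order, rows ordered
#' as in the database, numerics in 6-decimal fixed point, logicals as
#' `true`/`false`, missing values as empty fields.
#'
#' @param db A validated `food_db`.
#' @param food_path,recipe_path,recipe_meta_path Output file paths; the
#'   recipe-meta file is only written when a path is given.
#' @return Invisibly, the paths written.
#' @export
write_food_db <- function(db, food_path, recipe_path, recipe_meta_path = NULL) {
  foods_out <- mutate(db$foods,
    across(c("monosaccharides_g", "disaccharides_g", "total_sugars_g",
             "fructose_g", "energy_kJ"), fmt_num),
    across(c("sugars_all_added", "sugars_all_free", "contains_fruit_or_veg"),
           fmt_lgl),
    across(c("name", "unsweetened_counterpart_id", "provenance"), fmt_chr))
  readr::write_csv(foods_out, food_path, na = "")
  recipes_out <- mutate(db$recipes, raw_weight_g = fmt_num(.data$raw_weight_g))
  readr::write_csv(recipes_out, recipe_path, na = "")
  if (!is.null(recipe_meta_path)) {
    meta_out <- mutate(db$recipe_meta,
                       batch_post_weight_g = fmt_num(.data$batch_post_weight_g))
    readr::write_csv(meta_out, recipe_meta_path, na = "")
  }
  invisible(c(food_path, recipe_path, recipe_meta_path))
}

#' Load a food database from CSV files
#'
#' Reads the item and recipe tables written by [write_food_db()] (or prepared
#' by hand in the same schema), then validates every invariant, including
#' referential integrity of recipe links.
#'
#' @inheritParams write_food_db
#' @return A validated `food_db`.
#' @export
load_food_db <- function(food_path, recipe_path, recipe_meta_path = NULL) {
  foods <- readr::read_csv(
    food_path,
    col_types = readr::cols(
      item_id = "c", name = "c", kind = "c", category = "c",
      monosaccharides_g = "d", disaccharides_g = "d", total_sugars_g = "d",
      fructose_g = "d", energy_kJ = "d",
      sugars_all_added = "l", sugars_all_free = "l",
      contains_fruit_or_veg = "l",
      unsweetened_counterpart_id = "c", provenance = "c"),
    na = c("", "NA"), progress = FALSE)
  recipes <- readr::read_csv(
    recipe_path,
    col_types = readr::cols(composite_id = "c", ingredient_id = "c",
                            raw_weight_g = "d"),
    na = c("", "NA"), progress = FALSE)
  meta <- NULL
  if (!is.null(recipe_meta_path) && file.exists(recipe_meta_path)) {
    meta <- readr::read_csv(
      recipe_meta_path,
      col_types = readr::cols(composite_id = "c", batch_post_weight_g = "d"),
      na = c("", "NA"), progress = FALSE)
  }
  food_db(foods, recipes, meta)
}

#' Read a participant roster
#'
#' @param path CSV with columns `participant_id,sex,school_year`
#'   (sex `girl`/`boy`, school_year 5/8/11).
#' @return Tibble with one row per participant.
#' @export
read_participants <- function(path) {
  p <- readr::read_csv(path,
    col_types = readr::cols(participant_id = "c", sex = "c", school_year = "c"),
    progress = FALSE)
  if (anyDuplicated(p$participant_id)) {
    abort("duplicate participant_id in roster")
  }
  if (!all(p$sex %in% c("girl", "boy"))) abort("sex must be 'girl' or 'boy'")
  if (!all(p$school_year %in% c("5", "8", "11"))) {
    abort("school_year must be 5, 8 or 11")
  }
  p
}

#' Read two-day dietary records
#'
#' @param path CSV with columns
#'   `participant_id,day_index,day_class,food_id,amount_g`; `day_index` is 1
#'   or 2 and `day_class` is `weekday` (Mon-Thu) or `weekend` (Fri-Sun).
#' @return Tibble of consumption rows.
#' @export
read_records <- function(path) {
  r <- readr::read_csv(path,
    col_types = readr::cols(participant_id = "c", day_index = "i",
                            day_class = "c", food_id = "c", amount_g = "d"),
    progress = FALSE)
  if (!all(r$day_index %in% c(1L, 2L))) abort("day_index must be 1 or 2")
  if (!all(r$day_class %in% c("weekday", "weekend"))) {
    abort("day_class must be 'weekday' or 'weekend'")
  }
  if (any(r$amount_g < 0)) abort("amount_g must be >= 0")
  r
}
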