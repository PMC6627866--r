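#' Configuration of the ten-step sugars estimation procedure
#'
#' Collects the tunable rules of the decision procedure. Defaults follow the
#' strict Nordic definition of added sugars (refined sugars only: honey and
#' unsweetened fruit-juice sugars are not added) and the WHO definition of
#' free sugars (added sugars plus natural sugars of honey, syrup and fruit
#' juice), with vegetable-juice sugars excluded from free sugars.
#'
#' @param bread_discount_threshold Grams of sugars per 1000 g pre-baking
#'   weight below which (strictly) sugars in plain bread are discounted as
#'   fermentation amounts; default 9.
#' @param honey_in_added Count honey's natural sugars as added (some national
#'   labelling definitions do); default `FALSE`.
#' @param fruit_puree_in_free Count fruit-puree sugars as free; default
#'   `FALSE` (purees retain the fruit matrix).
#' @param vegetable_juice_in_free Count vegetable-juice sugars as free;
#'   default `FALSE`.
#' @param step10_fraction Border-case fallback: fraction of total sugars
#'   assigned at the final subjective step; default 0.5.
#' @param overrides Tibble `item_id, added_g, free_g`: manufacturer/recipe
#'   information per 100 g, used by the first subjective step.
#' @param proportional_references Tibble `item_id, reference_id, ratio`:
#'   proportional scaling from a comparable reference item (estimate =
#'   `ratio` times the reference's estimate).
#' @param bread_batches Tibble `item_id, pre_baking_weight_g,
#'   sugars_in_batch_g`: dough batch data enabling the bread discount rule for
#'   single plain-bread items.
#' @return A `procedure_config` list.
#' @export
procedure_config <- function(bread_discount_threshold = 9,
                             honey_in_added = FALSE,
                             fruit_puree_in_free = FALSE,
                             vegetable_juice_in_free = FALSE,
                             step10_fraction = 0.5,
                             overrides = NULL,
                             proportional_references = NULL,
                             bread_batches = NULL) {
  if (!is.numeric(bread_discount_threshold) || bread_discount_threshold <= 0) {
    abort("bread_discount_threshold must be > 0")
  }
  if (!is.null(overrides)) {
    overrides <- as_tibble(overrides)
    stopifnot(all(c("item_id", "added_g", "free_g") %in% names(overrides)))
    if (any(overrides$added_g > overrides$free_g + SUGARS_TOL)) {
      abort("override with added_g > free_g violates the free-superset invariant")
    }
  }
  if (!is.null(proportional_references)) {
    proportional_references <- as_tibble(proportional_references)
    stopifnot(all(c("item_id", "reference_id", "ratio") %in%
                    names(proportional_references)))
  }
  if (!is.null(bread_batches)) {
    bread_batches <- as_tibble(bread_batches)
    stopifnot(all(c("item_id", "pre_baking_weight_g", "sugars_in_batch_g") %in%
                    names(bread_batches)))
  }
  structure(
    list(bread_discount_threshold = bread_discount_threshold,
         honey_in_added = honey_in_added,
         fruit_puree_in_free = fruit_puree_in_free,
         vegetable_juice_in_free = vegetable_juice_in_free,
         step10_fraction = step10_fraction,
         overrides = overrides,
         proportional_references = proportional_references,
         bread_batches = bread_batches),
    class = "procedure_config")
}

#' Bread discount rule
#'
#' Plain breads are routinely made with a small amount of sugars that mostly
#' feeds the yeast; such minimal amounts are discounted from added sugars.
#' The rule compares the dough batch's sugars per 1000 g pre-baking weight
#' against a strict threshold.
#'
#' @param item A one-row foods table entry (or a category string); must be
#'   `bread_plain`.
#' @param pre_baking_weight_g Total raw dough weight of the batch, grams.
#' @param sugars_in_batch_g Sugars in the batch, grams.
#' @param config A [procedure_config()].
#' @return `TRUE` if added sugars are discounted (set to zero), i.e. sugars
#'   per 1000 g pre-baking weight are strictly below the threshold.
#' @export
bread_rule <- function(item, pre_baking_weight_g, sugars_in_batch_g,
                       config = procedure_config()) {
  category <- if (is.character(item)) item else item$category
  if (!identical(category, "bread_plain")) {
    abort("bread_rule applies only to items of category 'bread_plain'")
  }
  if (pre_baking_weight_g <= 0) abort("pre_baking_weight_g must be > 0")
  rate <- sugars_in_batch_g / pre_baking_weight_g * 1000
  rate < config$bread_discount_threshold
}

#' Fructose subtraction for fruit/vegetable-containing foods
#'
#' For foods containing fruits and/or vegetables with an analytical fructose
#' value, the non-added sugars candidate is obtained by subtracting fructose
#' from total sugars. Only fructose is subtracted; other intrinsic sugars are
#' not accounted for, so the result may slightly overestimate added/free
#' sugars. Negative differences are clamped to zero with a warning.
#'
#' @param profile A one-row nutrient profile (list or tibble) with
#'   `total_sugars_g` and `fructose_g`.
#' @return Added-sugars candidate, g/100 g.
#' @export
fructose_subtraction <- function(profile) {
  total <- profile$total_sugars_g
  fruct <- profile$fructose_g
  if (is.null(fruct) || is.na(fruct)) {
    abort("fructose subtraction requires an analytical fructose value; item is ineligible for this step")
  }
  res <- total - fruct
  if (res < 0) {
    warn(sprintf("fructose (%.3f) exceeds total sugars (%.3f); clamping to 0",
                 fruct, total))
    res <- 0
  }
  res
}

#' Step assignment rule for composite foods
#'
#' A composite made only of components at steps 1-4 is itself an objective
#' estimate (step 4); a composite containing at least one component at steps
#' 5-10 is a subjective estimate (step 9).
#'
#' @param component_steps Integer vector of the direct components' steps.
#' @return 4L or 9L.
#' @export
composite_step <- function(component_steps) {
  if (length(component_steps) == 0) {
    abort("composite_step needs at least one component step")
  }
  if (max(component_steps) <= 4) 4L else 9L
}

#' Recipe-weighted added/free sugars of a composite
#'
#' @param db A validated `food_db`.
#' @param composite_id Composite item id.
#' @param estimates Estimates table (as from [assign_and_estimate()]) covering
#'   all ingredients.
#' @return Named numeric: `added_g`, `free_g` per 100 g finished food.
#' @export
composite_content <- function(db, composite_id, estimates) {
  rc <- db$recipes[db$recipes$composite_id == composite_id, ]
  if (nrow(rc) == 0) abort(paste0(composite_id, " has no recipe components"))
  idx <- match(rc$ingredient_id, estimates$item_id)
  if (anyNA(idx)) {
    abort(paste0("unresolved ingredient(s) for ", composite_id, ": ",
                 paste(rc$ingredient_id[is.na(idx)], collapse = ", ")))
  }
  post <- batch_post_weight(db, composite_id)
  added <- sum(rc$raw_weight_g * estimates$added_g[idx] / 100) / post * 100
  free <- sum(rc$raw_weight_g * estimates$free_g[idx] / 100) / post * 100
  c(added_g = added, free_g = free)
}

# Decision chain for one single item and one sugar type ("added"/"free").
# Returns list(step, value, note). `est_for` resolves another item's estimate
# (used by the proportional-reference step).
single_step_value <- function(food, profile, type, config, est_for) {
  total <- profile$total_sugars_g
  cat_ <- food$category
  res <- function(step, value, note) list(step = as.integer(step),
                                          value = value, note = note)

  # Step 1: no sugars at all.
  if (total <= SUGARS_TOL) return(res(1, 0, "no sugars"))

  # Step 2/3: category-determined natural sugars.
  if (cat_ %in% INTRINSIC_CATEGORIES) {
    return(res(2, 0, "intrinsic sugars only"))
  }
  if (cat_ == "juice_vegetable") {
    if (type == "free" && config$vegetable_juice_in_free) {
      return(res(3, total, "vegetable juice counted as free"))
    }
    return(res(2, 0, "vegetable juice excluded"))
  }
  if (cat_ %in% FREE_SOURCE_CATEGORIES) {
    if (type == "added") {
      if (cat_ == "honey" && config$honey_in_added) {
        return(res(3, total, "honey counted as added"))
      }
      return(res(2, 0, "natural free-sugars source, not added"))
    }
    return(res(3, total, "natural free-sugars source"))
  }

  # Plain bread with dough batch data: discount small fermentation amounts,
  # otherwise the batch sugars are deliberate additions.
  if (cat_ == "bread_plain" && !is.null(config$bread_batches) &&
      food$item_id %in% config$bread_batches$item_id) {
    b <- config$bread_batches[config$bread_batches$item_id == food$item_id, ]
    if (bread_rule(food, b$pre_baking_weight_g[[1]], b$sugars_in_batch_g[[1]],
                   config)) {
      return(res(2, 0, "bread discount (< threshold per 1000 g pre-baking weight)"))
    }
    return(res(3, total, "bread above discount threshold: sugars added"))
  }

  # Step 3: all sugars added (explicit flag, all-added category, or sweetened
  # pickled products lacking an unsweetened counterpart).
  has_counterpart <- !is.na(food$unsweetened_counterpart_id)
  all_added <- isTRUE(food$sugars_all_added) || cat_ %in% ALL_ADDED_CATEGORIES ||
    (cat_ == "pickled_sweetened" && !has_counterpart)
  if (all_added) return(res(3, total, "all sugars added"))
  if (type == "free" && isTRUE(food$sugars_all_free)) {
    return(res(3, total, "all sugars free"))
  }

  # Step 5: subtraction against an unsweetened counterpart.
  if (has_counterpart) {
    cp <- est_for(food$unsweetened_counterpart_id, want = "total")
    v <- total - cp
    note <- "unsweetened counterpart subtraction"
    if (v < 0) {
      note <- paste0(note, " (clamped to 0)")
      v <- 0
    }
    return(res(5, v, note))
  }

  # Step 6: analytical fructose subtraction for fruit/vegetable foods.
  if (isTRUE(food$contains_fruit_or_veg) && !is.na(profile$fructose_g)) {
    v <- max(0, total - profile$fructose_g)
    note <- if (total < profile$fructose_g) {
      "fructose subtraction (clamped to 0)"
    } else "fructose subtraction"
    return(res(6, v, note))
  }

  # a declared or scaled estimate can never exceed measured total sugars
  cap <- function(v, note) {
    if (v > total) list(v = total, note = paste0(note, " (capped at total sugars)"))
    else list(v = v, note = note)
  }

  # Step 7: manufacturer/recipe override supplied as data.
  ov <- config$overrides
  if (!is.null(ov) && food$item_id %in% ov$item_id) {
    row <- ov[ov$item_id == food$item_id, ]
    v <- if (type == "added") row$added_g[[1]] else row$free_g[[1]]
    c7 <- cap(v, "manufacturer/recipe information")
    return(res(7, c7$v, c7$note))
  }

  # Step 8: proportional scaling from a comparable reference item.
  pr <- config$proportional_references
  if (!is.null(pr) && food$item_id %in% pr$item_id) {
    row <- pr[pr$item_id == food$item_id, ]
    ref <- est_for(row$reference_id[[1]], want = type)
    c8 <- cap(row$ratio[[1]] * ref, "proportional to reference item")
    return(res(8, c8$v, c8$note))
  }

  # Step 10: border-case fallback.
  res(10, config$step10_fraction * total,
      sprintf("fallback: %.0f%% of total sugars", 100 * config$step10_fraction))
}

#' Assign procedure steps and estimate added/free sugars for every item
#'
#' Runs the ten-step decision procedure over a whole database. Single items
#' are classified by steps 1-3, 5-8 and 10 (in that order, first applicable
#' rule wins, separately for added and for free sugars); composite items are
#' assigned step 4 when all direct components sit at steps 1-4 and step 9
#' otherwise, with their content obtained by yield-adjusted recipe-weighted
#' aggregation of the component estimates. Steps 1-6 are objective (data or
#' rule driven), steps 7-10 subjective. The procedure is total: an item that
#' matches no rule is an error, as is a subjective item lacking its override
#' or reference data.
#'
#' @param db A validated `food_db`.
#' @param config A [procedure_config()].
#' @return A tibble of class `sugar_estimates` with columns
#'   `item_id, kind, step_added, step_free, added_g, free_g, total_g,
#'   objective_added, objective_free, notes`.
#' @export
assign_and_estimate <- function(db, config = procedure_config()) {
  stopifnot(inherits(config, "procedure_config"))
  profiles <- resolve_profiles(db)
  ord <- topological_order(db)
  foods <- db$foods
  frow <- stats::setNames(seq_len(nrow(foods)), foods$item_id)
  prow <- stats::setNames(seq_len(nrow(profiles)), profiles$item_id)

  est <- new.env(parent = emptyenv())
  in_progress <- character(0)

  estimate_item <- function(id) {
    if (!is.null(est[[id]])) return(est[[id]])
    if (id %in% in_progress) {
      abort(paste0("circular proportional-reference chain at: ", id))
    }
    if (!id %in% names(frow)) abort(paste0("unknown item id: ", id))
    in_progress <<- c(in_progress, id)
    on.exit(in_progress <<- setdiff(in_progress, id), add = TRUE)

    food <- foods[frow[[id]], ]
    profile <- profiles[prow[[id]], ]
    if (food$kind == "composite") {
      rc <- db$recipes[db$recipes$composite_id == id, ]
      comp_est <- lapply(rc$ingredient_id, estimate_item)
      step_a <- composite_step(vapply(comp_est, `[[`, 1L, "step_added"))
      step_f <- composite_step(vapply(comp_est, `[[`, 1L, "step_free"))
      etab <- tibble(
        item_id = rc$ingredient_id,
        added_g = vapply(comp_est, `[[`, 0, "added_g"),
        free_g = vapply(comp_est, `[[`, 0, "free_g"))
      content <- composite_content(db, id, etab)
      out <- list(item_id = id, kind = "composite",
                  step_added = step_a, step_free = step_f,
                  added_g = unname(content[["added_g"]]),
                  free_g = unname(content[["free_g"]]),
                  total_g = profile$total_sugars_g,
                  notes = "recipe-weighted aggregation of components")
    } else {
      est_for <- function(other_id, want) {
        if (want == "total") {
          op <- profiles[prow[[other_id]], ]
          if (is.null(op$total_sugars_g)) abort(paste0("unknown item id: ", other_id))
          return(op$total_sugars_g)
        }
        e <- estimate_item(other_id)
        if (want == "added") e$added_g else e$free_g
      }
      a <- single_step_value(food, profile, "added", config, est_for)
      f <- single_step_value(food, profile, "free", config, est_for)
      if (a$value > f$value + SUGARS_TOL) {
        abort(paste0(id, ": estimated added sugars (", a$value,
                     ") exceed free sugars (", f$value,
                     "); check overrides/references"))
      }
      out <- list(item_id = id, kind = "single",
                  step_added = a$step, step_free = f$step,
                  added_g = a$value, free_g = max(f$value, a$value),
                  total_g = profile$total_sugars_g,
                  notes = paste0("added: ", a$note, "; free: ", f$note))
    }
    est[[id]] <- out
    out
  }

  rows <- lapply(ord, estimate_item)
  out <- dplyr::bind_rows(rows)
  out <- mutate(out,
                objective_added = .data$step_added <= 6L,
                objective_free = .data$step_free <= 6L)
  out <- out[match(foods$item_id, out$item_id),
             c("item_id", "kind", "step_added", "step_free", "added_g",
               "free_g", "total_g", "objective_added", "objective_free",
               "notes")]
  class(out) <- c("sugar_estimates", class(out))
  out
}

#' Step distribution of sugar estimates
#'
#' Tabulates how many items were assigned each procedure step, separately for
#' added and free sugars, with percentages to one decimal. Accepts either an
#' estimates table from [assign_and_estimate()] or a pre-computed counts table
#' with columns `step, added_n, free_n` (e.g. a published distribution).
#'
#' @param x A `sugar_estimates` tibble or a counts tibble.
#' @return Tibble of class `step_distribution` with columns
#'   `step, sugar_type, n, pct`; steps 1-10 appear for both sugar types and
#'   counts sum to the database size.
#' @export
step_distribution <- function(x) {
  if (all(c("step", "added_n", "free_n") %in% names(x))) {
    counts <- as_tibble(x)
  } else {
    stopifnot(all(c("step_added", "step_free") %in% names(x)))
    counts <- tibble(
      step = 1:10,
      added_n = as.integer(table(factor(x$step_added, levels = 1:10))),
      free_n = as.integer(table(factor(x$step_free, levels = 1:10))))
  }
  long <- tidyr::pivot_longer(counts, c("added_n", "free_n"),
                              names_to = "sugar_type", values_to = "n")
  long <- mutate(long,
                 sugar_type = sub("_n$", "", .data$sugar_type))
  long <- group_by(long, .data$sugar_type)
  long <- mutate(long, pct = round(.data$n / sum(.data$n) * 100, 1))
  long <- ungroup(long)
  long <- arrange(long, .data$sugar_type, .data$step)
  class(long) <- c("step_distribution", class(long))
  long
}

#' Objective-step fractions
#'
#' Share of items whose estimate came from an objective step (1-6) rather than
#' a subjective one (7-10), rounded to the nearest integer percent.
#'
#' @param x A `step_distribution` or `sugar_estimates` object.
#' @return Tibble `sugar_type, objective_pct, subjective_pct`.
#' @export
objective_fraction <- function(x) {
  if (!inherits(x, "step_distribution")) x <- step_distribution(x)
  out <- group_by(x, .data$sugar_type)
  out <- summarise(out,
                   objective_pct = round(sum(.data$n[.data$step <= 6]) /
                                           sum(.data$n) * 100),
                   .groups = "drop")
  mutate(out, subjective_pct = 100 - .data$objective_pct)
}

#' Share of items containing a given sugar type
#'
#' @param n_containing Count of items with non-zero content.
#' @param n_total Database size.
#' @return Integer percent (nearest).
#' @export
containing_share_pct <- function(n_containing, n_total) {
  round(n_containing / n_total * 100)
}

#' Write sugar estimates to CSV
#'
#' @param estimates A `sugar_estimates` tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_estimates <- function(estimates, path) {
  out <- mutate(estimates,
    across(c("added_g", "free_g", "total_g"), fmt_num),
    across(c("objective_added", "objective_free"), fmt_lgl))
  out <- rename(out,
    added_sugars_g_per100 = "added_g", free_sugars_g_per100 = "free_g",
    total_sugars_g_per100 = "total_g")
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read a sugar-estimates CSV
#'
#' @param path Path written by [write_estimates()].
#' @return A `sugar_estimates` tibble.
#' @export
read_estimates <- function(path) {
  e <- readr::read_csv(path,
    col_types = readr::cols(
      item_id = "c", kind = "c", step_added = "i", step_free = "i",
      added_sugars_g_per100 = "d", free_sugars_g_per100 = "d",
      total_sugars_g_per100 = "d", objective_added = "l",
      objective_free = "l", notes = "c"),
    na = c("", "NA"), progress = FALSE)
  e <- rename(e, added_g = "added_sugars_g_per100",
              free_g = "free_sugars_g_per100",
              total_g = "total_sugars_g_per100")
  class(e) <- c("sugar_estimates", class(e))
  e
}
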