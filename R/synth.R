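default_category_mix <- function() {
  c(beverage_soft = 0.06, juice_fruit = 0.04, juice_vegetable = 0.01,
    honey = 0.01, syrup = 0.01, fruit_raw = 0.08, vegetable_raw = 0.10,
    dairy_plain = 0.06, dairy_sweetened = 0.06, bread_plain = 0.06,
    baked_sweet = 0.08, cereal_breakfast = 0.04, confectionery = 0.08,
    pickled_sweetened = 0.03, pseudocereal = 0.02, meat_fish_plain = 0.12,
    fat_oil = 0.04, other_single = 0.10)
}

default_participants <- function() {
  tibble(school_year = rep(c("5", "8", "11"), each = 2),
         sex = rep(c("girl", "boy"), 3),
         n = c(559L, 490L, 574L, 476L, 577L, 423L))
}

#' Configuration for the synthetic food database and survey generator
#'
#' Defaults emulate the conditions of a national two-day adolescent dietary
#' survey: a food list of 844 single and 639 composite items; 3099
#' participants in school years 5, 8 and 11 (girl counts 559/574/577); two
#' recall days per participant with weekend (Friday-Sunday) probability 3/7;
#' habitual total-sugars intake with median 100 g/day and habitual energy
#' with median 8.5 MJ/day, log-scale between-/within-person variances
#' 0.16/0.25 (sugars) and 0.05/0.08 (energy), correlation 0.6 between the
#' sugars and energy deviations; a person-level added-sugars share centred
#' at 0.51 and a free-but-not-added share of the remainder centred at 0.163
#' (so habitual added/free/total medians sit near 51/59/100 g/day); a
#' multiplicative weekend effect of 1.1 on sugars.
#'
#' @param n_single,n_composite Numbers of single and composite items.
#' @param max_dag_depth Maximum nesting depth of composite recipes (>= 1).
#' @param category_mix Named probabilities over [food_categories()]; must sum
#'   to 1.
#' @param participants Tibble `school_year, sex, n` of roster counts.
#' @param median_habitual_total Median of the true habitual total-sugars
#'   distribution, g/day (the day-level log location is derived from it).
#' @param sigma2_between,sigma2_within Log-scale variance components of daily
#'   total sugars.
#' @param median_habitual_energy Median of the true habitual energy
#'   distribution, kJ/day.
#' @param sigma2_between_energy,sigma2_within_energy Log-scale variance
#'   components of daily energy.
#' @param energy_sugars_cor Correlation between the sugars and energy
#'   person-level (and day-level) log deviations; keeps low-energy/high-sugar
#'   days as rare as they are in real data while leaving the marginal
#'   variance components exact.
#' @param added_share_mean,added_share_conc Beta mean/concentration of the
#'   person-level added share of total sugars.
#' @param free_extra_share_mean,free_extra_share_conc Beta mean/concentration
#'   of the free-but-not-added share of non-added sugars.
#' @param weekend_effect Multiplicative weekend effect on daily sugars.
#' @param weekend_share Probability a recall day is a weekend day (3/7).
#' @param seed Integer seed fixing all randomness.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_single = 844, n_composite = 639, max_dag_depth = 3,
                         category_mix = default_category_mix(),
                         participants = default_participants(),
                         median_habitual_total = 100,
                         sigma2_between = 0.16, sigma2_within = 0.25,
                         median_habitual_energy = 8500,
                         sigma2_between_energy = 0.05,
                         sigma2_within_energy = 0.08,
                         energy_sugars_cor = 0.6,
                         added_share_mean = 0.51, added_share_conc = 30,
                         free_extra_share_mean = 0.163,
                         free_extra_share_conc = 30,
                         weekend_effect = 1.1, weekend_share = 3 / 7,
                         seed = 1L) {
  if (max_dag_depth < 1) abort("max_dag_depth must be >= 1")
  if (abs(sum(category_mix) - 1) > 1e-8) abort("category_mix must sum to 1")
  if (!all(names(category_mix) %in% food_categories())) {
    abort("category_mix has unknown categories")
  }
  if (any(c(sigma2_between, sigma2_within, sigma2_between_energy,
            sigma2_within_energy) < 0)) {
    abort("variance components must be >= 0")
  }
  if (abs(energy_sugars_cor) > 1) abort("energy_sugars_cor must be in [-1, 1]")
  structure(as.list(environment()), class = "synth_config")
}

# per-100 g energy beyond sugars, kJ, by category
energy_base <- function(cat_, n) {
  rng <- switch(cat_,
    beverage_soft = c(0, 20), juice_fruit = c(20, 60),
    juice_vegetable = c(20, 60), honey = c(20, 60), syrup = c(20, 60),
    fruit_raw = c(50, 150), vegetable_raw = c(50, 150),
    dairy_plain = c(150, 250), dairy_sweetened = c(150, 250),
    bread_plain = c(900, 1100), baked_sweet = c(1200, 1600),
    cereal_breakfast = c(1300, 1500), confectionery = c(1200, 1800),
    pickled_sweetened = c(200, 400), pseudocereal = c(1400, 1500),
    meat_fish_plain = c(500, 900), fat_oil = c(3700, 3700),
    other_single = c(400, 1200))
  stats::runif(n, rng[1], rng[2])
}

total_sugars_range <- function(cat_) {
  switch(cat_,
    beverage_soft = c(8, 12), juice_fruit = c(8, 12),
    juice_vegetable = c(2, 6), honey = c(75, 82), syrup = c(60, 80),
    fruit_raw = c(5, 15), vegetable_raw = c(0.5, 5),
    dairy_plain = c(3, 5), dairy_sweetened = c(10, 16),
    bread_plain = NULL, baked_sweet = c(15, 35),
    cereal_breakfast = c(10, 30), confectionery = c(40, 70),
    pickled_sweetened = c(5, 15), pseudocereal = c(0.5, 2),
    meat_fish_plain = c(0, 0), fat_oil = c(0, 0),
    other_single = c(5, 30))
}

#' Generate a synthetic food database with planted ground truth
#'
#' Draws single items per category with internally consistent profiles and
#' flags, builds composite items over a random ingredient DAG of bounded
#' depth, and computes the ground-truth added/free sugars of every item
#' analytically from the planted sugar-source labels (so the decision
#' procedure's output can be checked against a known answer). Counterpart
#' subtraction, fructose subtraction, bread batch data, manufacturer
#' overrides and proportional references are all represented, so every
#' procedure step occurs. Output is a pure function of the config (seed
#' included).
#'
#' @param config A [synth_config()].
#' @return A `synth_food_db` list: `db` (a validated [food_db()]), `truth`
#'   (tibble `item_id, kind, step_added, step_free, added_g, free_g,
#'   total_g`), and `config` (a [procedure_config()] carrying the planted
#'   overrides, references and bread batches).
#' @export
generate_food_db <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n_single <- config$n_single
  mix <- config$category_mix

  cats <- sample(names(mix), n_single, replace = TRUE, prob = mix)
  # guarantee the categories the survey realizer and the procedure need,
  # but only those the configured mix actually allows
  anchor <- intersect(
    c("beverage_soft", "juice_fruit", "fruit_raw", "fat_oil",
      "dairy_plain", "vegetable_raw", "confectionery"),
    names(mix)[mix > 0])
  if (n_single >= length(anchor)) cats[seq_along(anchor)] <- anchor

  ids <- sprintf("S%04d", seq_len(n_single))
  # base categories first so counterparts/references can point at them
  phase2 <- cats %in% c("dairy_sweetened", "pickled_sweetened", "other_single")
  gen_order <- c(which(!phase2), which(phase2))

  rows <- vector("list", n_single)
  truth <- vector("list", n_single)
  overrides <- list()
  references <- list()
  breads <- list()
  by_cat <- split(ids, cats)
  other_kind <- 0L

  for (i in gen_order) {
    cat_ <- cats[[i]]
    id <- ids[[i]]
    flags <- list(all_added = FALSE, all_free = FALSE, fruitveg = FALSE)
    counterpart <- NA_character_
    fruct <- NA_real_

    if (cat_ == "bread_plain") {
      pre <- 1000
      batch_sugars <- round(stats::runif(1, 3, 15), 4)
      total <- round(batch_sugars / 10, 4)
      breads[[length(breads) + 1]] <- tibble(
        item_id = id, pre_baking_weight_g = pre,
        sugars_in_batch_g = batch_sugars)
    } else {
      rng <- total_sugars_range(cat_)
      total <- round(stats::runif(1, rng[1], rng[2]), 4)
    }

    mono <- round(total * stats::runif(1, 0.3, 0.7), 4)
    di <- round(total - mono, 4)
    total <- mono + di

    if (cat_ %in% c("fruit_raw", "juice_fruit", "vegetable_raw",
                    "juice_vegetable")) {
      flags$fruitveg <- TRUE
      fruct <- round(min(mono, total * stats::runif(1, 0.2, 0.5)), 4)
    }
    if (cat_ %in% c("confectionery", "beverage_soft", "baked_sweet")) {
      flags$all_added <- TRUE
    }

    # planted truth per category semantics
    if (total <= SUGARS_TOL) {
      tr <- list(sa = 1L, sf = 1L, a = 0, f = 0)
    } else if (cat_ %in% INTRINSIC_CATEGORIES || cat_ == "juice_vegetable") {
      tr <- list(sa = 2L, sf = 2L, a = 0, f = 0)
    } else if (cat_ %in% FREE_SOURCE_CATEGORIES) {
      tr <- list(sa = 2L, sf = 3L, a = 0, f = total)
    } else if (cat_ == "bread_plain") {
      if (batch_sugars < 9) {
        tr <- list(sa = 2L, sf = 2L, a = 0, f = 0)
      } else {
        tr <- list(sa = 3L, sf = 3L, a = total, f = total)
      }
    } else if (cat_ %in% c("confectionery", "beverage_soft", "baked_sweet")) {
      tr <- list(sa = 3L, sf = 3L, a = total, f = total)
    } else if (cat_ == "cereal_breakfast") {
      if (stats::runif(1) < 0.5) {
        flags$fruitveg <- TRUE
        fruct <- round(min(mono, total * stats::runif(1, 0.2, 0.4)), 4)
        v <- total - fruct
        tr <- list(sa = 6L, sf = 6L, a = v, f = v)
      } else {
        flags$all_added <- TRUE
        tr <- list(sa = 3L, sf = 3L, a = total, f = total)
      }
    } else if (cat_ %in% c("dairy_sweetened", "pickled_sweetened")) {
      base_cat <- if (cat_ == "dairy_sweetened") "dairy_plain" else "vegetable_raw"
      pool <- by_cat[[base_cat]]
      use_cp <- length(pool) > 0 &&
        (cat_ == "dairy_sweetened" || stats::runif(1) < 0.5)
      if (use_cp) {
        counterpart <- sample(pool, 1)
        cp_total <- rows[[match(counterpart, ids)]]$total_sugars_g
        v <- max(0, total - cp_total)
        tr <- list(sa = 5L, sf = 5L, a = v, f = v)
      } else {
        if (cat_ == "dairy_sweetened") flags$all_added <- TRUE
        tr <- list(sa = 3L, sf = 3L, a = total, f = total)
      }
    } else { # other_single: subjective steps
      other_kind <- other_kind + 1L
      sub <- c(7L, 8L, 10L)[other_kind %% 3L + 1L]
      ref_pool <- c(by_cat[["confectionery"]], by_cat[["beverage_soft"]])
      if (sub == 8L && length(ref_pool) == 0) sub <- 10L
      if (sub == 7L) {
        a <- round(total * stats::runif(1, 0.2, 0.8), 4)
        f <- round(a + (total - a) * stats::runif(1, 0, 0.5), 4)
        overrides[[length(overrides) + 1]] <- tibble(
          item_id = id, added_g = a, free_g = f)
        tr <- list(sa = 7L, sf = 7L, a = a, f = f)
      } else if (sub == 8L) {
        ref <- sample(ref_pool, 1)
        ref_total <- rows[[match(ref, ids)]]$total_sugars_g
        # ratio chosen so the scaled estimate stays below the item's total
        ratio <- round(stats::runif(1, 0.3, 0.9) * total / ref_total, 4)
        references[[length(references) + 1]] <- tibble(
          item_id = id, reference_id = ref, ratio = ratio)
        v <- min(ratio * ref_total, total)
        tr <- list(sa = 8L, sf = 8L, a = v, f = v)
      } else {
        tr <- list(sa = 10L, sf = 10L, a = 0.5 * total, f = 0.5 * total)
      }
    }

    energy <- round(energy_base(cat_, 1) + total * 17, 2)
    rows[[i]] <- tibble(
      item_id = id, name = paste0(gsub("_", " ", cat_), " ", i),
      kind = "single", category = cat_,
      monosaccharides_g = mono, disaccharides_g = di, total_sugars_g = total,
      fructose_g = fruct, energy_kJ = energy,
      sugars_all_added = flags$all_added, sugars_all_free = flags$all_free,
      contains_fruit_or_veg = flags$fruitveg,
      unsweetened_counterpart_id = counterpart,
      provenance = "synthetic")
    truth[[i]] <- tibble(item_id = id, kind = "single",
                         step_added = tr$sa, step_free = tr$sf,
                         added_g = tr$a, free_g = tr$f, total_g = total)
  }

  foods <- bind_rows(rows)
  truth_tbl <- bind_rows(truth)

  # composites over a random DAG of bounded depth
  n_comp <- config$n_composite
  recipe_rows <- list()
  meta_rows <- list()
  comp_rows <- list()
  comp_level <- integer(0)
  if (n_comp > 0) {
    levels <- sort(sample(seq_len(config$max_dag_depth), n_comp,
                          replace = TRUE))
    comp_ids <- sprintf("C%04d", seq_len(n_comp))
    for (j in seq_len(n_comp)) {
      lvl <- levels[[j]]
      pool <- c(ids, comp_ids[seq_len(j - 1)][comp_level < lvl])
      k <- sample(2:min(5, length(pool)), 1)
      ing <- sample(pool, k)
      w <- round(stats::runif(k, 20, 500), 1)
      pre <- sum(w)
      post <- max(1, round(pre * stats::runif(1, 0.75, 1), 1))
      recipe_rows[[j]] <- tibble(composite_id = comp_ids[[j]],
                                 ingredient_id = ing, raw_weight_g = w)
      meta_rows[[j]] <- tibble(composite_id = comp_ids[[j]],
                               batch_post_weight_g = post)
      comp_rows[[j]] <- tibble(
        item_id = comp_ids[[j]], name = paste0("composite ", j),
        kind = "composite", category = "other_single",
        monosaccharides_g = NA_real_, disaccharides_g = NA_real_,
        total_sugars_g = NA_real_, fructose_g = NA_real_,
        energy_kJ = NA_real_,
        sugars_all_added = FALSE, sugars_all_free = FALSE,
        contains_fruit_or_veg = FALSE,
        unsweetened_counterpart_id = NA_character_,
        provenance = "synthetic")
      comp_level <- c(comp_level, lvl)
    }
    foods <- bind_rows(foods, bind_rows(comp_rows))
  }
  recipes <- if (length(recipe_rows)) bind_rows(recipe_rows) else NULL
  meta <- if (length(meta_rows)) bind_rows(meta_rows) else NULL

  db <- food_db(foods, recipes, meta)

  # analytic ground truth for composites, bottom-up
  if (n_comp > 0) {
    ord <- topological_order(db)
    tmap <- split(truth_tbl, truth_tbl$item_id)
    prof <- resolve_profiles(db)
    for (id in ord) {
      if (db$foods$kind[db$foods$item_id == id] != "composite") next
      rc <- db$recipes[db$recipes$composite_id == id, ]
      post <- batch_post_weight(db, id)
      comp <- bind_rows(tmap[rc$ingredient_id])
      a <- sum(rc$raw_weight_g * comp$added_g / 100) / post * 100
      f <- sum(rc$raw_weight_g * comp$free_g / 100) / post * 100
      tmap[[id]] <- tibble(
        item_id = id, kind = "composite",
        step_added = composite_step(comp$step_added),
        step_free = composite_step(comp$step_free),
        added_g = a, free_g = f,
        total_g = prof$total_sugars_g[prof$item_id == id])
    }
    truth_tbl <- bind_rows(tmap[db$foods$item_id])
  }

  proc_config <- procedure_config(
    overrides = if (length(overrides)) bind_rows(overrides) else NULL,
    proportional_references = if (length(references)) bind_rows(references) else NULL,
    bread_batches = if (length(breads)) bind_rows(breads) else NULL)

  structure(list(db = db, truth = truth_tbl, config = proc_config),
            class = "synth_food_db")
}

#' Generate a synthetic two-day dietary survey
#'
#' Simulates the roster and recall records with a known variance structure.
#' Day totals are generated top-down: each participant gets a log-scale
#' habitual level (between-person variance), each day a within-person
#' deviation and a multiplicative weekend effect; per-person Beta-distributed
#' shares split total sugars into added, free-not-added and intrinsic parts.
#' Each day is then realized as a food list whose record-level sums reproduce
#' the drawn day totals (within the 2 d.p. gram rounding): a soft drink
#' carries the added part, fruit juice the free-not-added part, raw fruit
#' the intrinsic part, oil tops up energy, and one random garnish food is
#' absorbed into the targets before solving. True habitual intakes are
#' returned for recovery testing.
#'
#' @param config A [synth_config()].
#' @param synth A `synth_food_db` from [generate_food_db()] (the planted
#'   truth provides the per-100 g added/free values of each food).
#' @return List with `participants`, `records`, `truth` (per-participant true
#'   habitual `added_g, free_g, total_g, energy_kJ`), and `day_targets` (the
#'   drawn per-day totals).
#' @export
generate_survey <- function(config = synth_config(), synth) {
  stopifnot(inherits(config, "synth_config"),
            inherits(synth, "synth_food_db"))
  db <- synth$db
  if (nrow(db$foods) == 0) abort("empty database")
  set.seed(config$seed + 1L)

  prof <- resolve_profiles(db)
  per100 <- left_join(
    select(synth$truth, "item_id", "added_g", "free_g", "total_g"),
    select(prof, "item_id", "energy_kJ"), by = "item_id")

  pick <- function(cat_, need_sugar = TRUE) {
    cand <- db$foods$item_id[db$foods$category == cat_ &
                               db$foods$kind == "single"]
    if (need_sugar) {
      cand <- cand[per100$total_g[match(cand, per100$item_id)] > 0.5]
    }
    if (length(cand) == 0) {
      abort(paste0("database lacks a usable single item of category ", cat_))
    }
    sort(cand)[[1]]
  }
  b_added <- pick("beverage_soft")
  b_free <- pick("juice_fruit")
  b_intr <- pick("fruit_raw")
  b_energy <- pick("fat_oil", need_sugar = FALSE)
  basis <- per100[match(c(b_added, b_free, b_intr, b_energy), per100$item_id), ]

  roster <- tidyr::uncount(config$participants, .data$n)
  roster <- mutate(roster,
                   participant_id = sprintf("P%04d", row_number()))
  roster <- select(roster, "participant_id", "sex", "school_year")
  np <- nrow(roster)

  # day-level log locations derived from the configured habitual medians:
  # the habitual mean carries the within-variance smearing term and the
  # weekday/weekend mixture, so both are removed here
  week_mix <- (1 - config$weekend_share) +
    config$weekend_share * config$weekend_effect
  loc_T <- log(config$median_habitual_total) -
    config$sigma2_within / 2 - log(week_mix)
  loc_E <- log(config$median_habitual_energy) -
    config$sigma2_within_energy / 2

  rho <- config$energy_sugars_cor
  bmean <- config$added_share_mean
  bconc <- config$added_share_conc
  fmean <- config$free_extra_share_mean
  fconc <- config$free_extra_share_conc
  u1 <- stats::rnorm(np)
  u2 <- stats::rnorm(np)
  persons <- mutate(roster,
    b_T = sqrt(config$sigma2_between) * u1,
    b_E = sqrt(config$sigma2_between_energy) *
      (rho * u1 + sqrt(1 - rho^2) * u2),
    a_share = stats::rbeta(np, bmean * bconc, (1 - bmean) * bconc),
    j_share = stats::rbeta(np, fmean * fconc, (1 - fmean) * fconc))

  days <- tidyr::expand_grid(participant_id = persons$participant_id,
                             day_index = 1:2)
  days <- left_join(days, persons, by = "participant_id")
  nd <- nrow(days)
  v1 <- stats::rnorm(nd)
  v2 <- stats::rnorm(nd)
  days <- mutate(days,
    weekend = stats::rbinom(nd, 1, config$weekend_share),
    day_class = if_else(.data$weekend == 1, "weekend", "weekday"),
    w_T = sqrt(config$sigma2_within) * v1,
    w_E = sqrt(config$sigma2_within_energy) *
      (rho * v1 + sqrt(1 - rho^2) * v2),
    total = exp(loc_T + .data$b_T +
                  log(config$weekend_effect) * .data$weekend + .data$w_T),
    energy = exp(loc_E + .data$b_E + .data$w_E),
    added = .data$a_share * .data$total,
    free_extra = .data$j_share * (.data$total - .data$added),
    intrinsic = .data$total - .data$added - .data$free_extra)

  # one random garnish food per day, absorbed into the targets
  g_idx <- sample.int(nrow(per100), nd, replace = TRUE)
  g <- per100[g_idx, ]
  days <- mutate(days,
    garnish_id = g$item_id,
    garnish_g = round(stats::runif(nd, 5, 30), 2),
    g_add = .data$garnish_g * g$added_g / 100,
    g_free_extra = .data$garnish_g * (g$free_g - g$added_g) / 100,
    g_intr = .data$garnish_g * (g$total_g - g$free_g) / 100,
    g_energy = .data$garnish_g * g$energy_kJ / 100,
    keep_garnish = .data$added - .data$g_add > 0 &
      .data$free_extra - .data$g_free_extra > 0 &
      .data$intrinsic - .data$g_intr > 0 &
      .data$energy - .data$g_energy > 0)
  days <- mutate(days,
    garnish_g = if_else(.data$keep_garnish, .data$garnish_g, 0),
    across(c("g_add", "g_free_extra", "g_intr", "g_energy"),
           ~ if_else(.data$keep_garnish, .x, 0)))

  t_add <- basis$added_g[[1]]
  t_free <- basis$free_g[[2]]
  t_intr <- basis$total_g[[3]]
  e_oil <- basis$energy_kJ[[4]]
  days <- mutate(days,
    g1 = round((.data$added - .data$g_add) / t_add * 100, 2),
    g2 = round((.data$free_extra - .data$g_free_extra) / t_free * 100, 2),
    g3 = round((.data$intrinsic - .data$g_intr) / t_intr * 100, 2),
    e_used = .data$g1 * basis$energy_kJ[[1]] / 100 +
      .data$g2 * basis$energy_kJ[[2]] / 100 +
      .data$g3 * basis$energy_kJ[[3]] / 100 + .data$g_energy,
    g4 = round(pmax(0, (.data$energy - .data$e_used) / e_oil * 100), 2))

  long <- tidyr::pivot_longer(
    select(days, "participant_id", "day_index", "day_class",
           "garnish_id", "garnish_g", "g1", "g2", "g3", "g4"),
    c("garnish_g", "g1", "g2", "g3", "g4"),
    names_to = "slot", values_to = "amount_g")
  long <- mutate(long,
    food_id = dplyr::case_when(
      .data$slot == "garnish_g" ~ .data$garnish_id,
      .data$slot == "g1" ~ b_added,
      .data$slot == "g2" ~ b_free,
      .data$slot == "g3" ~ b_intr,
      .data$slot == "g4" ~ b_energy))
  records <- filter(long, .data$amount_g > 0)
  records <- select(records, "participant_id", "day_index", "day_class",
                    "food_id", "amount_g")
  records <- arrange(records, .data$participant_id, .data$day_index,
                     .data$food_id)

  truth <- mutate(persons,
    total_g = exp(loc_T + .data$b_T + config$sigma2_within / 2) * week_mix,
    added_g = .data$a_share * .data$total_g,
    free_g = (.data$a_share + .data$j_share * (1 - .data$a_share)) *
      .data$total_g,
    energy_kJ = exp(loc_E + .data$b_E + config$sigma2_within_energy / 2))
  truth <- select(truth, "participant_id", "added_g", "free_g", "total_g",
                  "energy_kJ")

  day_targets <- select(days, "participant_id", "day_index", "day_class",
                        "added", "free_extra", "intrinsic", "total", "energy")

  list(participants = roster, records = records, truth = truth,
       day_targets = day_targets)
}
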