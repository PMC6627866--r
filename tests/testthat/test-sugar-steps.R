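estimates_for <- function(foods, config = procedure_config(), ...) {
  db <- food_db(foods, ...)
  assign_and_estimate(db, config)
}

test_that("single-item decision traces follow the step semantics", {
  est <- estimates_for(dplyr::bind_rows(
    single_item("cola", "beverage_soft", total = 10.6, all_added = TRUE),
    single_item("orange_juice", "juice_fruit", total = 9, mono = 5,
                fructose = 2.5, fruitveg = TRUE),
    single_item("honey1", "honey", total = 80, mono = 60),
    single_item("carrot_juice", "juice_vegetable", total = 4, fruitveg = TRUE),
    single_item("plain_tea", total = 0, mono = 0, energy = 1)))

  cola <- est[est$item_id == "cola", ]
  expect_equal(c(cola$step_added, cola$step_free), c(3L, 3L))
  expect_equal(c(cola$added_g, cola$free_g), c(10.6, 10.6))

  oj <- est[est$item_id == "orange_juice", ]
  expect_equal(oj$step_added, 2L)
  expect_equal(oj$added_g, 0)
  expect_equal(oj$step_free, 3L)
  expect_equal(oj$free_g, 9)

  h <- est[est$item_id == "honey1", ]
  expect_equal(c(h$added_g, h$free_g), c(0, 80))

  cj <- est[est$item_id == "carrot_juice", ]
  expect_equal(c(cj$added_g, cj$free_g), c(0, 0))

  tea <- est[est$item_id == "plain_tea", ]
  expect_equal(c(tea$step_added, tea$step_free), c(1L, 1L))
  expect_equal(c(tea$added_g, tea$free_g), c(0, 0))
})

test_that("config switches move honey and vegetable juice between definitions", {
  foods <- dplyr::bind_rows(
    single_item("honey1", "honey", total = 80, mono = 60),
    single_item("carrot_juice", "juice_vegetable", total = 4, fruitveg = TRUE))
  est <- estimates_for(foods, procedure_config(honey_in_added = TRUE,
                                               vegetable_juice_in_free = TRUE))
  expect_equal(est$added_g[est$item_id == "honey1"], 80)
  expect_equal(est$free_g[est$item_id == "carrot_juice"], 4)
  expect_equal(est$added_g[est$item_id == "carrot_juice"], 0)
})

test_that("counterpart subtraction and fructose subtraction drive steps 5 and 6", {
  foods <- dplyr::bind_rows(
    single_item("yog_plain", "dairy_plain", total = 4.5),
    single_item("yog_sweet", "dairy_sweetened", total = 12.5,
                counterpart = "yog_plain"),
    single_item("muesli_fruit", "cereal_breakfast", total = 10, mono = 5,
                fructose = 3, fruitveg = TRUE),
    single_item("herring_sweet", "pickled_sweetened", total = 3,
                counterpart = "yog_plain"))  # counterpart total 4.5 > 3
  est <- estimates_for(foods)

  ys <- est[est$item_id == "yog_sweet", ]
  expect_equal(c(ys$step_added, ys$step_free), c(5L, 5L))
  expect_equal(ys$added_g, 8)

  mf <- est[est$item_id == "muesli_fruit", ]
  expect_equal(c(mf$step_added, mf$step_free), c(6L, 6L))
  expect_equal(mf$added_g, 7)

  hs <- est[est$item_id == "herring_sweet", ]
  expect_equal(hs$step_added, 5L)
  expect_equal(hs$added_g, 0)  # clamped

  expect_equal(fructose_subtraction(list(total_sugars_g = 5, fructose_g = 0)), 5)
  expect_warning(
    v <- fructose_subtraction(list(total_sugars_g = 2, fructose_g = 2.5)),
    "clamp")
  expect_equal(v, 0)
  expect_error(
    fructose_subtraction(list(total_sugars_g = 2, fructose_g = NA_real_)),
    "ineligible")
})

test_that("the bread discount threshold is strict", {
  bread <- single_item("loaf", "bread_plain", total = 0.9)
  expect_true(bread_rule(bread, 1000, 8))
  expect_false(bread_rule(bread, 1000, 9))
  expect_true(bread_rule(bread, 1000, 0))
  expect_error(bread_rule(single_item("x", "fruit_raw"), 1000, 5),
               "bread_plain")

  est <- estimates_for(
    dplyr::bind_rows(
      single_item("low", "bread_plain", total = 0.8),
      single_item("high", "bread_plain", total = 1.2)),
    procedure_config(bread_batches = tibble::tibble(
      item_id = c("low", "high"), pre_baking_weight_g = 1000,
      sugars_in_batch_g = c(8, 12))))
  expect_equal(est$added_g[est$item_id == "low"], 0)
  expect_equal(est$added_g[est$item_id == "high"], 1.2)
  expect_true(all(est$step_added <= 6))
})

test_that("subjective steps use overrides, references and the 50% fallback", {
  foods <- dplyr::bind_rows(
    single_item("ref_sweet", "confectionery", total = 50, all_added = TRUE),
    single_item("mystery1", total = 20),
    single_item("mystery2", total = 20),
    single_item("mystery3", total = 20),
    single_item("mystery4", total = 20))
  cfg <- procedure_config(
    overrides = tibble::tibble(item_id = "mystery1", added_g = 4, free_g = 6),
    proportional_references = tibble::tibble(
      item_id = c("mystery2", "mystery4"), reference_id = "ref_sweet",
      ratio = c(0.3, 0.6)))
  est <- estimates_for(foods, cfg)

  m1 <- est[est$item_id == "mystery1", ]
  expect_equal(c(m1$step_added, m1$added_g, m1$free_g), c(7, 4, 6))
  expect_false(m1$objective_added)

  m2 <- est[est$item_id == "mystery2", ]
  expect_equal(c(m2$step_added, m2$added_g), c(8, 15))

  # a scaled value above the item's own total sugars is capped there
  m4 <- est[est$item_id == "mystery4", ]
  expect_equal(c(m4$step_added, m4$added_g), c(8, 20))

  m3 <- est[est$item_id == "mystery3", ]
  expect_equal(c(m3$step_added, m3$added_g), c(10, 10))

  expect_error(procedure_config(
    overrides = tibble::tibble(item_id = "a", added_g = 5, free_g = 3)),
    "free")
  cyc <- procedure_config(proportional_references = tibble::tibble(
    item_id = c("mystery2", "mystery3"),
    reference_id = c("mystery3", "mystery2"), ratio = 0.5))
  expect_error(estimates_for(foods, cyc), "circular")
})

test_that("composite step rule and content aggregation", {
  expect_equal(composite_step(c(2, 4)), 4L)
  expect_equal(composite_step(c(2, 6)), 9L)
  expect_equal(composite_step(1), 4L)
  expect_error(composite_step(integer(0)), "at least one")

  db <- toy_db()
  est <- assign_and_estimate(db)
  mix <- est[est$item_id == "syrupmix", ]
  expect_equal(mix$step_added, 4L)
  expect_equal(mix$added_g, 50)

  cc <- composite_content(db, "syrupmix",
                          tibble::tibble(item_id = c("sugar", "water"),
                                         added_g = c(50, 0),
                                         free_g = c(50, 0)))
  expect_equal(unname(cc["added_g"]), 25)
  expect_error(composite_content(db, "syrupmix",
                                 tibble::tibble(item_id = "sugar",
                                                added_g = 50, free_g = 50)),
               "water")
})

test_that("step distribution reproduces published percentages and fractions", {
  counts <- reference_step_counts()
  dist <- step_distribution(counts)
  added <- dist[dist$sugar_type == "added", ]
  expect_equal(added$pct,
               c(13.1, 25.7, 9.8, 38.1, 1.3, 3.9, 0.1, 2.3, 5.0, 0.6))
  free <- dist[dist$sugar_type == "free", ]
  expect_equal(free$pct,
               c(13.1, 24.0, 11.9, 38.4, 1.3, 3.9, 0.1, 1.9, 4.7, 0.6))
  expect_equal(sum(added$n), 1483)

  of <- objective_fraction(dist)
  expect_equal(of$objective_pct[of$sugar_type == "added"], 92)
  expect_equal(of$objective_pct[of$sugar_type == "free"], 93)

  all1 <- step_distribution(tibble::tibble(step = 1:10,
                                           added_n = c(7, rep(0, 9)),
                                           free_n = c(7, rep(0, 9))))
  expect_equal(objective_fraction(all1)$objective_pct, c(100, 100))
})

test_that("procedure invariants hold on synthetic databases", {
  synth <- generate_food_db(small_config(seed = 11, n_single = 120,
                                         n_composite = 80))
  est <- assign_and_estimate(synth$db, synth$config)

  expect_equal(nrow(est), nrow(synth$db$foods))        # totality
  expect_true(all(est$added_g >= -1e-12))
  expect_true(all(est$added_g <= est$free_g + 1e-9))
  expect_true(all(est$free_g <= est$total_g + 1e-9))
  comp <- est[est$kind == "composite", ]
  expect_true(all(comp$step_added %in% c(4L, 9L)))
  expect_true(all(comp$step_free %in% c(4L, 9L)))

  # the 4-vs-9 rule matches the components' steps exactly
  emap <- est[match(synth$db$recipes$ingredient_id, est$item_id), ]
  by_comp <- split(emap$step_added, synth$db$recipes$composite_id)
  for (id in names(by_comp)) {
    expect_equal(est$step_added[est$item_id == id],
                 composite_step(by_comp[[id]]))
  }

  est2 <- assign_and_estimate(synth$db, synth$config)
  expect_identical(est, est2)                          # determinism
})

test_that("the estimator recovers planted ground truth exactly", {
  synth <- generate_food_db(small_config(seed = 5, n_single = 80,
                                         n_composite = 40))
  est <- assign_and_estimate(synth$db, synth$config)
  cmp <- dplyr::left_join(synth$truth, est, by = "item_id",
                          suffix = c("_truth", ""))
  expect_equal(cmp$step_added, cmp$step_added_truth)
  expect_equal(cmp$step_free, cmp$step_free_truth)
  expect_lt(max(abs(cmp$added_g - cmp$added_g_truth)), 1e-9)
  expect_lt(max(abs(cmp$free_g - cmp$free_g_truth)), 1e-9)
})

test_that("estimates round-trip through the estimates CSV", {
  synth <- generate_food_db(small_config(seed = 2, n_single = 15,
                                         n_composite = 5))
  est <- assign_and_estimate(synth$db, synth$config)
  path <- withr::local_tempfile(fileext = ".csv")
  write_estimates(est, path)
  rt <- read_estimates(path)
  expect_equal(rt$added_g, est$added_g, tolerance = 1e-6)
  expect_equal(rt$step_added, est$step_added)
})
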