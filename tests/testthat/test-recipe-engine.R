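test_that("topological order resolves nested composites bottom-up", {
  db <- nested_db()
  ord <- topological_order(db)
  expect_setequal(ord, db$foods$item_id)
  expect_lt(match("oil", ord), match("mayonnaise", ord))
  expect_lt(match("mayonnaise", ord), match("remoulade", ord))

  singles <- food_db(dplyr::bind_rows(single_item("b"), single_item("a"),
                                      single_item("c")))
  expect_equal(topological_order(singles), c("a", "b", "c"))
})

test_that("cycles are detected and named", {
  foods <- dplyr::bind_rows(
    single_item("s1"),
    tibble::tibble(
      item_id = c("A", "B"), name = c("A", "B"), kind = "composite",
      category = "other_single", monosaccharides_g = NA_real_,
      disaccharides_g = NA_real_, total_sugars_g = NA_real_,
      fructose_g = NA_real_, energy_kJ = NA_real_, sugars_all_added = FALSE,
      sugars_all_free = FALSE, contains_fruit_or_veg = FALSE,
      unsweetened_counterpart_id = NA_character_, provenance = "test"))
  recipes <- tibble::tibble(composite_id = c("A", "B"),
                            ingredient_id = c("B", "A"),
                            raw_weight_g = 100)
  db <- food_db(foods, recipes)
  expect_error(topological_order(db), "cycle.*A.*B")
  expect_error(flatten_to_singles(db, "A"), "cycle")
})

test_that("profile resolution follows the yield-adjusted weighted sum", {
  db <- toy_db()  # 50 g sucrose + 50 g water, post-weight 100 g
  p <- resolve_profile(db, "syrupmix")
  expect_equal(p$total_sugars_g, 50)
  expect_equal(p$energy_kJ, 850)

  # single-ingredient passthrough
  foods <- dplyr::bind_rows(
    single_item("a", total = 12, mono = 5, energy = 700),
    tibble::tibble(
      item_id = "wrap", name = "wrap", kind = "composite",
      category = "other_single", monosaccharides_g = NA_real_,
      disaccharides_g = NA_real_, total_sugars_g = NA_real_,
      fructose_g = NA_real_, energy_kJ = NA_real_, sugars_all_added = FALSE,
      sugars_all_free = FALSE, contains_fruit_or_veg = FALSE,
      unsweetened_counterpart_id = NA_character_, provenance = "test"))
  recipes <- tibble::tibble(composite_id = "wrap", ingredient_id = "a",
                            raw_weight_g = 100)
  meta <- tibble::tibble(composite_id = "wrap", batch_post_weight_g = 100)
  p2 <- resolve_profile(food_db(foods, recipes, meta), "wrap")
  expect_equal(p2$total_sugars_g, 12)
  expect_equal(p2$monosaccharides_g, 5)
  expect_equal(p2$energy_kJ, 700)
})

test_that("baking loss concentrates sugars through the post-weight", {
  # dough: flour 600 g at 1.5 g/100 g, water 350 g, sucrose 50 g; baked to 800 g
  foods <- dplyr::bind_rows(
    single_item("flour", total = 1.5, mono = 0.5, energy = 1500),
    single_item("water2", total = 0, mono = 0, energy = 0),
    single_item("sucrose", "confectionery", total = 100, mono = 0,
                all_added = TRUE, energy = 1700),
    tibble::tibble(
      item_id = "loaf", name = "loaf", kind = "composite",
      category = "bread_plain", monosaccharides_g = NA_real_,
      disaccharides_g = NA_real_, total_sugars_g = NA_real_,
      fructose_g = NA_real_, energy_kJ = NA_real_, sugars_all_added = FALSE,
      sugars_all_free = FALSE, contains_fruit_or_veg = FALSE,
      unsweetened_counterpart_id = NA_character_, provenance = "test"))
  recipes <- tibble::tibble(
    composite_id = "loaf",
    ingredient_id = c("flour", "water2", "sucrose"),
    raw_weight_g = c(600, 350, 50))
  meta <- tibble::tibble(composite_id = "loaf", batch_post_weight_g = 800)
  db <- food_db(foods, recipes, meta)
  expect_equal(resolve_profile(db, "loaf")$total_sugars_g, 7.375)

  # halving the post-weight doubles every per-100 g concentration
  meta2 <- tibble::tibble(composite_id = "loaf", batch_post_weight_g = 400)
  db2 <- food_db(foods, recipes, meta2)
  expect_equal(resolve_profile(db2, "loaf")$total_sugars_g, 2 * 7.375)
})

test_that("flattening expands nested recipes to composed leaf proportions", {
  db <- nested_db()
  fl <- flatten_to_singles(db, "remoulade")
  expect_setequal(fl$single_id,
                  c("oil", "vinegar", "eggyolk", "pickles", "parsley"))
  # mayonnaise contributes 160 g of its 200 g batch: oil share 150/200
  expect_equal(fl$grams_per_100g[fl$single_id == "oil"],
               160 / 200 * 150 / 200 * 100)
  # leaf contributions conserve mass (all post-weights default to pre-weights)
  expect_equal(sum(fl$grams_per_100g), 100)

  one <- flatten_to_singles(db, "oil")
  expect_equal(one, tibble::tibble(single_id = "oil", grams_per_100g = 100))
})

test_that("flatten-then-sum reproduces recursive resolution on random DAGs", {
  for (seed in 1:30) {
    synth <- generate_food_db(
      small_config(seed = seed, n_single = 8, n_composite = 6,
                   max_dag_depth = 4))
    prof <- resolve_profiles(synth$db)
    comps <- synth$db$foods$item_id[synth$db$foods$kind == "composite"]
    singles <- prof[match(synth$db$foods$item_id[synth$db$foods$kind == "single"],
                          prof$item_id), ]
    for (id in comps) {
      fl <- flatten_to_singles(synth$db, id)
      leaf <- singles[match(fl$single_id, singles$item_id), ]
      oracle <- sum(fl$grams_per_100g * leaf$total_sugars_g / 100)
      expect_lt(abs(oracle - prof$total_sugars_g[prof$item_id == id]), 1e-9)
      oracle_e <- sum(fl$grams_per_100g * leaf$energy_kJ / 100)
      expect_lt(abs(oracle_e - prof$energy_kJ[prof$item_id == id]), 1e-6)
    }
  }
})

test_that("raising an ingredient's sugars never lowers the composite's", {
  synth <- generate_food_db(small_config(seed = 3, n_single = 10,
                                         n_composite = 5))
  db <- synth$db
  prof0 <- resolve_profiles(db)
  target <- db$foods$item_id[db$foods$kind == "single" &
                               db$foods$total_sugars_g < 90][1]
  i <- match(target, db$foods$item_id)
  db$foods$disaccharides_g[i] <- db$foods$disaccharides_g[i] + 5
  db$foods$total_sugars_g[i] <- db$foods$total_sugars_g[i] + 5
  prof1 <- resolve_profiles(db)
  expect_true(all(prof1$total_sugars_g >= prof0$total_sugars_g - 1e-12))
})
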