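#' Topological resolution order over the recipe DAG
#'
#' Composite foods reference ingredients that may themselves be composite, so
#' nutrient resolution must proceed bottom-up: every ingredient before every
#' composite that uses it. Ties are broken by lexicographic `item_id` order so
#' the result is deterministic.
#'
#' @param db A validated `food_db`.
#' @return Character vector of all item ids in resolution order.
#' @export
topological_order <- function(db) {
  ids <- sort(db$foods$item_id)
  edges <- db$recipes[, c("ingredient_id", "composite_id")]
  indeg <- stats::setNames(integer(length(ids)), ids)
  tab <- table(edges$composite_id)
  indeg[names(tab)] <- as.integer(tab)
  out_edges <- split(edges$composite_id, edges$ingredient_id)

  order <- character(0)
  ready <- sort(ids[indeg == 0L])
  while (length(ready) > 0) {
    nxt <- ready[[1]]
    ready <- ready[-1]
    order <- c(order, nxt)
    for (succ in out_edges[[nxt]] %||% character(0)) {
      indeg[[succ]] <- indeg[[succ]] - 1L
      if (indeg[[succ]] == 0L) ready <- sort(c(ready, succ))
    }
  }
  if (length(order) < length(ids)) {
    cyc <- setdiff(ids, order)
    abort(paste0("recipe graph contains a cycle involving: ",
                 paste(cyc, collapse = ", ")))
  }
  order
}

# Post-cooking batch weight for one composite; defaults to the raw sum.
batch_post_weight <- function(db, composite_id) {
  meta <- db$recipe_meta
  hit <- meta$batch_post_weight_g[meta$composite_id == composite_id]
  if (length(hit) == 1 && !is.na(hit)) {
    if (hit <= 0) abort(paste0(composite_id, ": batch_post_weight_g must be > 0"))
    return(hit)
  }
  comps <- db$recipes[db$recipes$composite_id == composite_id, ]
  sum(comps$raw_weight_g)
}

NUTRIENT_COLS <- c("monosaccharides_g", "disaccharides_g", "total_sugars_g",
                   "fructose_g", "energy_kJ")

#' Resolve nutrient profiles for all items
#'
#' Single items keep their stored per-100 g values. Composite items are
#' computed in topological order as the yield-adjusted weighted sum of their
#' ingredients: each per-100 g nutrient equals
#' `sum_i(raw_weight_i * nutrient_i / 100) / batch_post_weight * 100`, so
#' cooking losses (water only; sugars fully retained) act through the
#' post-cooking batch weight. Fructose of a composite is `NA` whenever any
#' ingredient lacks an analytical fructose value.
#'
#' @param db A validated `food_db`.
#' @return Tibble `item_id` plus per-100 g nutrient columns for every item.
#' @export
resolve_profiles <- function(db) {
  ord <- topological_order(db)
  foods <- db$foods
  prof <- as.data.frame(foods[match(ord, foods$item_id),
                              c("item_id", NUTRIENT_COLS)])
  rownames(prof) <- prof$item_id
  recipes <- split(db$recipes, db$recipes$composite_id)
  is_comp <- stats::setNames(foods$kind == "composite", foods$item_id)

  for (id in ord) {
    if (!is_comp[[id]]) next
    rc <- recipes[[id]]
    post <- batch_post_weight(db, id)
    ing <- prof[rc$ingredient_id, NUTRIENT_COLS, drop = FALSE]
    w <- rc$raw_weight_g
    vals <- colSums(as.matrix(ing) * w) / 100 / post * 100
    stopifnot(all(vals >= -1e-9, na.rm = TRUE))
    prof[id, NUTRIENT_COLS] <- as.list(vals)
  }
  out <- as_tibble(prof)
  out[match(foods$item_id, out$item_id), ]
}

#' Resolve one composite item's nutrient profile
#'
#' @param db A validated `food_db`.
#' @param composite_id Item id (single items are returned as stored).
#' @return One-row tibble of per-100 g nutrients of the finished (post-yield)
#'   food.
#' @export
resolve_profile <- function(db, composite_id) {
  if (!composite_id %in% db$foods$item_id) {
    abort(paste0("unknown item id: ", composite_id))
  }
  prof <- resolve_profiles(db)
  prof[prof$item_id == composite_id, ]
}

#' Flatten a composite food to its single-item leaves
#'
#' Fully expands nested recipes: the result maps each single (leaf) item to
#' the effective grams it contributes per 100 g of the finished composite.
#' Summing each leaf's per-100 g nutrients weighted by these gram
#' contributions reproduces [resolve_profile()]; the package's tests use this
#' as an independent oracle for the recursive resolution.
#'
#' @param db A validated `food_db`.
#' @param composite_id Item id; for a single item the mapping is itself at
#'   100 g.
#' @return Tibble `single_id, grams_per_100g`, sorted by `single_id`.
#' @export
flatten_to_singles <- function(db, composite_id) {
  foods <- db$foods
  if (!composite_id %in% foods$item_id) {
    abort(paste0("unknown item id: ", composite_id))
  }
  recipes <- split(db$recipes, db$recipes$composite_id)
  kind <- stats::setNames(foods$kind, foods$item_id)
  memo <- new.env(parent = emptyenv())

  expand <- function(id, path) {
    if (id %in% path) {
      abort(paste0("recipe graph contains a cycle involving: ",
                   paste(c(path, id), collapse = " -> ")))
    }
    if (kind[[id]] == "single") return(c(stats::setNames(100, id)))
    if (!is.null(memo[[id]])) return(memo[[id]])
    rc <- recipes[[id]]
    post <- batch_post_weight(db, id)
    acc <- numeric(0)
    for (k in seq_len(nrow(rc))) {
      sub <- expand(rc$ingredient_id[[k]], c(path, id))
      contrib <- sub * rc$raw_weight_g[[k]] / post
      for (nm in names(contrib)) {
        cur <- if (nm %in% names(acc)) acc[[nm]] else 0
        acc[[nm]] <- cur + contrib[[nm]]
      }
    }
    memo[[id]] <- acc
    acc
  }
  g <- expand(composite_id, character(0))
  g <- g[order(names(g))]
  tibble(single_id = names(g), grams_per_100g = unname(g))
}
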