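# Classification scheme: food groups, healthiness tiers, unhealthy subgroups.
#
# The scheme fixes the taxonomy every other module validates against:
# six top-level food groups (the five core Australian Dietary Guidelines
# groups plus "Unhealthy Foods" for discretionary items), three healthiness
# tiers, and a configurable inventory of unhealthy-food subgroups (13 in the
# default scheme, drawn from the Australian Health Survey discretionary
# classification).

#' Food group, tier and subgroup constants
#'
#' Canonical keys and display labels for the six food groups and the three
#' healthiness tiers. The five core groups carry "at least" guideline targets;
#' Unhealthy Foods carries an "at most" (upper-limit) target and is disjoint
#' from the five: a food contributes either to the five food groups or to
#' Unhealthy Foods, never both.
#'
#' @format `food_groups()` and `healthiness_tiers()` return named character
#'   vectors mapping snake-case keys to display labels.
#' @examples
#' food_groups()
#' healthiness_tiers()
#' @export
food_groups <- function() {
  c(
    fruit           = "Fruit",
    vegetables      = "Vegetables",
    breads_cereals  = "Breads and Cereals",
    meat_fish_eggs  = "Meat, Fish and Eggs",
    dairy           = "Dairy",
    unhealthy_foods = "Unhealthy Foods"
  )
}

#' @rdname food_groups
#' @export
five_food_groups <- function() {
  fg <- food_groups()
  fg[setdiff(names(fg), "unhealthy_foods")]
}

#' @rdname food_groups
#' @export
healthiness_tiers <- function() {
  c(
    best_choice         = "Best Choice",
    less_healthy_choice = "Less Healthy Choice",
    unhealthy_foods     = "Unhealthy Foods"
  )
}

# serve-factor column stems, in group order (no unhealthy column: discretionary
# serves are energy-defined, not factor-defined)
serve_factor_cols <- function() {
  c(
    fruit          = "serves_fruit_per_100g",
    vegetables     = "serves_veg_per_100g",
    breads_cereals = "serves_grains_per_100g",
    meat_fish_eggs = "serves_meat_per_100g",
    dairy          = "serves_dairy_per_100g"
  )
}

#' The default classification scheme
#'
#' Returns the packaged scheme: 6 food groups, 3 healthiness tiers and 13
#' unhealthy-food subgroups. The subgroup inventory follows the Australian
#' Health Survey discretionary classification and is replaceable configuration:
#' supply your own scheme (same shape) to [read_reference()] to reclassify.
#'
#' @return A list of class `food_scheme` with elements `groups`, `tiers`,
#'   `subgroups` (tibble of `subgroup_id`, `label`).
#' @examples
#' sch <- default_scheme()
#' nrow(sch$subgroups) # 13
#' @export
default_scheme <- function() {
  subgroups <- tibble(
    subgroup_id = c(
      "sugar_sweetened_beverages", "energy_drinks_cordials", "confectionery",
      "sweet_biscuits", "cakes_muffins_desserts", "savoury_pastries_pies",
      "savoury_snacks", "processed_meats", "takeaway_foods",
      "fried_potato_products", "ice_cream_frozen_desserts",
      "table_sugar_sweeteners", "sauces_spreads_condiments"
    ),
    label = c(
      "Sugar-sweetened beverages", "Energy drinks and cordials",
      "Confectionery", "Sweet biscuits", "Cakes, muffins and desserts",
      "Savoury pastries and pies", "Savoury snacks", "Processed meats",
      "Takeaway foods", "Fried potato products",
      "Ice cream and frozen desserts", "Table sugar and sweeteners",
      "Sauces, spreads and condiments"
    )
  )
  structure(
    list(groups = food_groups(), tiers = healthiness_tiers(), subgroups = subgroups),
    class = "food_scheme"
  )
}

#' Read or write a classification scheme as JSON
#'
#' @param path file path of the JSON scheme document.
#' @return `read_scheme()` returns a `food_scheme`; `write_scheme()` returns
#'   `path` invisibly.
#' @export
read_scheme <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (field in c("groups", "tiers", "subgroups")) {
    if (is.null(doc[[field]])) {
      abort(glue::glue("scheme document is missing '{field}'"), class = "s2s_schema_error")
    }
  }
  sch <- structure(
    list(
      groups = unlist(doc$groups),
      tiers = unlist(doc$tiers),
      subgroups = as_tibble(doc$subgroups)
    ),
    class = "food_scheme"
  )
  validate_scheme(sch)
}

#' @rdname read_scheme
#' @param scheme a `food_scheme`.
#' @export
write_scheme <- function(scheme, path) {
  validate_scheme(scheme)
  jsonlite::write_json(
    list(
      groups = as.list(scheme$groups),
      tiers = as.list(scheme$tiers),
      subgroups = scheme$subgroups
    ),
    path,
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

validate_scheme <- function(scheme) {
  if (!"unhealthy_foods" %in% names(scheme$groups)) {
    abort("scheme must contain an 'unhealthy_foods' group", class = "s2s_schema_error")
  }
  if (anyDuplicated(scheme$subgroups$subgroup_id)) {
    abort("duplicate subgroup_id in scheme", class = "s2s_schema_error")
  }
  scheme
}

#' @export
print.food_scheme <- function(x, ...) {
  cat("<food_scheme>\n")
  cat("  groups:   ", paste(unname(x$groups), collapse = "; "), "\n")
  cat("  tiers:    ", paste(unname(x$tiers), collapse = "; "), "\n")
  cat("  subgroups:", nrow(x$subgroups), "unhealthy-food subgroups\n")
  invisible(x)
}
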