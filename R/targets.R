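# Population-weighted dietary guideline targets.
#
# Guideline recommendations are per age/sex stratum; store-level reporting
# needs a single per-person-per-day target per food group. The target is the
# population-proportion-weighted mean of per-stratum recommended serves,
# rounded to the nearest 0.5 serves, and the reference energy requirement is
# the weighted mean of per-stratum EERs rounded to the nearest 100 kJ. For
# Unhealthy Foods the per-stratum value supplied must be the *upper limit* of
# the discretionary recommendation, and the resulting target is an at-most
# bound; the five food groups carry at-least bounds.

#' Round serves to the nearest half serve
#'
#' Midpoints round up: 2.25 -> 2.5.
#'
#' @param x non-negative serves.
#' @return Nearest multiple of 0.5.
#' @examples
#' round_to_half(c(2.24, 2.25, 5.3))
#' @export
round_to_half <- function(x) {
  floor(2 * x + 0.5) / 2
}

#' Read a demographic strata table
#'
#' @param path CSV with columns `stratum_id`, `weight`, `serves_fruit`,
#'   `serves_veg`, `serves_grains`, `serves_meat`, `serves_dairy`,
#'   `serves_discretionary_upper`, `eer_kj`. Weights are population
#'   proportions and must sum to 1 (+/- 1e-9); `serves_discretionary_upper`
#'   is the upper limit of the discretionary recommendation.
#' @return Validated tibble.
#' @export
read_strata <- function(path) {
  if (!file.exists(path)) {
    abort(glue::glue("strata file not found: {path}"), class = "s2s_missing_input")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_strata(df)
}

strata_serve_cols <- function() {
  c(fruit = "serves_fruit", vegetables = "serves_veg",
    breads_cereals = "serves_grains", meat_fish_eggs = "serves_meat",
    dairy = "serves_dairy", unhealthy_foods = "serves_discretionary_upper")
}

validate_strata <- function(df) {
  df <- as_tibble(df)
  need <- c("stratum_id", "weight", unname(strata_serve_cols()), "eer_kj")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(glue::glue("strata table is missing column(s): {paste(missing, collapse = ', ')}"),
          class = "s2s_schema_error")
  }
  if (abs(sum(df$weight) - 1) > 1e-9) {
    abort(glue::glue("stratum weights must sum to 1 (got {sum(df$weight)})"),
          class = "s2s_input_error")
  }
  if (any(df$eer_kj <= 0) || any(as.matrix(df[unname(strata_serve_cols())]) < 0)) {
    abort("strata recommendations must be >= 0 and EERs > 0", class = "s2s_input_error")
  }
  df
}

#' Population-weighted target for one food group
#'
#' `round_to_half(sum(weight * recommended_serves))` over strata. The
#' unrounded weighted mean is a convex combination of the per-stratum
#' recommendations, so it always lies within their range, and rounding moves
#' it by at most 0.25 serves.
#'
#' @param strata tibble from [read_strata()].
#' @param group food-group key (see [food_groups()]).
#' @return Target in serves/person/day (a multiple of 0.5).
#' @export
weighted_target <- function(strata, group) {
  strata <- validate_strata(strata)
  col <- strata_serve_cols()[group]
  if (is.na(col)) abort(glue::glue("unknown food group '{group}'"), class = "s2s_input_error")
  col <- unname(col)
  round_to_half(sum(strata$weight * strata[[col]]))
}

#' Population-weighted estimated energy requirement
#'
#' Weighted mean of per-stratum EERs, rounded to the nearest 100 kJ (so a
#' value of 8.9 MJ/person/day is representable exactly).
#'
#' @inheritParams weighted_target
#' @return kJ/person/day.
#' @export
weighted_eer <- function(strata) {
  strata <- validate_strata(strata)
  floor(sum(strata$weight * strata$eer_kj) / 100 + 0.5) * 100
}

new_target_set <- function(targets, reference_energy) {
  structure(targets, class = c("target_set", class(tibble())),
            reference_energy = reference_energy)
}

#' Derive a full target set from demographic strata
#'
#' @inheritParams weighted_target
#' @return A `target_set`: tibble `group`, `group_label`, `target`
#'   (serves/person/day), `direction` (`"at_least"` for the five food groups,
#'   `"at_most"` for Unhealthy Foods), with attribute `reference_energy`.
#' @export
derive_targets <- function(strata) {
  strata <- validate_strata(strata)
  groups <- names(food_groups())
  new_target_set(
    tibble(
      group = groups,
      group_label = unname(food_groups()[groups]),
      target = unname(vapply(groups, function(g) weighted_target(strata, g), double(1))),
      direction = if_else(groups == "unhealthy_foods", "at_most", "at_least")
    ),
    reference_energy = weighted_eer(strata)
  )
}

#' The packaged default guideline targets
#'
#' The authoritative defaults for remote-community store reporting, weighted
#' to the population profile of very remote Indigenous Australian communities
#' (2011 Census) and rounded to the nearest 0.5 serves: Fruit >= 2,
#' Vegetables >= 5, Breads and Cereals >= 5.5, Meat, Fish and Eggs >= 2.5,
#' Dairy >= 2.5 serves/person/day, and Unhealthy Foods <= 2.5 serves/person/day
#' (an upper limit: the discretionary target uses the upper bound of the
#' recommendation range). Reference energy 8 900 kJ/person/day.
#'
#' @return A `target_set` (see [derive_targets()]).
#' @examples
#' default_targets()
#' @export
default_targets <- function() {
  new_target_set(
    tibble(
      group = names(food_groups()),
      group_label = unname(food_groups()),
      target = c(2, 5, 5.5, 2.5, 2.5, 2.5),
      direction = c(rep("at_least", 5), "at_most")
    ),
    reference_energy = 8900
  )
}

#' Read / write a target set as JSON
#'
#' @param path JSON path.
#' @export
read_targets <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  tg <- as_tibble(doc$targets)
  if (!all(c("group", "target", "direction") %in% names(tg))) {
    abort("target JSON needs fields group, target, direction", class = "s2s_schema_error")
  }
  if (!"group_label" %in% names(tg)) tg$group_label <- unname(food_groups()[tg$group])
  new_target_set(tg[c("group", "group_label", "target", "direction")],
                 reference_energy = doc$reference_energy %||% 8900)
}

#' @rdname read_targets
#' @param targets a `target_set`.
#' @export
write_targets <- function(targets, path) {
  jsonlite::write_json(
    list(reference_energy = attr(targets, "reference_energy"),
         targets = as_tibble(targets)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @export
print.target_set <- function(x, ...) {
  cat("<target_set> reference energy ", attr(x, "reference_energy"),
      " kJ/person/day\n", sep = "")
  NextMethod()
}
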