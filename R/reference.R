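# Food reference table: load, validate, classify.
#
# The reference is a flat, pre-joined extract of the national food-composition
# sources a practitioner would use (AUSNUT energy densities, Australian
# Dietary Guidelines serve factors, the ABS Discretionary Food List flag).
# One row per food code. Validation enforces the rules that make the
# indicators meaningful, in particular the discretionary-exclusion rule:
# a discretionary food must carry zero five-food-group serve factors, so that
# e.g. the potato in deep-fried hot chips can never count toward Vegetables.

reference_cols <- function() {
  c("food_code", "description", "energy_density_kj_per_100g",
    unname(serve_factor_cols()),
    "is_discretionary", "unhealthy_subgroup", "tier", "is_alcohol")
}

#' Read and validate a food reference table
#'
#' Reads a CSV reference table (one row per food code), validates every row
#' against the classification invariants, and returns the valid records as a
#' `food_reference` tibble. Invalid rows are rejected -- never silently kept --
#' and reported row-by-row in `attr(, "rejected")`.
#'
#' Validation rules:
#' * `energy_density_kj_per_100g >= 0`, all serve factors `>= 0` (`range` rule);
#' * `food_code` unique (`uniqueness` rule);
#' * a discretionary record has all five-food-group serve factors equal to
#'   zero (`discretionary-exclusion` rule);
#' * `tier == "Unhealthy Foods"` exactly when `is_discretionary` (`tier-consistency`);
#' * a subgroup id implies `is_discretionary` and must exist in the scheme
#'   (`subgroup-consistency`).
#'
#' Beverages are tabulated per 100 mL with millilitres carried in the gram
#' fields (density 1.0 assumed).
#'
#' @param path CSV file with columns `food_code`, `description`,
#'   `energy_density_kj_per_100g`, `serves_fruit_per_100g`,
#'   `serves_veg_per_100g`, `serves_grains_per_100g`, `serves_meat_per_100g`,
#'   `serves_dairy_per_100g`, `is_discretionary`, `unhealthy_subgroup`,
#'   `tier`, `is_alcohol`.
#' @param scheme a `food_scheme`; defaults to [default_scheme()].
#' @return A tibble of class `food_reference` with one row per valid food,
#'   attributes `rejected` (tibble: `row`, `food_code`, `rule`, `message`),
#'   `n_loaded`, `n_rejected`, and `scheme`.
#' @seealso [classify_foods()], [write_reference()]
#' @export
read_reference <- function(path, scheme = default_scheme()) {
  if (!file.exists(path)) {
    abort(glue::glue("reference file not found: {path}"), class = "s2s_missing_input")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(reference_cols(), names(raw))
  if (length(missing) > 0) {
    abort(
      glue::glue("reference table is missing mandatory column(s): {paste(missing, collapse = ', ')}"),
      class = "s2s_schema_error"
    )
  }
  raw <- raw %>%
    mutate(
      food_code = as.character(.data$food_code),
      unhealthy_subgroup = as.character(.data$unhealthy_subgroup),
      is_discretionary = as.logical(.data$is_discretionary),
      is_alcohol = as.logical(.data$is_alcohol)
    )
  validate_reference(raw, scheme)
}

#' Validate an in-memory reference table
#'
#' @param df data frame shaped like the reference CSV.
#' @inheritParams read_reference
#' @return Same as [read_reference()].
#' @export
validate_reference <- function(df, scheme = default_scheme()) {
  df <- as_tibble(df)
  sf_cols <- unname(serve_factor_cols())
  reject <- list()
  flag <- function(rows, rule, message) {
    if (length(rows) == 0) return()
    reject[[length(reject) + 1]] <<- tibble(
      row = rows,
      food_code = df$food_code[rows],
      rule = rule,
      message = message
    )
  }

  dup <- which(duplicated(df$food_code) | duplicated(df$food_code, fromLast = TRUE))
  flag(dup, "uniqueness", "duplicate food_code")

  bad_energy <- which(is.na(df$energy_density_kj_per_100g) | df$energy_density_kj_per_100g < 0)
  flag(bad_energy, "range", "energy_density_kj_per_100g must be >= 0")

  sf_mat <- as.matrix(df[sf_cols])
  bad_sf <- which(apply(sf_mat, 1, function(x) any(is.na(x) | x < 0)))
  flag(bad_sf, "range", "serve factors must be >= 0")

  disc_with_serves <- which(df$is_discretionary & apply(sf_mat, 1, function(x) any(x > 0, na.rm = TRUE)))
  flag(disc_with_serves, "discretionary-exclusion",
       "discretionary foods may not carry five-food-group serve factors")

  tier_bad <- which(
    (df$is_discretionary & df$tier != healthiness_tiers()[["unhealthy_foods"]]) |
      (!df$is_discretionary & df$tier == healthiness_tiers()[["unhealthy_foods"]]) |
      !(df$tier %in% unname(healthiness_tiers()))
  )
  flag(tier_bad, "tier-consistency",
       'tier must be "Unhealthy Foods" exactly for discretionary foods')

  has_sub <- !is.na(df$unhealthy_subgroup) & df$unhealthy_subgroup != ""
  sub_bad <- which(has_sub & (!df$is_discretionary |
                                !(df$unhealthy_subgroup %in% scheme$subgroups$subgroup_id)))
  flag(sub_bad, "subgroup-consistency",
       "unhealthy_subgroup must name a scheme subgroup and implies is_discretionary")

  rejected <- if (length(reject) > 0) {
    bind_rows(reject) %>% arrange(.data$row)
  } else {
    tibble(row = integer(), food_code = character(), rule = character(), message = character())
  }
  bad_rows <- unique(rejected$row)
  ok <- df[setdiff(seq_len(nrow(df)), bad_rows), , drop = FALSE]
  ok$unhealthy_subgroup[!is.na(ok$unhealthy_subgroup) & ok$unhealthy_subgroup == ""] <- NA_character_

  if (nrow(rejected) > 0) {
    warn(glue::glue("{length(bad_rows)} reference row(s) rejected; see attr(, 'rejected')"))
  }
  structure(
    ok,
    class = c("food_reference", class(tibble())),
    rejected = rejected,
    n_loaded = nrow(ok),
    n_rejected = length(bad_rows),
    scheme = scheme
  )
}

#' Write a reference table back to CSV
#'
#' Writes in the same dialect [read_reference()] consumes, so a load/write/load
#' round trip yields identical records.
#'
#' @param reference a `food_reference`.
#' @param path output CSV path.
#' @export
write_reference <- function(reference, path) {
  readr::write_csv(as_tibble(reference)[reference_cols()], path, progress = FALSE)
  invisible(path)
}

#' Classify foods into group, tier and subgroup
#'
#' Deterministically assigns each food its primary food group, healthiness
#' tier and (for discretionary foods) unhealthy subgroup. Discretionary foods
#' map to Unhealthy Foods. A five-food-group food maps to the group with the
#' largest serve factor; ties break alphabetically by group label. A mixed
#' dish still contributes serves to *all* its groups in the indicators -- the
#' primary group only drives report grouping and dollar shares.
#'
#' A non-discretionary food with all-zero serve factors is unclassifiable:
#' it gets `group = NA` and is reported, not fatal.
#'
#' @param reference a `food_reference`.
#' @return Tibble with `food_code`, `group` (key), `group_label`, `tier`,
#'   `unhealthy_subgroup`, `unclassifiable` (logical).
#' @examples
#' fx <- generate_reference_fixture()
#' classify_foods(fx$reference)
#' @export
classify_foods <- function(reference) {
  sfc <- serve_factor_cols()
  sf_mat <- as.matrix(as_tibble(reference)[unname(sfc)])
  group_keys <- names(sfc)
  labels <- five_food_groups()

  primary <- vapply(seq_len(nrow(sf_mat)), function(i) {
    x <- sf_mat[i, ]
    if (all(x <= 0)) return(NA_character_)
    cand <- group_keys[x == max(x)]
    # alphabetical by display label on ties
    cand[order(labels[cand])][1]
  }, character(1))

  tibble(
    food_code = reference$food_code,
    group = if_else(reference$is_discretionary, "unhealthy_foods", primary),
    tier = reference$tier,
    unhealthy_subgroup = reference$unhealthy_subgroup
  ) %>%
    mutate(
      group_label = unname(food_groups()[.data$group]),
      unclassifiable = is.na(.data$group),
      .after = "group"
    ) %>%
    select("food_code", "group", "group_label", "tier", "unhealthy_subgroup", "unclassifiable")
}

#' @export
print.food_reference <- function(x, ...) {
  cat("<food_reference> ", attr(x, "n_loaded"), " foods loaded, ",
      attr(x, "n_rejected"), " rejected\n", sep = "")
  NextMethod()
}
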