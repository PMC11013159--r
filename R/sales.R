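# Point-of-sale ingest: read weekly sales, link to the food reference,
# quantify grams / kilojoules / serves per record.

#' Read weekly point-of-sale records
#'
#' Reads a sales CSV (one row per store x week x product), validates rows and
#' merges duplicates. Rows with unparseable dates or missing fields are
#' rejected with row-level diagnostics; rows with negative `units_sold` or
#' `dollar_value` (returns/refunds) are quarantined rather than netted, unless
#' `net_refunds = TRUE`, in which case they are kept and subtract during the
#' duplicate merge. Duplicate (store, week, product) rows are summed with a
#' warning.
#'
#' @param path CSV with columns `store_id`, `week_start` (ISO-8601 date),
#'   `product_id`, `units_sold`, `dollar_value`.
#' @param net_refunds keep negative-quantity rows and net them against sales
#'   (default `FALSE`: quarantine).
#' @return Tibble of validated sales with attributes `rejected` (tibble with
#'   `row`, `rule`, `message`), `quarantined` (the refund rows), and
#'   `n_merged` (count of duplicate rows folded in).
#' @export
read_sales <- function(path, net_refunds = FALSE) {
  if (!file.exists(path)) {
    abort(glue::glue("sales file not found: {path}"), class = "s2s_missing_input")
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      store_id = readr::col_character(),
      week_start = readr::col_character(),
      product_id = readr::col_character(),
      units_sold = readr::col_double(),
      dollar_value = readr::col_double()
    ),
    progress = FALSE
  )
  missing <- setdiff(c("store_id", "week_start", "product_id", "units_sold", "dollar_value"),
                     names(raw))
  if (length(missing) > 0) {
    abort(
      glue::glue("sales table is missing mandatory column(s): {paste(missing, collapse = ', ')}"),
      class = "s2s_schema_error"
    )
  }

  week <- suppressWarnings(lubridate::ymd(raw$week_start))
  bad_date <- which(is.na(week))
  bad_field <- which(is.na(raw$units_sold) | is.na(raw$dollar_value) |
                       is.na(raw$store_id) | is.na(raw$product_id))
  rejected <- bind_rows(
    tibble(row = bad_date, rule = "date", message = "unparseable week_start"),
    tibble(row = setdiff(bad_field, bad_date), rule = "missing-field",
           message = "missing store/product/units/dollars")
  ) %>% arrange(.data$row)

  ok <- raw %>%
    mutate(week_start = week, .row = row_number()) %>%
    filter(!(.data$.row %in% rejected$row)) %>%
    select(-".row")

  negative <- ok %>% filter(.data$units_sold < 0 | .data$dollar_value < 0)
  if (!net_refunds) {
    ok <- ok %>% filter(.data$units_sold >= 0 & .data$dollar_value >= 0)
  }

  n_before <- nrow(ok)
  ok <- ok %>%
    group_by(.data$store_id, .data$week_start, .data$product_id) %>%
    summarise(
      units_sold = sum(.data$units_sold),
      dollar_value = sum(.data$dollar_value),
      .groups = "drop"
    )
  n_merged <- n_before - nrow(ok)
  if (n_merged > 0) {
    warn(glue::glue("{n_merged} duplicate (store, week, product) row(s) merged by summation"))
  }
  if (nrow(rejected) > 0) {
    warn(glue::glue("{nrow(rejected)} malformed sales row(s) rejected; see attr(, 'rejected')"))
  }

  structure(
    ok,
    rejected = rejected,
    quarantined = if (net_refunds) negative[0, ] else negative,
    n_merged = n_merged
  )
}

#' Read a product catalogue
#'
#' The catalogue maps till product identifiers to a reference food code and a
#' pack size (grams, or millilitres for beverages, per unit sold). Non-food
#' products carry an empty `food_code`.
#'
#' @param path CSV with columns `product_id`, `description`, `pack_size_g`,
#'   `food_code`.
#' @return Validated tibble; rows violating `pack_size_g > 0` for food-linked
#'   products are rejected with diagnostics in `attr(, "rejected")`.
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) {
    abort(glue::glue("catalogue file not found: {path}"), class = "s2s_missing_input")
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      product_id = readr::col_character(),
      description = readr::col_character(),
      pack_size_g = readr::col_double(),
      food_code = readr::col_character()
    ),
    progress = FALSE
  )
  missing <- setdiff(c("product_id", "description", "pack_size_g", "food_code"), names(raw))
  if (length(missing) > 0) {
    abort(
      glue::glue("catalogue is missing mandatory column(s): {paste(missing, collapse = ', ')}"),
      class = "s2s_schema_error"
    )
  }
  has_food <- !is.na(raw$food_code) & raw$food_code != ""
  bad <- which(has_food & (is.na(raw$pack_size_g) | raw$pack_size_g <= 0))
  dup <- which(duplicated(raw$product_id) | duplicated(raw$product_id, fromLast = TRUE))
  rejected <- bind_rows(
    tibble(row = bad, rule = "range", message = "pack_size_g must be > 0 for food products"),
    tibble(row = dup, rule = "uniqueness", message = "duplicate product_id")
  ) %>% arrange(.data$row)
  ok <- raw[setdiff(seq_len(nrow(raw)), unique(rejected$row)), , drop = FALSE]
  ok$food_code[!is.na(ok$food_code) & ok$food_code == ""] <- NA_character_
  if (nrow(rejected) > 0) {
    warn(glue::glue("{length(unique(rejected$row))} catalogue row(s) rejected"))
  }
  structure(ok, rejected = rejected)
}

#' Link sales to the food reference and quantify
#'
#' Joins sales to the catalogue and reference, converting each sale to grams,
#' kilojoules and per-food-group serves. Sales that cannot be linked (unknown
#' product, non-food product, food code absent from the reference) and sales
#' of alcohol-flagged foods are excluded from the quantified output and
#' tallied in the linkage report; they are never fatal. Alcohol is removed
#' wholesale: it contributes to neither serve numerators nor the energy
#' denominator.
#'
#' Per linked record: `grams_sold = units_sold * pack_size_g`,
#' `energy_kj = grams_sold * energy_density / 100`, five-food-group serves
#' `grams_sold * serve_factor / 100` (zero for discretionary foods, which are
#' excluded from the five-group indicators by construction).
#'
#' @param sales tibble from [read_sales()].
#' @param catalog tibble from [read_catalog()].
#' @param reference a `food_reference` from [read_reference()].
#' @return Tibble of quantified sales (`store_id`, `week_start`, `product_id`,
#'   `food_code`, `units_sold`, `grams_sold`, `energy_kj`, `dollars`,
#'   `serves_*`, `is_discretionary`, `unhealthy_subgroup`, `tier`, `group`)
#'   with attribute `linkage`, a one-row tibble: `n_input`, `n_linked`,
#'   `n_unlinked_product`, `n_nonfood`, `n_unknown_food_code`, `n_alcohol`,
#'   `alcohol_energy_kj`.
#' @examples
#' fx <- generate_reference_fixture()
#' sales <- generate_sales(scenario_spec(n_stores = 1, n_weeks = 2, seed = 1), fx)
#' q <- link_sales(sales, fx$catalog, fx$reference)
#' attr(q, "linkage")
#' @export
link_sales <- function(sales, catalog, reference) {
  sfc <- serve_factor_cols()
  ref <- as_tibble(reference)

  joined <- as_tibble(sales) %>%
    left_join(select(as_tibble(catalog), "product_id", "pack_size_g", "food_code"),
              by = "product_id") %>%
    mutate(in_catalog = .data$product_id %in% catalog$product_id) %>%
    left_join(ref, by = "food_code", suffix = c("", ".ref")) %>%
    mutate(
      status = case_when(
        !.data$in_catalog ~ "unlinked_product",
        is.na(.data$food_code) ~ "nonfood",
        is.na(.data$energy_density_kj_per_100g) ~ "unknown_food_code",
        .data$is_alcohol ~ "alcohol",
        TRUE ~ "linked"
      )
    )

  classification <- classify_foods(reference) %>% select("food_code", "group")

  quantified <- joined %>%
    filter(.data$status == "linked") %>%
    mutate(
      grams_sold = .data$units_sold * .data$pack_size_g,
      energy_kj = .data$grams_sold * .data$energy_density_kj_per_100g / 100,
      dollars = .data$dollar_value
    ) %>%
    left_join(classification, by = "food_code")
  for (g in names(sfc)) {
    quantified[[paste0("serves_", g)]] <-
      quantified$grams_sold * quantified[[sfc[[g]]]] / 100
  }

  alcohol_energy <- joined %>%
    filter(.data$status == "alcohol") %>%
    summarise(e = sum(.data$units_sold * .data$pack_size_g *
                        .data$energy_density_kj_per_100g / 100)) %>%
    pull(.data$e)

  linkage <- tibble(
    n_input = nrow(joined),
    n_linked = sum(joined$status == "linked"),
    n_unlinked_product = sum(joined$status == "unlinked_product"),
    n_nonfood = sum(joined$status == "nonfood"),
    n_unknown_food_code = sum(joined$status == "unknown_food_code"),
    n_alcohol = sum(joined$status == "alcohol"),
    alcohol_energy_kj = if (length(alcohol_energy) == 1) alcohol_energy else 0
  )

  out <- quantified %>%
    select("store_id", "week_start", "product_id", "food_code", "group",
           "units_sold", "grams_sold", "energy_kj", "dollars",
           paste0("serves_", names(sfc)),
           "is_discretionary", "unhealthy_subgroup", "tier")
  structure(out, linkage = linkage)
}
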