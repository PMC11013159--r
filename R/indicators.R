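# Key dietary indicators: serves per person per day per food group, subgroup
# and healthiness tier, energy-normalised to the reference daily requirement.
#
# The indicator for key k in store s and period p is
#
#   serves_k(s, p) * E_ref / E(s, p)
#
# where serves_k is the raw serve count purchased, E the total energy (kJ) of
# classified, non-alcohol food purchased, and E_ref the reference estimated
# energy requirement (8 900 kJ/person/day by default). The ratio is invariant
# to uniform scaling of the basket, so stores of different sizes and periods
# of different lengths are directly comparable. Five-food-group serves come
# from gram-based serve factors over non-discretionary foods only;
# discretionary ("Unhealthy Foods") serves are energy-defined at a nominal
# 600 kJ per serve.

#' Period keys
#'
#' Assigns each week to a reporting period by its start date: a week belongs
#' wholly to the calendar month (or quarter) containing `week_start`.
#'
#' @param dates vector of week-start dates.
#' @param period_unit `"month"`, `"quarter"` or `"week"`.
#' @return Character period keys (`"2023-04"`, `"2023-Q2"`, `"2023-04-03"`).
#' @export
period_key <- function(dates, period_unit = c("month", "quarter", "week")) {
  period_unit <- match.arg(period_unit)
  switch(period_unit,
    month = format(dates, "%Y-%m"),
    quarter = paste0(lubridate::year(dates), "-Q", lubridate::quarter(dates)),
    week = format(dates, "%Y-%m-%d")
  )
}

period_start_of <- function(dates, period_unit) {
  switch(period_unit,
    month = lubridate::floor_date(dates, "month"),
    quarter = lubridate::floor_date(dates, "quarter"),
    week = dates
  )
}

#' Total classified food energy per store and period
#'
#' Sums `energy_kj` over quantified records whose food is classifiable
#' (alcohol and non-food never reach this stage; unclassifiable foods --
#' non-discretionary with all-zero serve factors -- are excluded from the
#' denominator as a documented choice). Periods with no sales report 0 kJ and
#' `no_sales = TRUE`.
#'
#' @param quantified tibble from [link_sales()].
#' @inheritParams period_key
#' @return Tibble `store_id`, `period`, `energy_kj`, `no_sales`.
#' @export
total_energy <- function(quantified, period_unit = c("month", "quarter", "week")) {
  period_unit <- match.arg(period_unit)
  as_tibble(quantified) %>%
    filter(!is.na(.data$group)) %>%
    mutate(period = period_key(.data$week_start, period_unit)) %>%
    group_by(.data$store_id, .data$period) %>%
    summarise(energy_kj = sum(.data$energy_kj), .groups = "drop") %>%
    mutate(no_sales = .data$energy_kj <= 0)
}

#' Raw serves by group, subgroup and tier
#'
#' Aggregates quantified sales into un-normalised serve counts: five-food-group
#' serves from serve factors over non-discretionary foods; Unhealthy Foods
#' serves as discretionary energy / `discretionary_serve_kj`; subgroup serves
#' likewise from each subgroup's energy; tier serves as the sum over member
#' foods (a mixed dish contributes all its group serves to its tier).
#'
#' @inheritParams total_energy
#' @param scheme a `food_scheme` fixing the indicator key set.
#' @param discretionary_serve_kj energy content of one discretionary serve
#'   (default 600 kJ, the Australian Dietary Guidelines' nominal serve).
#' @return Tibble `store_id`, `period`, `level` (group/subgroup/tier),
#'   `indicator`, `raw_serves`; every scheme key present for every
#'   store-period (zero-filled).
#' @export
serves_by_group <- function(quantified, period_unit = c("month", "quarter", "week"),
                            scheme = default_scheme(), discretionary_serve_kj = 600) {
  period_unit <- match.arg(period_unit)
  q <- as_tibble(quantified) %>%
    filter(!is.na(.data$group)) %>%
    mutate(period = period_key(.data$week_start, period_unit))
  if (nrow(q) == 0) {
    return(tibble(store_id = character(), period = character(),
                  level = character(), indicator = character(),
                  raw_serves = double()))
  }

  grp_cols <- paste0("serves_", names(five_food_groups()))
  five <- q %>%
    filter(!.data$is_discretionary) %>%
    group_by(.data$store_id, .data$period) %>%
    summarise(across(all_of(grp_cols), sum), .groups = "drop") %>%
    tidyr::pivot_longer(all_of(grp_cols), names_to = "indicator",
                        names_prefix = "serves_", values_to = "raw_serves") %>%
    mutate(level = "group")

  disc <- q %>% filter(.data$is_discretionary)
  unhealthy <- disc %>%
    group_by(.data$store_id, .data$period) %>%
    summarise(raw_serves = sum(.data$energy_kj) / discretionary_serve_kj, .groups = "drop") %>%
    mutate(level = "group", indicator = "unhealthy_foods")

  subgroups <- disc %>%
    filter(!is.na(.data$unhealthy_subgroup)) %>%
    group_by(.data$store_id, .data$period, indicator = .data$unhealthy_subgroup) %>%
    summarise(raw_serves = sum(.data$energy_kj) / discretionary_serve_kj, .groups = "drop") %>%
    mutate(level = "subgroup")

  tier_key <- setNames(names(healthiness_tiers()), unname(healthiness_tiers()))
  tiers <- q %>%
    mutate(
      tier_serves = if_else(
        .data$is_discretionary,
        .data$energy_kj / discretionary_serve_kj,
        rowSums(across(all_of(grp_cols)))
      ),
      indicator = unname(tier_key[.data$tier])
    ) %>%
    group_by(.data$store_id, .data$period, .data$indicator) %>%
    summarise(raw_serves = sum(.data$tier_serves), .groups = "drop") %>%
    mutate(level = "tier")

  keys <- bind_rows(
    tibble(level = "group", indicator = names(scheme$groups)),
    tibble(level = "subgroup", indicator = scheme$subgroups$subgroup_id),
    tibble(level = "tier", indicator = names(scheme$tiers))
  )
  bind_rows(five, unhealthy, subgroups, tiers) %>%
    tidyr::complete(
      tidyr::nesting(!!!rlang::syms(c("store_id", "period"))),
      keys,
      fill = list(raw_serves = 0)
    ) %>%
    select("store_id", "period", "level", "indicator", "raw_serves") %>%
    arrange(.data$store_id, .data$period, .data$level, .data$indicator)
}

#' Energy-normalise raw serves to serves per person per day
#'
#' `raw_serves * reference_energy / total_energy_kj`. When the period has no
#' energy the indicator is undefined and returned as `NA` (reports render
#' "no data"); division by zero never occurs.
#'
#' @param raw_serves numeric vector of raw serve counts.
#' @param total_energy_kj matching total classified energy (kJ).
#' @param reference_energy reference daily energy requirement in kJ
#'   (default 8 900 kJ = 8.9 MJ/person/day).
#' @return Numeric vector of serves/person/day.
#' @examples
#' normalize_to_person_day(4, 17800)  # 2 serves/person/day
#' @export
normalize_to_person_day <- function(raw_serves, total_energy_kj, reference_energy = 8900) {
  if_else(total_energy_kj > 0, raw_serves * reference_energy / total_energy_kj, NA_real_)
}

#' Compute the key dietary indicators
#'
#' The pipeline's central operation: aggregates quantified sales per store and
#' period, normalises to serves/person/day at the reference energy, and
#' returns a tidy `indicator_set`.
#'
#' @inheritParams serves_by_group
#' @param reference_energy reference daily energy requirement (kJ/person/day).
#' @return A tibble of class `indicator_set`: `store_id`, `period`,
#'   `period_start`, `level`, `indicator`, `value` (serves/person/day; `NA`
#'   when the period has no classified energy), `unit`. Attributes: `totals`
#'   (store x period energy, dollars, no-sales flag), `period_unit`,
#'   `reference_energy`, `discretionary_serve_kj`.
#' @examples
#' fx <- generate_reference_fixture()
#' spec <- scenario_spec(n_stores = 2, n_weeks = 8, seed = 7)
#' sales <- generate_sales(spec, fx)
#' ind <- link_sales(sales, fx$catalog, fx$reference) |> compute_indicators()
#' dplyr::filter(ind, level == "group")
#' @export
compute_indicators <- function(quantified, period_unit = c("month", "quarter", "week"),
                               reference_energy = 8900, discretionary_serve_kj = 600,
                               scheme = default_scheme()) {
  period_unit <- match.arg(period_unit)
  raw <- serves_by_group(quantified, period_unit, scheme, discretionary_serve_kj)
  energy <- total_energy(quantified, period_unit)
  dollars <- as_tibble(quantified) %>%
    filter(!is.na(.data$group)) %>%
    mutate(period = period_key(.data$week_start, period_unit)) %>%
    group_by(.data$store_id, .data$period) %>%
    summarise(dollars = sum(.data$dollars), .groups = "drop")
  totals <- energy %>% left_join(dollars, by = c("store_id", "period"))

  out <- raw %>%
    left_join(select(totals, "store_id", "period", "energy_kj"),
              by = c("store_id", "period")) %>%
    mutate(
      value = normalize_to_person_day(.data$raw_serves, .data$energy_kj, reference_energy),
      unit = "serves_per_person_day",
      period_start = period_start_from_key(.data$period, period_unit)
    ) %>%
    select("store_id", "period", "period_start", "level", "indicator", "value", "unit")

  structure(
    out,
    class = c("indicator_set", class(tibble())),
    totals = totals,
    period_unit = period_unit,
    reference_energy = reference_energy,
    discretionary_serve_kj = discretionary_serve_kj
  )
}

period_start_from_key <- function(period, period_unit) {
  switch(period_unit,
    month = lubridate::ymd(paste0(period, "-01")),
    quarter = {
      y <- as.integer(substr(period, 1, 4))
      q <- as.integer(substr(period, 7, 7))
      lubridate::make_date(y, (q - 1) * 3 + 1, 1)
    },
    week = lubridate::ymd(period)
  )
}

#' Share of discretionary energy covered by named subgroups
#'
#' The subgroup scheme names only the biggest contributors to discretionary
#' energy; this statistic reports what fraction of all discretionary energy
#' they jointly cover (1.0 when every discretionary food carries a subgroup).
#' Undefined (NA, flagged) when there is no discretionary energy.
#'
#' @inheritParams total_energy
#' @param by_store also return per-store fractions.
#' @return One-row tibble `covered_fraction`, `discretionary_energy_kj`,
#'   `undefined`; with `by_store = TRUE`, one row per store plus the pooled
#'   row (`store_id = "(pooled)"`).
#' @export
discretionary_coverage <- function(quantified, by_store = FALSE) {
  q <- as_tibble(quantified) %>% filter(.data$is_discretionary)
  pooled <- q %>%
    summarise(
      discretionary_energy_kj = sum(.data$energy_kj),
      covered_kj = sum(.data$energy_kj[!is.na(.data$unhealthy_subgroup)])
    ) %>%
    mutate(
      store_id = "(pooled)",
      covered_fraction = if_else(.data$discretionary_energy_kj > 0,
                                 .data$covered_kj / .data$discretionary_energy_kj, NA_real_),
      undefined = .data$discretionary_energy_kj <= 0
    ) %>%
    select("store_id", "covered_fraction", "discretionary_energy_kj", "undefined")
  if (!by_store) {
    return(select(pooled, -"store_id"))
  }
  per_store <- q %>%
    group_by(.data$store_id) %>%
    summarise(
      discretionary_energy_kj = sum(.data$energy_kj),
      covered_kj = sum(.data$energy_kj[!is.na(.data$unhealthy_subgroup)]),
      .groups = "drop"
    ) %>%
    mutate(
      covered_fraction = if_else(.data$discretionary_energy_kj > 0,
                                 .data$covered_kj / .data$discretionary_energy_kj, NA_real_),
      undefined = .data$discretionary_energy_kj <= 0
    ) %>%
    select("store_id", "covered_fraction", "discretionary_energy_kj", "undefined")
  bind_rows(per_store, pooled)
}

#' Dollar share by primary food group
#'
#' Optional auxiliary indicator: the fraction of classified food dollars spent
#' in each primary food group. Shares sum to 1 over classified dollars;
#' undefined when no classified dollars exist.
#'
#' @inheritParams total_energy
#' @return Tibble `group`, `dollars`, `share` (pooled over stores/periods).
#' @export
dollar_share_by_group <- function(quantified) {
  q <- as_tibble(quantified) %>% filter(!is.na(.data$group))
  total <- sum(q$dollars)
  if (nrow(q) == 0 || total <= 0) {
    return(tibble(group = names(food_groups()), dollars = 0, share = NA_real_))
  }
  q %>%
    group_by(.data$group) %>%
    summarise(dollars = sum(.data$dollars), .groups = "drop") %>%
    tidyr::complete(group = names(food_groups()), fill = list(dollars = 0)) %>%
    mutate(share = .data$dollars / total)
}

#' Write / read indicator sets (CSV and JSON)
#'
#' Tidy interchange: one row per store x period x indicator, columns
#' `store_id`, `period`, `indicator_key` (`level/indicator`), `value`, `unit`,
#' plus per-period total rows (`total/energy_kj`, `total/dollars`). Both
#' formats round-trip losslessly through [read_indicators()].
#'
#' @param indicators an `indicator_set`.
#' @param path output path; format chosen by extension (`.csv` or `.json`).
#' @export
write_indicators <- function(indicators, path) {
  long <- indicator_long(indicators)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    payload <- list(
      period_unit = attr(indicators, "period_unit"),
      reference_energy = attr(indicators, "reference_energy"),
      discretionary_serve_kj = attr(indicators, "discretionary_serve_kj"),
      rows = long
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    readr::write_csv(long, path, progress = FALSE)
  }
  invisible(path)
}

indicator_long <- function(indicators) {
  totals <- attr(indicators, "totals")
  bind_rows(
    as_tibble(indicators) %>%
      mutate(indicator_key = paste(.data$level, .data$indicator, sep = "/")) %>%
      select("store_id", "period", "indicator_key", "value", "unit"),
    totals %>%
      tidyr::pivot_longer(c("energy_kj", "dollars"), names_to = "indicator",
                          values_to = "value") %>%
      mutate(
        indicator_key = paste0("total/", .data$indicator),
        unit = if_else(.data$indicator == "energy_kj", "kJ", "AUD")
      ) %>%
      select("store_id", "period", "indicator_key", "value", "unit")
  ) %>%
    arrange(.data$store_id, .data$period, .data$indicator_key)
}

#' @rdname write_indicators
#' @param period_unit period unit of the stored set (recorded in JSON;
#'   required for CSV).
#' @export
read_indicators <- function(path, period_unit = "month") {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    payload <- jsonlite::read_json(path, simplifyVector = TRUE)
    long <- as_tibble(payload$rows)
    long$value <- as.numeric(long$value)
    period_unit <- payload$period_unit
    ref_e <- payload$reference_energy
    disc_kj <- payload$discretionary_serve_kj
  } else {
    long <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    ref_e <- 8900
    disc_kj <- 600
  }
  totals <- long %>%
    filter(startsWith(.data$indicator_key, "total/")) %>%
    mutate(indicator = sub("^total/", "", .data$indicator_key)) %>%
    select("store_id", "period", "indicator", "value") %>%
    tidyr::pivot_wider(names_from = "indicator", values_from = "value") %>%
    mutate(no_sales = .data$energy_kj <= 0) %>%
    select("store_id", "period", "energy_kj", "no_sales", "dollars")
  rows <- long %>%
    filter(!startsWith(.data$indicator_key, "total/")) %>%
    tidyr::separate_wider_delim("indicator_key", "/", names = c("level", "indicator")) %>%
    mutate(period_start = period_start_from_key(.data$period, period_unit)) %>%
    select("store_id", "period", "period_start", "level", "indicator", "value", "unit")
  structure(
    rows,
    class = c("indicator_set", class(tibble())),
    totals = totals,
    period_unit = period_unit,
    reference_energy = ref_e,
    discretionary_serve_kj = disc_kj
  )
}

#' @export
print.indicator_set <- function(x, ...) {
  cat("<indicator_set> ", length(unique(x$store_id)), " store(s), ",
      length(unique(x$period)), " ", attr(x, "period_unit"), " period(s), ",
      "reference energy ", attr(x, "reference_energy"), " kJ/person/day\n", sep = "")
  NextMethod()
}
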