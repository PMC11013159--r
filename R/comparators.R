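# Comparator series displayed alongside a store's indicators: the unweighted
# all-store average, the guideline target (period-constant), or a user-set
# target. Quarterly (and any re-windowed) values are always recomputed from
# the base weekly records, never averaged from finer periods: the indicator
# is a ratio, and a mean of ratios is not the ratio of pooled sums.

#' All-store average of an indicator
#'
#' Unweighted arithmetic mean over stores with a defined value in each period
#' (each store counts equally regardless of size); stores with no sales in a
#' period are omitted and the number of contributing stores is attached.
#' Set `weighted = TRUE` for the energy-weighted pooled alternative, which
#' weights each store by its classified energy in the period.
#'
#' @param indicators an `indicator_set` (see [compute_indicators()]).
#' @param indicator indicator key, e.g. `"fruit"` or `"unhealthy_foods"`.
#' @param level `"group"`, `"subgroup"` or `"tier"`.
#' @param weighted energy-weight the mean instead of one-store-one-vote.
#' @return Tibble `period`, `value`, `n_stores`; `value` is `NA` with
#'   `n_stores = 0` for periods where no store has data.
#' @export
all_store_average <- function(indicators, indicator, level = "group", weighted = FALSE) {
  rows <- as_tibble(indicators) %>%
    filter(.data$level == !!level, .data$indicator == !!indicator)
  if (nrow(rows) == 0) {
    abort(glue::glue("unknown indicator '{level}/{indicator}'"), class = "s2s_input_error")
  }
  if (weighted) {
    totals <- attr(indicators, "totals")
    rows <- rows %>%
      left_join(select(totals, "store_id", "period", "energy_kj"),
                by = c("store_id", "period"))
    rows %>%
      group_by(.data$period) %>%
      summarise(
        n_stores = sum(!is.na(.data$value)),
        value = if (any(!is.na(.data$value))) {
          stats::weighted.mean(.data$value, .data$energy_kj, na.rm = TRUE)
        } else NA_real_,
        .groups = "drop"
      ) %>%
      select("period", "value", "n_stores")
  } else {
    rows %>%
      group_by(.data$period) %>%
      summarise(
        n_stores = sum(!is.na(.data$value)),
        value = if (any(!is.na(.data$value))) mean(.data$value, na.rm = TRUE) else NA_real_,
        .groups = "drop"
      ) %>%
      select("period", "value", "n_stores")
  }
}

#' Trend series for one store and indicator
#'
#' Recomputes indicators from the base quantified records at the requested
#' period unit, then returns the most recent `window` periods in
#' chronological order. Calendar gaps (periods with no sales between the
#' first and last displayed period) are preserved as explicit `NA` rows. If
#' fewer periods than `window` exist, all available are returned with a
#' notice attribute (`truncated = TRUE`).
#'
#' @param quantified tibble from [link_sales()].
#' @param store store identifier.
#' @param indicator indicator key.
#' @param window number of periods to display (>= 1).
#' @param period_unit `"month"` or `"quarter"`.
#' @param level indicator level.
#' @inheritParams compute_indicators
#' @return Tibble `period`, `period_start`, `value`, ordered oldest-first.
#' @export
trend_series <- function(quantified, store, indicator, window,
                         period_unit = c("month", "quarter"), level = "group",
                         reference_energy = 8900, discretionary_serve_kj = 600,
                         scheme = default_scheme()) {
  period_unit <- match.arg(period_unit)
  stopifnot(window >= 1)
  ind <- compute_indicators(quantified, period_unit, reference_energy,
                            discretionary_serve_kj, scheme)
  rows <- as_tibble(ind) %>%
    filter(.data$store_id == store, .data$level == !!level,
           .data$indicator == !!indicator) %>%
    arrange(.data$period_start)
  if (nrow(rows) == 0) {
    return(structure(tibble(period = character(), period_start = as.Date(character()),
                            value = double()),
                     truncated = TRUE))
  }
  # fill calendar gaps between first and last observed period
  all_starts <- seq(min(rows$period_start), max(rows$period_start),
                    by = if (period_unit == "month") "month" else "3 months")
  grid <- tibble(period_start = all_starts,
                 period = period_key(all_starts, period_unit))
  full <- grid %>% left_join(select(rows, "period", "value"), by = "period")
  truncated <- nrow(full) < window
  out <- tail(full, window) %>% select("period", "period_start", "value")
  if (truncated) {
    inform(glue::glue(
      "window {window} exceeds available history ({nrow(full)} {period_unit}s); returning all"))
  }
  structure(out, truncated = truncated)
}
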