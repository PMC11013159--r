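# broom-style verbs for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an indicator set
#'
#' Returns the long indicator table as a plain tibble (one row per store x
#' period x indicator). With `against`, joins the group-level rows to a
#' target set and adds `target`, `direction` and `meets_target`.
#'
#' @param x an `indicator_set`.
#' @param against optional `target_set` to compare group indicators with.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.indicator_set <- function(x, against = NULL, ...) {
  out <- as_tibble(x)
  if (!is.null(against)) {
    tg <- as_tibble(against)[c("group", "target", "direction")]
    out <- out %>%
      filter(.data$level == "group") %>%
      left_join(tg, by = c(indicator = "group")) %>%
      mutate(meets_target = meets_target(.data$value, .data$target, .data$direction))
  }
  out
}

#' One-row summary of an indicator set
#'
#' @param x an `indicator_set`.
#' @param ... unused.
#' @return Tibble with store/period counts, the period unit, reference
#'   energy, and pooled classified energy and dollars.
#' @export
glance.indicator_set <- function(x, ...) {
  totals <- attr(x, "totals")
  tibble(
    n_stores = length(unique(x$store_id)),
    n_periods = length(unique(x$period)),
    period_unit = attr(x, "period_unit"),
    reference_energy = attr(x, "reference_energy"),
    total_energy_kj = sum(totals$energy_kj),
    total_dollars = sum(totals$dollars),
    n_no_sales = sum(totals$no_sales)
  )
}

#' Tidy a target set
#'
#' @param x a `target_set`.
#' @param ... unused.
#' @return Tibble `group`, `group_label`, `target`, `direction`.
#' @export
tidy.target_set <- function(x, ...) {
  as_tibble(x)
}

#' @rdname tidy.target_set
#' @export
glance.target_set <- function(x, ...) {
  tibble(
    n_groups = nrow(x),
    reference_energy = attr(x, "reference_energy"),
    n_at_most = sum(x$direction == "at_most")
  )
}
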