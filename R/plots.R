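# ggplot2 graphics for interactive use. The HTML report embeds its own
# deterministic SVG; these functions give analysts the same views as
# composable ggplot objects.

#' Plot an indicator trend
#'
#' Line (default) or bar chart of one indicator for one or more stores, with
#' an optional dashed guideline-target line.
#'
#' @param indicators an `indicator_set`.
#' @param indicator indicator key (e.g. `"fruit"`).
#' @param level indicator level (`"group"`, `"subgroup"`, `"tier"`).
#' @param stores optional subset of store ids.
#' @param targets optional `target_set` supplying the dashed target line
#'   (group level only).
#' @param chart `"line"` or `"bar"`.
#' @return A ggplot object.
#' @export
plot_trend <- function(indicators, indicator, level = "group", stores = NULL,
                       targets = default_targets(), chart = c("line", "bar")) {
  chart <- match.arg(chart)
  rows <- as_tibble(indicators) %>%
    filter(.data$level == !!level, .data$indicator == !!indicator)
  if (!is.null(stores)) rows <- filter(rows, .data$store_id %in% stores)
  p <- ggplot2::ggplot(rows, ggplot2::aes(x = .data$period_start, y = .data$value,
                                          colour = .data$store_id,
                                          group = .data$store_id))
  p <- if (chart == "bar") {
    p + ggplot2::geom_col(ggplot2::aes(fill = .data$store_id), position = "dodge",
                          colour = NA)
  } else {
    p + ggplot2::geom_line() + ggplot2::geom_point()
  }
  if (level == "group" && !is.null(targets)) {
    trow <- as_tibble(targets) %>% filter(.data$group == indicator)
    if (nrow(trow) == 1) {
      p <- p + ggplot2::geom_hline(yintercept = trow$target, linetype = "dashed")
    }
  }
  p + ggplot2::labs(
    x = NULL, y = "serves/person/day",
    title = unname(food_groups()[indicator]) %||% indicator
  ) + ggplot2::theme_minimal()
}

#' Gauge-style view of the latest values against targets
#'
#' One panel per selected group indicator showing the latest-period value as
#' a horizontal gauge with the target boundary; green/red shading sits on the
#' target-satisfying/violating side and flips for the Unhealthy Foods upper
#' limit.
#'
#' @inheritParams plot_trend
#' @param store store id.
#' @return A ggplot object.
#' @export
plot_gauge <- function(indicators, store, targets = default_targets()) {
  pal <- report_palette()
  tg <- as_tibble(targets)
  latest <- as_tibble(indicators) %>%
    filter(.data$store_id == store, .data$level == "group") %>%
    group_by(.data$indicator) %>%
    arrange(.data$period_start) %>%
    summarise(value = dplyr::last(.data$value), .groups = "drop") %>%
    inner_join(tg, by = c(indicator = "group")) %>%
    mutate(
      xmax = pmax(2 * .data$target, .data$value, na.rm = TRUE),
      met = meets_target(.data$value, .data$target, .data$direction)
    )
  zones <- latest %>%
    tidyr::pivot_longer(cols = c("target", "xmax"), values_to = "xend") %>%
    group_by(.data$indicator) %>%
    mutate(xstart = dplyr::lag(.data$xend, default = 0)) %>%
    ungroup() %>%
    mutate(zone = if_else(
      (.data$name == "target") == (.data$direction == "at_least"),
      "below_target_side", "above_target_side"
    ),
    colour = if_else(
      (.data$direction == "at_least") == (.data$name == "xmax"),
      pal[["green"]], pal[["red"]]
    ))
  ggplot2::ggplot(latest) +
    ggplot2::geom_rect(data = zones,
                       ggplot2::aes(xmin = .data$xstart, xmax = .data$xend,
                                    ymin = 0.3, ymax = 0.7),
                       fill = zones$colour, alpha = 0.35) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$value, xend = .data$value,
                                       y = 0.2, yend = 0.8), linewidth = 1.2) +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$target), linetype = "dashed") +
    ggplot2::facet_wrap(~ .data$group_label, scales = "free_x", ncol = 2) +
    ggplot2::scale_y_continuous(NULL, breaks = NULL, limits = c(0, 1)) +
    ggplot2::labs(x = "serves/person/day",
                  title = glue::glue("Store {store}: latest period vs targets")) +
    ggplot2::theme_minimal()
}

#' @rdname plot_trend
#' @param object an `indicator_set`.
#' @param ... passed on to [plot_trend()].
#' @export
autoplot.indicator_set <- function(object, indicator = "unhealthy_foods", ...) {
  plot_trend(object, indicator = indicator, ...)
}
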