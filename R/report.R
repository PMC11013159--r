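# Store reports: gauge chart per indicator against its target, trend chart
# over the chosen window, traffic-light healthiness colours, and the
# store-facing descriptor wording ("Best Choice", "Less Healthy Choice",
# "Unhealthy Foods"). Reports are self-contained HTML with charts embedded
# as SVG, written by a purpose-built deterministic writer: identical inputs
# yield byte-identical files (no timestamps unless stamped), so reports can
# be diffed and cached.

#' Does a value meet its target?
#'
#' Boundary inclusive on both sides: an at-least target is met when
#' `value >= target`, an at-most (upper-limit) target when `value <= target`.
#' Undefined values return `NA` (rendered grey / "no data").
#'
#' @param value serves/person/day (may be `NA`).
#' @param target target value.
#' @param direction `"at_least"` or `"at_most"`.
#' @return Logical vector.
#' @examples
#' meets_target(2.0, 2.0, "at_least")   # TRUE (boundary)
#' meets_target(2.6, 2.5, "at_most")    # FALSE
#' @export
meets_target <- function(value, target, direction) {
  stopifnot(all(direction %in% c("at_least", "at_most")))
  ifelse(direction == "at_least", value >= target, value <= target)
}

#' Traffic-light colour for a healthiness tier
#'
#' Colour-blind-safe palette (Okabe-Ito): Best Choice green `#009E73`,
#' Less Healthy Choice amber `#E69F00`, Unhealthy Foods red `#D55E00`.
#'
#' @param tier tier key or display label (see [healthiness_tiers()]).
#' @return Hex colour string.
#' @examples
#' traffic_light("best_choice")
#' traffic_light("Unhealthy Foods")
#' @export
traffic_light <- function(tier) {
  pal <- c(best_choice = "#009E73", less_healthy_choice = "#E69F00",
           unhealthy_foods = "#D55E00")
  label_to_key <- setNames(names(healthiness_tiers()), unname(healthiness_tiers()))
  key <- if_else(tier %in% names(pal), tier, unname(label_to_key[tier]))
  if (any(is.na(key))) {
    abort(glue::glue("unknown tier: {paste(tier[is.na(key)], collapse = ', ')}"),
          class = "s2s_input_error")
  }
  unname(pal[key])
}

report_palette <- function() {
  c(green = "#009E73", red = "#D55E00", amber = "#E69F00", grey = "#999999",
    line = "#0072B2", average = "#CC79A7", target = "#000000")
}

#' Report customisation
#'
#' @param store_id store to report on.
#' @param window number of periods to display in trend charts (>= 1).
#' @param period_unit `"month"` or `"quarter"`.
#' @param comparators subset of `"guideline-target"`, `"all-store-average"`,
#'   `"user-target"`.
#' @param selected_indicators non-empty vector of group-level indicator keys.
#' @param user_targets optional `target_set` override; only used when
#'   `"user-target"` is listed in `comparators`.
#' @param chart trend chart style, `"line"` (default) or `"bar"`.
#' @param stamp include a generation timestamp (breaks byte-stability).
#' @return List of class `report_spec`.
#' @export
report_spec <- function(store_id, window = 6, period_unit = c("month", "quarter"),
                        comparators = c("guideline-target"),
                        selected_indicators = names(food_groups()),
                        user_targets = NULL,
                        chart = c("line", "bar"), stamp = FALSE) {
  period_unit <- match.arg(period_unit)
  chart <- match.arg(chart)
  stopifnot(window >= 1)
  if (length(selected_indicators) == 0) {
    abort("selected_indicators must be non-empty", class = "s2s_input_error")
  }
  bad <- setdiff(comparators, c("guideline-target", "all-store-average", "user-target"))
  if (length(bad) > 0) {
    abort(glue::glue("unknown comparator(s): {paste(bad, collapse = ', ')}"),
          class = "s2s_input_error")
  }
  structure(
    list(store_id = store_id, window = as.integer(window), period_unit = period_unit,
         comparators = comparators, selected_indicators = selected_indicators,
         user_targets = user_targets, chart = chart, stamp = stamp),
    class = "report_spec"
  )
}

fmt <- function(x, digits = 2) {
  ifelse(is.na(x), "NA", sprintf(paste0("%.", digits, "f"), x))
}

svg_gauge <- function(value, target, direction, label, width = 260, height = 170) {
  pal <- report_palette()
  cx <- width / 2; cy <- height - 30; r <- 95
  vmax <- max(2 * target, if (is.na(value)) 0 else value * 1.05, 1e-9)
  pt <- function(v, rad = r) {
    p <- min(max(v / vmax, 0), 1)
    phi <- pi * (1 - p)
    c(cx + rad * cos(phi), cy - rad * sin(phi))
  }
  arc <- function(v1, v2, colour) {
    a <- pt(v1); b <- pt(v2)
    sprintf(
      '<path d="M %s %s A %s %s 0 %d 1 %s %s" fill="none" stroke="%s" stroke-width="22"/>',
      fmt(a[1]), fmt(a[2]), fmt(r), fmt(r),
      as.integer((v2 - v1) / vmax > 0.5), fmt(b[1]), fmt(b[2]), colour
    )
  }
  # green sits on the target-satisfying side; orientation flips for at-most
  zones <- if (direction == "at_least") {
    paste0(arc(0, target, pal[["red"]]), arc(target, vmax, pal[["green"]]))
  } else {
    paste0(arc(0, target, pal[["green"]]), arc(target, vmax, pal[["red"]]))
  }
  needle <- if (!is.na(value)) {
    tip <- pt(min(value, vmax), r - 14)
    ok <- meets_target(value, target, direction)
    paste0(
      sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#333333" stroke-width="3"/>',
              fmt(cx), fmt(cy), fmt(tip[1]), fmt(tip[2])),
      sprintf('<circle cx="%s" cy="%s" r="5" fill="#333333"/>', fmt(cx), fmt(cy)),
      sprintf('<text x="%s" y="%s" text-anchor="middle" font-size="16" fill="%s">%s</text>',
              fmt(cx), fmt(cy + 24), if (ok) pal[["green"]] else pal[["red"]], fmt(value))
    )
  } else {
    sprintf('<text x="%s" y="%s" text-anchor="middle" font-size="14" fill="%s">no data</text>',
            fmt(cx), fmt(cy - 30), pal[["grey"]])
  }
  tpos <- pt(target, r + 16)
  paste0(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" role="img" aria-label="%s gauge">',
            width, height, label),
    zones, needle,
    sprintf('<text x="%s" y="%s" text-anchor="middle" font-size="11">target %s%s</text>',
            fmt(tpos[1]), fmt(tpos[2]),
            if (direction == "at_least") "&#8805;" else "&#8804;", fmt(target, 1)),
    sprintf('<text x="%s" y="%s" text-anchor="middle" font-size="11">0</text>',
            fmt(cx - r), fmt(cy + 14)),
    sprintf('<text x="%s" y="%s" text-anchor="middle" font-size="11">%s</text>',
            fmt(cx + r), fmt(cy + 14), fmt(vmax, 1)),
    "</svg>"
  )
}

svg_trend <- function(series, target = NA, average = NULL, chart = "line",
                      label = "", width = 440, height = 220) {
  pal <- report_palette()
  ml <- 42; mr <- 12; mt <- 14; mb <- 38
  pw <- width - ml - mr; ph <- height - mt - mb
  vals <- c(series$value, target, if (!is.null(average)) average$value)
  ymax <- max(c(vals[!is.na(vals)], 1e-9)) * 1.15
  n <- nrow(series)
  xs <- ml + pw * (seq_len(n) - 0.5) / n
  y_of <- function(v) mt + ph * (1 - v / ymax)
  body <- character()
  # axes
  body <- c(body, sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#444444"/>',
                          fmt(ml), fmt(mt + ph), fmt(ml + pw), fmt(mt + ph)))
  for (frac in c(0, 0.5, 1)) {
    v <- ymax * frac
    body <- c(body,
      sprintf('<text x="%s" y="%s" text-anchor="end" font-size="10">%s</text>',
              fmt(ml - 4), fmt(y_of(v) + 3), fmt(v, 1)),
      sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#dddddd"/>',
              fmt(ml), fmt(y_of(v)), fmt(ml + pw), fmt(y_of(v))))
  }
  if (!is.na(target)) {
    body <- c(body, sprintf(
      '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-dasharray="6 3" stroke-width="1.5"/>',
      fmt(ml), fmt(y_of(target)), fmt(ml + pw), fmt(y_of(target)), pal[["target"]]))
  }
  if (chart == "bar") {
    bw <- pw / n * 0.6
    for (i in seq_len(n)) {
      if (is.na(series$value[i])) next
      body <- c(body, sprintf(
        '<rect x="%s" y="%s" width="%s" height="%s" fill="%s"/>',
        fmt(xs[i] - bw / 2), fmt(y_of(series$value[i])), fmt(bw),
        fmt(mt + ph - y_of(series$value[i])), pal[["line"]]))
    }
  } else {
    ok <- !is.na(series$value)
    runs <- split(seq_len(n)[ok], cumsum(!ok)[ok])
    for (run in runs) {
      if (length(run) >= 2) {
        pts <- paste(sprintf("%s,%s", fmt(xs[run]), fmt(y_of(series$value[run]))),
                     collapse = " ")
        body <- c(body, sprintf(
          '<polyline points="%s" fill="none" stroke="%s" stroke-width="2"/>',
          pts, pal[["line"]]))
      }
      for (i in run) {
        body <- c(body, sprintf('<circle cx="%s" cy="%s" r="3" fill="%s"/>',
                                fmt(xs[i]), fmt(y_of(series$value[i])), pal[["line"]]))
      }
    }
  }
  if (!is.null(average)) {
    av <- average$value[match(series$period, average$period)]
    ok <- !is.na(av)
    if (any(ok)) {
      pts <- paste(sprintf("%s,%s", fmt(xs[ok]), fmt(y_of(av[ok]))), collapse = " ")
      body <- c(body, sprintf(
        '<polyline points="%s" fill="none" stroke="%s" stroke-width="1.5" stroke-dasharray="2 2"/>',
        pts, pal[["average"]]))
    }
  }
  for (i in seq_len(n)) {
    body <- c(body, sprintf(
      '<text x="%s" y="%s" text-anchor="middle" font-size="9">%s</text>',
      fmt(xs[i]), fmt(mt + ph + 14), series$period[i]))
  }
  paste0(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" role="img" aria-label="%s trend">',
            width, height, label),
    paste(body, collapse = ""), "</svg>"
  )
}

serve_guide_html <- function() {
  paste0(
    "<section class='guide'><h2>What is a serve?</h2>",
    "<p>Targets and results are in <strong>serves per person per day</strong>, ",
    "standardised to an average daily energy requirement of 8.9&#8201;MJ. ",
    "One serve is about:</p><ul>",
    "<li><strong>Fruit</strong>: 150&#8201;g fresh fruit (1 medium apple) or 125&#8201;mL 100% juice</li>",
    "<li><strong>Vegetables</strong>: 75&#8201;g (half a cup cooked vegetables)</li>",
    "<li><strong>Breads and Cereals</strong>: 1 slice of bread or half a cup cooked rice</li>",
    "<li><strong>Meat, Fish and Eggs</strong>: 65&#8201;g cooked lean meat, 100&#8201;g fish or 2 eggs</li>",
    "<li><strong>Dairy</strong>: 250&#8201;mL milk, 200&#8201;g yoghurt or 40&#8201;g cheese</li>",
    "<li><strong>Unhealthy Foods</strong>: about 600&#8201;kJ of discretionary food or drink ",
    "(a small chocolate bar or a 375&#8201;mL can of soft drink)</li></ul>",
    "<h2>Frequently asked questions</h2>",
    "<p><strong>Why serves and not dollars?</strong> Prices change; serves track the ",
    "quantity of food your community purchased, scaled to energy so stores of ",
    "different sizes and months of different lengths compare fairly.</p>",
    "<p><strong>What counts as an Unhealthy Food?</strong> Discretionary foods and ",
    "drinks: those not needed for nutrient requirements, such as soft drinks, ",
    "confectionery, chips and takeaway. These never count toward the five food ",
    "groups, even when they contain some (for example the potato in hot chips).</p>",
    "<p><strong>Where do the targets come from?</strong> Dietary guideline ",
    "recommendations weighted by the community population profile, rounded to ",
    "the nearest half serve. The Unhealthy Foods target is an upper limit.</p>",
    "<p>Alcoholic beverages are excluded from all figures.</p></section>"
  )
}

#' Build a store report
#'
#' Renders a self-contained HTML report for one store: per selected
#' indicator, a gauge panel for the latest period (needle against a red/green
#' target zone, orientation flipped for the Unhealthy Foods upper limit) and
#' a trend chart over the window with the chosen comparator overlays, plus
#' the serve-size guide and FAQ. A machine-readable JSON payload (values,
#' targets, comparator series, statuses) is embedded in the document and
#' optionally written alongside.
#'
#' Stores or periods with no data render explicit "no data" panels, never an
#' error. Without `stamp`, identical inputs produce byte-identical output.
#'
#' @param spec a [report_spec()].
#' @param quantified tibble from [link_sales()] covering all stores (needed
#'   for the all-store-average comparator).
#' @param targets a `target_set`; defaults to [default_targets()].
#' @param file output HTML path.
#' @param payload_file optional path for the standalone JSON payload.
#' @return `file`, invisibly, with the payload list as attribute `payload`.
#' @export
build_report <- function(spec, quantified, targets = default_targets(), file,
                         payload_file = NULL) {
  stopifnot(inherits(spec, "report_spec"))
  ref_e <- attr(targets, "reference_energy") %||% 8900
  ind <- compute_indicators(quantified, spec$period_unit, reference_energy = ref_e)
  tg <- as_tibble(targets)
  if ("user-target" %in% spec$comparators && !is.null(spec$user_targets)) {
    ut <- as_tibble(spec$user_targets)
    tg <- tg %>%
      rows_update_by_group(ut)
  }
  unknown <- setdiff(spec$selected_indicators, tg$group)
  if (length(unknown) > 0) {
    abort(glue::glue(
      "unknown indicator key(s): {paste(unknown, collapse = ', ')}; valid keys: {paste(tg$group, collapse = ', ')}"),
      class = "s2s_unknown_indicator")
  }

  store_rows <- as_tibble(ind) %>% filter(.data$store_id == spec$store_id)
  panels <- character()
  payload_ind <- list()
  for (key in spec$selected_indicators) {
    trow <- tg[tg$group == key, ]
    series <- trend_series(quantified, spec$store_id, key, spec$window,
                           spec$period_unit, reference_energy = ref_e)
    latest <- if (nrow(series) > 0) series$value[nrow(series)] else NA_real_
    latest_period <- if (nrow(series) > 0) series$period[nrow(series)] else NA_character_
    avg <- if ("all-store-average" %in% spec$comparators) {
      all_store_average(ind, key)
    } else NULL
    status <- meets_target(latest, trow$target, trow$direction)
    status_txt <- dplyr::case_when(
      is.na(status) ~ "No data",
      status ~ "Meeting target",
      TRUE ~ "Not meeting target"
    )
    pal <- report_palette()
    status_col <- if (is.na(status)) pal[["grey"]] else if (status) pal[["green"]] else pal[["red"]]
    show_target <- any(c("guideline-target", "user-target") %in% spec$comparators)
    panels <- c(panels, paste0(
      sprintf("<section class='panel' id='panel-%s'><h2>%s</h2>", key, trow$group_label),
      sprintf("<p class='status' style='color:%s'><strong>%s</strong>%s</p>",
              status_col, status_txt,
              if (!is.na(latest)) sprintf(" &#8212; %s serves/person/day in %s",
                                          fmt(latest), latest_period) else ""),
      "<div class='charts'>",
      svg_gauge(latest, trow$target, trow$direction, trow$group_label),
      svg_trend(series, target = if (show_target) trow$target else NA,
                average = avg, chart = spec$chart, label = trow$group_label),
      "</div>",
      if (!is.null(avg)) {
        n_latest <- avg$n_stores[match(latest_period, avg$period)]
        sprintf("<p class='note'>All-store average shown (n=%s stores in %s).</p>",
                ifelse(is.na(n_latest), 0, n_latest), latest_period)
      } else "",
      "</section>"
    ))
    payload_ind[[key]] <- list(
      label = trow$group_label,
      target = trow$target, direction = trow$direction,
      latest_period = latest_period, latest_value = latest,
      status = if (is.na(status)) "no_data" else if (status) "meeting" else "not_meeting",
      trend = series[c("period", "value")],
      all_store_average = if (!is.null(avg)) avg else NULL
    )
  }

  payload <- list(
    store_id = spec$store_id,
    period_unit = spec$period_unit,
    window = spec$window,
    reference_energy = ref_e,
    comparators = spec$comparators,
    tier_colours = as.list(setNames(traffic_light(names(healthiness_tiers())),
                                    unname(healthiness_tiers()))),
    indicators = payload_ind
  )
  payload_json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                                   na = "null", dataframe = "columns")

  html <- paste0(
    "<!DOCTYPE html><html lang='en'><head><meta charset='utf-8'/>",
    sprintf("<title>Store report &#8212; %s</title>", spec$store_id),
    "<style>body{font-family:sans-serif;max-width:960px;margin:auto;padding:1em;}",
    ".panel{border:1px solid #ddd;border-radius:8px;padding:0.5em 1em;margin:1em 0;}",
    ".charts{display:flex;flex-wrap:wrap;gap:1em;align-items:center;}",
    ".note{color:#666;font-size:0.85em;} .guide{color:#333;}</style></head><body>",
    sprintf("<h1>Healthy food report: store %s</h1>", spec$store_id),
    "<p>Serves purchased per person per day, standardised to 8.9&#8201;MJ of ",
    "energy purchased. Green means the store is on the healthy side of the ",
    "target; for Unhealthy Foods the target is an upper limit, so lower is better.</p>",
    if (spec$stamp) sprintf("<p class='note'>Generated %s</p>", format(Sys.time())) else "",
    paste(panels, collapse = ""),
    serve_guide_html(),
    "<script type='application/json' id='payload'>", payload_json, "</script>",
    "</body></html>"
  )
  writeLines(html, file, sep = "")
  if (!is.null(payload_file)) {
    jsonlite::write_json(payload, payload_file, auto_unbox = TRUE, digits = NA,
                         na = "null", dataframe = "columns")
  }
  invisible(structure(file, payload = payload))
}

# replace target rows by group key (user overrides)
rows_update_by_group <- function(tg, ut) {
  idx <- match(ut$group, tg$group)
  keep <- !is.na(idx)
  tg$target[idx[keep]] <- ut$target[keep]
  if ("direction" %in% names(ut)) tg$direction[idx[keep]] <- ut$direction[keep]
  tg
}
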