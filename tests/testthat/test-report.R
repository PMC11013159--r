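report_quantified <- function() {
  fx <- generate_reference_fixture()
  spec <- scenario_spec(n_stores = 3, n_weeks = 10, noise = 0.1, seed = 41)
  link_sales(generate_sales(spec, fx), fx$catalog, fx$reference)
}

test_that("target satisfaction is boundary-inclusive and direction-aware", {
  expect_true(meets_target(2.0, 2.0, "at_least"))
  expect_false(meets_target(2.6, 2.5, "at_most"))
  expect_true(meets_target(5.5, 5.0, "at_least"))
  expect_true(meets_target(2.5, 2.5, "at_most"))
  expect_true(is.na(meets_target(NA_real_, 2, "at_least")))
  # monotone: on an at-most target, increasing the value never turns
  # "not meeting" into "meeting"
  vals <- sort(stats::runif(50, 0, 6))
  met <- meets_target(vals, 2.5, "at_most")
  expect_true(all(diff(met) <= 0))
})

test_that("traffic-light colours are a bijection over tiers", {
  cols <- traffic_light(names(healthiness_tiers()))
  expect_length(unique(cols), 3)
  expect_equal(traffic_light("best_choice"), "#009E73")
  expect_equal(traffic_light("Unhealthy Foods"), "#D55E00")
  expect_equal(traffic_light("Less Healthy Choice"), "#E69F00")
  expect_error(traffic_light("super_healthy"), class = "s2s_input_error")
})

test_that("reports contain one gauge and one trend per selected indicator", {
  q <- report_quantified()
  file <- file.path(withr::local_tempdir(), "r.html")
  spec <- report_spec("S01", window = 3,
                      selected_indicators = c("fruit", "unhealthy_foods"))
  build_report(spec, q, file = file)
  html <- readChar(file, file.size(file))
  expect_equal(length(gregexpr("<section class='panel'", html)[[1]]), 2)
  expect_equal(length(gregexpr("gauge\">", html)[[1]]), 2)
  expect_equal(length(gregexpr("trend\">", html)[[1]]), 2)
  # deselected indicators never appear as panels
  expect_false(grepl("id='panel-dairy'", html))
  # descriptor wording present in the serve guide
  expect_true(grepl("Unhealthy Foods", html))
})

test_that("gauge red/green orientation flips for the upper-limit target", {
  q <- report_quantified()
  dir <- withr::local_tempdir()
  spec <- report_spec("S01", selected_indicators = c("fruit", "unhealthy_foods"))
  out <- build_report(spec, q, file = file.path(dir, "r.html"))
  payload <- attr(out, "payload")
  expect_equal(payload$indicators$fruit$direction, "at_least")
  expect_equal(payload$indicators$unhealthy_foods$direction, "at_most")

  html <- readChar(file.path(dir, "r.html"), file.size(file.path(dir, "r.html")))
  # per gauge the first zone arc spans [0, target]: red for at-least
  # indicators, green for at-most
  gauges <- regmatches(html, gregexpr("aria-label=\"[^\"]+ gauge\">.*?</svg>", html))[[1]]
  fruit_g <- gauges[grepl("Fruit gauge", gauges)][1]
  unh_g <- gauges[grepl("Unhealthy Foods gauge", gauges)]
  first_zone_colour <- function(svg) {
    regmatches(svg, regexpr('stroke="#[0-9A-F]{6}"', svg))
  }
  expect_equal(first_zone_colour(fruit_g), 'stroke="#D55E00"')   # red below target
  expect_equal(first_zone_colour(unh_g), 'stroke="#009E73"')     # green below limit
})

test_that("report status classifies values against targets, boundary inclusive", {
  fx <- generate_reference_fixture()
  # noise-free scenario pinned exactly at fruit = 2.0 (the target boundary)
  # and unhealthy = 3.0 (above the 2.5 upper limit)
  spec <- scenario_spec(
    n_stores = 1, n_weeks = 4, noise = 0, store_scale_sigma = 0, seed = 43,
    target_indicators = c(fruit = 2, vegetables = 5, breads_cereals = 5.5,
                          meat_fish_eggs = 2.5, dairy = 2.5, unhealthy_foods = 3)
  )
  q <- link_sales(generate_sales(spec, fx), fx$catalog, fx$reference)
  out <- build_report(
    report_spec("S01", selected_indicators = c("fruit", "unhealthy_foods")),
    q, file = file.path(withr::local_tempdir(), "r.html")
  )
  payload <- attr(out, "payload")
  expect_equal(payload$indicators$fruit$status, "meeting")        # 2.0 vs >= 2
  expect_equal(payload$indicators$unhealthy_foods$status, "not_meeting")  # 3.0 vs <= 2.5
})

test_that("identical inputs yield byte-identical reports", {
  q <- report_quantified()
  dir <- withr::local_tempdir()
  spec <- report_spec("S02", window = 3, comparators = c("guideline-target", "all-store-average"))
  build_report(spec, q, file = file.path(dir, "a.html"))
  build_report(spec, q, file = file.path(dir, "b.html"))
  expect_equal(tools::md5sum(file.path(dir, "a.html"))[[1]],
               tools::md5sum(file.path(dir, "b.html"))[[1]])
})

test_that("a store with no data renders no-data panels, not an error", {
  q <- report_quantified()
  out <- build_report(report_spec("S99", selected_indicators = "fruit"), q,
                      file = file.path(withr::local_tempdir(), "r.html"))
  payload <- attr(out, "payload")
  expect_equal(payload$indicators$fruit$status, "no_data")
})

test_that("unknown indicator selections fail with the valid keys listed", {
  q <- report_quantified()
  err <- expect_error(
    build_report(report_spec("S01", selected_indicators = "sausages"), q,
                 file = tempfile(fileext = ".html")),
    class = "s2s_unknown_indicator"
  )
  expect_match(conditionMessage(err), "fruit")
})

test_that("user targets override guideline targets when selected", {
  q <- report_quantified()
  ut <- default_targets()
  ut$target[ut$group == "fruit"] <- 9
  out <- build_report(
    report_spec("S01", comparators = c("user-target"), user_targets = ut,
                selected_indicators = "fruit"),
    q, file = file.path(withr::local_tempdir(), "r.html")
  )
  expect_equal(attr(out, "payload")$indicators$fruit$target, 9)
})

test_that("ggplot builders return valid plots", {
  q <- report_quantified()
  ind <- compute_indicators(q)
  p1 <- plot_trend(ind, "fruit")
  p2 <- plot_trend(ind, "unhealthy_foods", chart = "bar")
  p3 <- plot_gauge(ind, "S01")
  p4 <- ggplot2::autoplot(ind)
  for (p in list(p1, p2, p3, p4)) {
    expect_s3_class(p, "ggplot")
    built <- ggplot2::ggplot_build(p)
    expect_gt(length(built$data), 0)
  }
})
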