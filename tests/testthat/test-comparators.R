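three_store_quantified <- function() {
  # S01 and S02 have ordinary baskets; S03 has a zero-unit row, so its
  # period exists but the indicator is undefined
  fx <- generate_reference_fixture()
  sales <- dplyr::bind_rows(
    sales_row("S01", product = "P_APPLE", units = 2),
    sales_row("S01", product = "P_COLA", units = 4),
    sales_row("S02", product = "P_APPLE", units = 6),
    sales_row("S02", product = "P_COLA", units = 4),
    sales_row("S03", product = "P_APPLE", units = 0)
  )
  link_sales(sales, fx$catalog, fx$reference)
}

test_that("all-store average is the unweighted mean over defined stores", {
  ind <- compute_indicators(three_store_quantified())
  avg <- all_store_average(ind, "fruit")
  rows <- tibble::as_tibble(ind)
  v <- rows$value[rows$level == "group" & rows$indicator == "fruit"]
  v <- v[!is.na(v)]
  expect_equal(avg$value, mean(v))
  expect_equal(avg$n_stores, 2)  # S03 undefined, omitted

  single <- compute_indicators(
    three_store_quantified()[three_store_quantified()$store_id == "S01", ])
  a1 <- all_store_average(single, "fruit")
  expect_equal(a1$n_stores, 1)
})

test_that("store order does not change the average", {
  q <- three_store_quantified()
  ind1 <- compute_indicators(q)
  ind2 <- compute_indicators(q[rev(seq_len(nrow(q))), ])
  expect_equal(all_store_average(ind1, "unhealthy_foods"),
               all_store_average(ind2, "unhealthy_foods"))
})

test_that("energy-weighted averaging is available behind a flag", {
  ind <- compute_indicators(three_store_quantified())
  unweighted <- all_store_average(ind, "fruit")
  weighted <- all_store_average(ind, "fruit", weighted = TRUE)
  totals <- attr(ind, "totals")
  rows <- tidy(ind) |> dplyr::filter(level == "group", indicator == "fruit") |>
    dplyr::left_join(totals, by = c("store_id", "period")) |>
    dplyr::filter(!is.na(value))
  expect_equal(weighted$value, sum(rows$value * rows$energy_kj) / sum(rows$energy_kj))
  expect_false(isTRUE(all.equal(weighted$value, unweighted$value)))
})

test_that("unknown indicators raise an input error", {
  ind <- compute_indicators(three_store_quantified())
  expect_error(all_store_average(ind, "sausages"), class = "s2s_input_error")
})

test_that("trend windows return the most recent periods in order, with gaps", {
  fx <- generate_reference_fixture()
  spec <- scenario_spec(n_stores = 1, n_weeks = 52, noise = 0, store_scale_sigma = 0,
                        seed = 31, start_date = as.Date("2023-01-02"))
  sales <- generate_sales(spec, fx)
  # remove one mid-year month entirely to create a gap
  sales <- sales[format(sales$week_start, "%Y-%m") != "2023-06", ]
  q <- link_sales(sales, fx$catalog, fx$reference)

  tr6 <- trend_series(q, "S01", "fruit", window = 6)
  expect_equal(nrow(tr6), 6)
  expect_true(!is.unsorted(tr6$period_start))

  tr_all <- trend_series(q, "S01", "fruit", window = 12)
  expect_true("2023-06" %in% tr_all$period)
  expect_true(is.na(tr_all$value[tr_all$period == "2023-06"]))

  expect_message(tr_big <- trend_series(q, "S01", "fruit", window = 99),
                 "exceeds available history")
  expect_true(attr(tr_big, "truncated"))
})

test_that("quarterly values are recomputed from weekly records, not averaged months", {
  fx <- generate_reference_fixture()
  # two months in one quarter with very different baskets and volumes
  sales <- dplyr::bind_rows(
    sales_row("S01", "2023-01-02", "P_APPLE", units = 20),
    sales_row("S01", "2023-02-06", "P_COLA", units = 40)
  )
  q <- link_sales(sales, fx$catalog, fx$reference)
  quarterly <- trend_series(q, "S01", "fruit", window = 1, period_unit = "quarter")
  monthly <- compute_indicators(q, "month")
  mrows <- tibble::as_tibble(monthly)
  mvals <- mrows$value[mrows$level == "group" & mrows$indicator == "fruit"]

  oracle <- oracle_indicators(sales, fx$catalog, tibble::as_tibble(fx$reference), "S01")
  expect_equal(quarterly$value, unname(oracle$groups[["fruit"]]), tolerance = 1e-9)
  # the mean of monthly ratios is a different (wrong) quantity here
  expect_false(isTRUE(all.equal(quarterly$value, mean(mvals))))
})

test_that("a quarterly window of 4 covers a year of monthly data", {
  fx <- generate_reference_fixture()
  spec <- scenario_spec(n_stores = 1, n_weeks = 52, noise = 0.1, seed = 33,
                        start_date = as.Date("2023-01-02"))
  q <- link_sales(generate_sales(spec, fx), fx$catalog, fx$reference)
  tr <- trend_series(q, "S01", "unhealthy_foods", window = 4, period_unit = "quarter")
  expect_equal(nrow(tr), 4)
  expect_equal(tr$period, c("2023-Q1", "2023-Q2", "2023-Q3", "2023-Q4"))
})
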