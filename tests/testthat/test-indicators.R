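quantify_tiny <- function(sales) {
  link_sales(sales, tiny_catalog(), validate_reference(tiny_reference_df()))
}

test_that("total energy is additive and empty periods are flagged", {
  q <- quantify_tiny(dplyr::bind_rows(
    sales_row(product = "P_COLA", units = 2),          # 1350 kJ
    sales_row(product = "P_CARROT", units = 0.65)      # 650 g x 150/100 = 975 kJ
  ))
  te <- total_energy(q)
  expect_equal(te$energy_kj, 1350 + 975)
  expect_false(te$no_sales)
  empty <- total_energy(q[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("serve numerators follow the serve factors and the 600 kJ discretionary serve", {
  q <- quantify_tiny(dplyr::bind_rows(
    sales_row(product = "P_APPLE", units = 2),   # 300 g fresh apple
    sales_row(product = "P_COLA", units = 2)     # 750 mL cola at 180 kJ/100 mL
  ))
  raw <- serves_by_group(q, "month")
  val <- function(lvl, key) raw$raw_serves[raw$level == lvl & raw$indicator == key]
  expect_equal(val("group", "fruit"), 300 * 0.667 / 100)   # ~2 serves at 150 g/serve
  expect_equal(val("group", "unhealthy_foods"), 1350 / 600) # 2.25 serves
  expect_equal(val("subgroup", "sugar_sweetened_beverages"), 2.25)
  expect_equal(val("group", "vegetables"), 0)
})

test_that("adding a discretionary item never changes five-group numerators", {
  fx <- generate_reference_fixture()
  base <- dplyr::bind_rows(
    sales_row(product = "P_APPLE", units = 3),
    sales_row(product = "P_CARROT", units = 1),
    sales_row(product = "P_WGBREAD", units = 2)
  )
  with_disc <- dplyr::bind_rows(base, sales_row(product = "P_HOTCHIPS", units = 4))
  raw0 <- serves_by_group(link_sales(base, fx$catalog, fx$reference), "month")
  raw1 <- serves_by_group(link_sales(with_disc, fx$catalog, fx$reference), "month")
  for (g in names(five_food_groups())) {
    expect_equal(raw1$raw_serves[raw1$level == "group" & raw1$indicator == g],
                 raw0$raw_serves[raw0$level == "group" & raw0$indicator == g])
  }
  # the denominator does change (hot chips carry energy)
  expect_gt(total_energy(link_sales(with_disc, fx$catalog, fx$reference))$energy_kj,
            total_energy(link_sales(base, fx$catalog, fx$reference))$energy_kj)
})

test_that("energy normalisation scales to the reference person-day", {
  expect_equal(normalize_to_person_day(4, 17800), 2)
  expect_equal(normalize_to_person_day(2, 8900), 2)
  expect_equal(normalize_to_person_day(3, 26700), 1)
  expect_true(is.na(normalize_to_person_day(3, 0)))
})

test_that("indicators are invariant to uniform scaling of the basket", {
  fx <- generate_reference_fixture()
  spec <- scenario_spec(n_stores = 2, n_weeks = 6, noise = 0.2, seed = 21)
  sales <- generate_sales(spec, fx)
  base <- compute_indicators(link_sales(sales, fx$catalog, fx$reference))
  for (k in c(0.5, 2, 10)) {
    scaled <- sales
    scaled$units_sold <- scaled$units_sold * k
    got <- compute_indicators(link_sales(scaled, fx$catalog, fx$reference))
    expect_equal(got$value, base$value, tolerance = 1e-9)
  }
})

test_that("pipeline matches the brute-force per-record oracle on small baskets", {
  fx <- generate_reference_fixture()
  set.seed(301)
  products <- fx$catalog$product_id
  for (rep in 1:25) {
    n <- sample(3:10, 1)
    sales <- tibble::tibble(
      store_id = "S01", week_start = as.Date("2023-01-02"),
      product_id = sample(products, n, replace = TRUE),
      units_sold = round(stats::runif(n, 0.5, 8), 3),
      dollar_value = 1
    )
    sales <- dplyr::summarise(
      dplyr::group_by(sales, store_id, week_start, product_id),
      units_sold = sum(units_sold), dollar_value = sum(dollar_value), .groups = "drop"
    )
    oracle <- oracle_indicators(sales, fx$catalog, tibble::as_tibble(fx$reference), "S01")
    ind <- compute_indicators(link_sales(sales, fx$catalog, fx$reference))
    rows <- tibble::as_tibble(ind)
    if (is.null(oracle)) {
      expect_true(nrow(rows) == 0 || all(is.na(rows$value)))
      next
    }
    for (g in names(oracle$groups)) {
      got <- rows$value[rows$level == "group" & rows$indicator == g]
      expect_equal(got, unname(oracle$groups[[g]]), tolerance = 1e-9)
    }
    for (sgrp in names(oracle$subgroups)) {
      got <- rows$value[rows$level == "subgroup" & rows$indicator == sgrp]
      expect_equal(got, unname(oracle$subgroups[[sgrp]]), tolerance = 1e-9)
    }
  }
})

test_that("subgroup serves sum to at most the Unhealthy Foods value", {
  fx <- generate_reference_fixture()
  spec <- scenario_spec(n_stores = 2, n_weeks = 4, unsubgrouped_share = 0.2, seed = 5)
  ind <- compute_indicators(link_sales(generate_sales(spec, fx), fx$catalog, fx$reference))
  rows <- tibble::as_tibble(ind)
  per_sp <- split(rows, paste(rows$store_id, rows$period))
  for (chunk in per_sp) {
    sub_sum <- sum(chunk$value[chunk$level == "subgroup"])
    unh <- chunk$value[chunk$level == "group" & chunk$indicator == "unhealthy_foods"]
    expect_lte(sub_sum, unh + 1e-9)
  }
})

test_that("discretionary coverage is the subgrouped share of discretionary energy", {
  # 877 kJ subgrouped of 1000 kJ discretionary -> 0.877
  ref <- validate_reference(dplyr::bind_rows(
    ref_row("SSB", 100, disc = TRUE, sub = "sugar_sweetened_beverages"),
    ref_row("MISC", 100, disc = TRUE)
  ))
  cat_df <- tibble::tibble(
    product_id = c("P_SSB", "P_MISC"), description = c("a", "b"),
    pack_size_g = c(100, 100), food_code = c("SSB", "MISC")
  )
  sales <- dplyr::bind_rows(
    sales_row(product = "P_SSB", units = 8.77),
    sales_row(product = "P_MISC", units = 1.23)
  )
  cov <- discretionary_coverage(link_sales(sales, cat_df, ref))
  expect_equal(cov$covered_fraction, 0.877)

  all_sub <- discretionary_coverage(link_sales(
    sales_row(product = "P_SSB", units = 2), cat_df, ref))
  expect_equal(all_sub$covered_fraction, 1)

  none <- discretionary_coverage(link_sales(sales[0, ], cat_df, ref))
  expect_true(is.na(none$covered_fraction))
  expect_true(none$undefined)
})

test_that("dollar shares are ratios over classified food dollars", {
  q <- quantify_tiny(dplyr::bind_rows(
    sales_row(product = "P_APPLE", units = 1, dollars = 30),
    sales_row(product = "P_COLA", units = 1, dollars = 70)
  ))
  sh <- dollar_share_by_group(q)
  expect_equal(sh$share[sh$group == "fruit"], 0.30)
  expect_equal(sh$share[sh$group == "unhealthy_foods"], 0.70)
  expect_equal(sum(sh$share), 1, tolerance = 1e-9)
})

test_that("indicator sets round-trip through CSV and JSON", {
  fx <- generate_reference_fixture()
  spec <- scenario_spec(n_stores = 2, n_weeks = 5, seed = 9)
  ind <- compute_indicators(link_sales(generate_sales(spec, fx), fx$catalog, fx$reference))
  for (ext in c("csv", "json")) {
    path <- file.path(withr::local_tempdir(), paste0("ind.", ext))
    write_indicators(ind, path)
    back <- read_indicators(path, period_unit = "month")
    expect_equal(tibble::as_tibble(back), tibble::as_tibble(ind))
    expect_equal(attr(back, "totals")$energy_kj, attr(ind, "totals")$energy_kj)
  }
})

test_that("tidy and glance summarise indicator sets", {
  fx <- generate_reference_fixture()
  spec <- scenario_spec(n_stores = 2, n_weeks = 5, seed = 13)
  ind <- compute_indicators(link_sales(generate_sales(spec, fx), fx$catalog, fx$reference))
  td <- tidy(ind, against = default_targets())
  expect_true(all(c("target", "direction", "meets_target") %in% names(td)))
  expect_true(all(td$level == "group"))
  gl <- glance(ind)
  expect_equal(gl$n_stores, 2)
  expect_equal(gl$period_unit, "month")
})
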