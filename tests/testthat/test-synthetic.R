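test_that("the built-in fixture spans the whole scheme and passes validation", {
  fx <- generate_reference_fixture()
  ref <- tibble::as_tibble(fx$reference)
  expect_gte(nrow(ref), 40)
  expect_equal(attr(fx$reference, "n_rejected"), 0)
  cls <- classify_foods(fx$reference)
  expect_setequal(unique(cls$group[!cls$unclassifiable]), names(food_groups()))
  expect_setequal(unique(ref$tier), unname(healthiness_tiers()))
  subs <- unique(ref$unhealthy_subgroup[!is.na(ref$unhealthy_subgroup)])
  expect_setequal(subs, default_scheme()$subgroups$subgroup_id)   # 13/13
  expect_true(any(ref$is_alcohol))
  expect_true(any(is.na(fx$catalog$food_code)))                   # a non-food product
  # every discretionary record has zeroed five-group factors
  disc <- ref[ref$is_discretionary, ]
  sf <- as.matrix(disc[grep("^serves_", names(disc))])
  expect_true(all(sf == 0))
})

test_that("noise-free scenarios are recovered exactly by the pipeline", {
  fx <- generate_reference_fixture()
  spec <- scenario_spec(n_stores = 2, n_weeks = 3, noise = 0, store_scale_sigma = 0,
                        seed = 51)
  sales <- generate_sales(spec, fx)
  truth <- attr(sales, "ground_truth")
  ind <- compute_indicators(link_sales(sales, fx$catalog, fx$reference))
  joined <- dplyr::inner_join(tibble::as_tibble(ind), truth,
                              by = c("level", "indicator"), suffix = c("", ".truth"))
  expect_gt(nrow(joined), 0)
  expect_equal(joined$value, joined$value.truth, tolerance = 1e-6)
  # the group ground truth is the requested target vector itself
  g <- truth[truth$level == "group", ]
  expect_equal(stats::setNames(g$value, g$indicator)[names(spec$target_indicators)],
               spec$target_indicators)
})

test_that("equal seeds give byte-identical files; different seeds differ", {
  fx <- generate_reference_fixture()
  spec <- scenario_spec(n_stores = 2, n_weeks = 3, noise = 0.2, seed = 52)
  d1 <- file.path(withr::local_tempdir(), "a")
  d2 <- file.path(withr::local_tempdir(), "b")
  write_scenario_files(spec, fx, d1)
  write_scenario_files(spec, fx, d2)
  expect_equal(tools::md5sum(file.path(d1, "sales.csv"))[[1]],
               tools::md5sum(file.path(d2, "sales.csv"))[[1]])
  s3 <- generate_sales(scenario_spec(n_stores = 2, n_weeks = 3, noise = 0.2, seed = 53), fx)
  expect_false(identical(s3$units_sold,
                         generate_sales(spec, fx)$units_sold))
})

test_that("whole-week noise leaves indicators on target; product jitter centres on it", {
  fx <- generate_reference_fixture()
  noisy <- scenario_spec(n_stores = 1, n_weeks = 52, noise = 0.1, seed = 54,
                         target_indicators = c(fruit = 1, vegetables = 2,
                                               breads_cereals = 4, meat_fish_eggs = 2,
                                               dairy = 1, unhealthy_foods = 7))
  ind <- compute_indicators(link_sales(generate_sales(noisy, fx),
                                       fx$catalog, fx$reference))
  rows <- tibble::as_tibble(ind)
  unh <- rows$value[rows$level == "group" & rows$indicator == "unhealthy_foods"]
  expect_equal(unh, rep(7, length(unh)), tolerance = 1e-9)

  jittered <- scenario_spec(n_stores = 1, n_weeks = 52, noise = 0.1,
                            product_jitter = 0.1, seed = 55,
                            target_indicators = c(fruit = 1, vegetables = 2,
                                                  breads_cereals = 4, meat_fish_eggs = 2,
                                                  dairy = 1, unhealthy_foods = 7))
  indj <- compute_indicators(link_sales(generate_sales(jittered, fx),
                                        fx$catalog, fx$reference), "week")
  rowsj <- tibble::as_tibble(indj)
  unhj <- rowsj$value[rowsj$level == "group" & rowsj$indicator == "unhealthy_foods"]
  expect_gt(stats::sd(unhj), 0)
  # annual mean within 3 Monte-Carlo standard errors of the target
  expect_lt(abs(mean(unhj) - 7), 3 * stats::sd(unhj) / sqrt(length(unhj)))
})

test_that("unachievable scenarios fail with the gap named", {
  fx <- generate_reference_fixture()
  # remove all dairy foods, then demand dairy serves
  no_dairy <- tibble::as_tibble(fx$reference)
  no_dairy <- no_dairy[no_dairy$serves_dairy_per_100g == 0, ]
  fx2 <- list(reference = validate_reference(no_dairy), catalog = fx$catalog)
  spec <- scenario_spec(n_stores = 1, n_weeks = 1, seed = 56)
  err <- expect_error(generate_sales(spec, fx2), class = "s2s_generation_error")
  expect_match(conditionMessage(err), "dairy")

  # energy-infeasible target mix: unhealthy target beyond the energy budget
  too_much <- scenario_spec(
    n_stores = 1, n_weeks = 1, seed = 57,
    target_indicators = c(fruit = 2, vegetables = 5, breads_cereals = 5.5,
                          meat_fish_eggs = 2.5, dairy = 2.5, unhealthy_foods = 20)
  )
  expect_error(generate_sales(too_much, fx), class = "s2s_generation_error")
})

test_that("the feasible unhealthy range brackets achievable targets", {
  fx <- generate_reference_fixture()
  five <- c(fruit = 1, vegetables = 2, breads_cereals = 4.5,
            meat_fish_eggs = 2, dairy = 1)
  rng <- feasible_unhealthy_range(fx, five)
  expect_lt(rng[1], rng[2])
  mid <- mean(rng)
  spec <- scenario_spec(n_stores = 1, n_weeks = 1, noise = 0, store_scale_sigma = 0,
                        seed = 58, target_indicators = c(five, unhealthy_foods = mid))
  sales <- generate_sales(spec, fx)
  truth <- attr(sales, "ground_truth")
  expect_equal(truth$value[truth$level == "group" & truth$indicator == "unhealthy_foods"],
               mid, tolerance = 1e-9)
})

test_that("scenario specs round-trip through YAML and JSON", {
  spec <- scenario_spec(n_stores = 4, n_weeks = 8, noise = 0.12,
                        unsubgrouped_share = 0.1, seed = 59)
  for (ext in c("yaml", "json")) {
    path <- file.path(withr::local_tempdir(), paste0("sc.", ext))
    write_scenario(spec, path)
    back <- read_scenario(path)
    expect_equal(back, spec)
  }
})

test_that("the unsubgrouped share controls discretionary coverage", {
  fx <- generate_reference_fixture()
  spec <- scenario_spec(n_stores = 2, n_weeks = 2, unsubgrouped_share = 0.123,
                        seed = 60)
  q <- link_sales(generate_sales(spec, fx), fx$catalog, fx$reference)
  cov <- discretionary_coverage(q)
  expect_equal(cov$covered_fraction, 1 - 0.123, tolerance = 1e-9)
  per_store <- discretionary_coverage(q, by_store = TRUE)
  expect_equal(nrow(per_store), 3)  # 2 stores + pooled
})
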