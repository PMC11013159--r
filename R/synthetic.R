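# Synthetic point-of-sale streams with known ground-truth indicators.
#
# Real remote-store sales data are restricted, so the generator emulates
# them: a food reference and product catalogue spanning the full
# classification scheme, and weekly multi-store sales whose noise-free
# indicator values equal a requested target exactly. Construction works
# backwards from the targets: fix a one-person-day basket of 8 900 kJ,
# allocate discretionary energy at 600 kJ/serve, then split each food
# group's serves across that group's foods so the group serve totals and the
# total energy close simultaneously (the within-group split between low- and
# high-energy-per-serve foods is the free variable). Weekly volume noise is
# lognormal and scales whole store-weeks; because the indicator is scale
# invariant this leaves per-period indicators exactly on target, while the
# optional per-product jitter perturbs them around it.

#' Scenario specification for the synthetic generator
#'
#' Defaults emulate the surveillance setting the tool is built for: 31
#' community stores over 52 weeks, a purchasing pattern with discretionary
#' intake well above its guideline upper limit and fruit/vegetables below
#' their targets, and ~15% week-to-week volume variability.
#'
#' @param n_stores number of stores (>= 1).
#' @param n_weeks number of sales weeks (>= 1).
#' @param target_indicators named vector of desired serves/person/day for the
#'   six group keys (see [food_groups()]).
#' @param noise lognormal sigma of the multiplicative weekly volume noise
#'   (0 = noise-free).
#' @param product_jitter lognormal sigma of optional per-product volume
#'   jitter; unlike whole-week noise this perturbs indicator values.
#' @param unsubgrouped_share fraction of discretionary energy routed to a
#'   discretionary food carrying no subgroup, so that named subgroups cover
#'   `1 - unsubgrouped_share` of discretionary energy.
#' @param weekly_energy_kj mean classified energy per store-week (default
#'   ~700 person-days at 8 900 kJ).
#' @param store_scale_sigma lognormal sigma of the between-store size spread.
#' @param start_date first week-start date (a Monday).
#' @param seed integer seed fixing the whole stream.
#' @param mix_breadth fraction of each group's serves spread equally over all
#'   of the group's foods (the rest goes to the low/high energy-per-serve
#'   foods that close the energy balance).
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(n_stores = 31, n_weeks = 52,
                          target_indicators = c(
                            fruit = 1.0, vegetables = 2.0, breads_cereals = 4.5,
                            meat_fish_eggs = 2.0, dairy = 1.0, unhealthy_foods = 6.0
                          ),
                          noise = 0.15, product_jitter = 0,
                          unsubgrouped_share = 0,
                          weekly_energy_kj = 700 * 8900,
                          store_scale_sigma = 0.4,
                          start_date = as.Date("2023-01-02"),
                          seed = 1L, mix_breadth = 0.5) {
  stopifnot(n_stores >= 1, n_weeks >= 1, noise >= 0, product_jitter >= 0,
            unsubgrouped_share >= 0, unsubgrouped_share < 1,
            weekly_energy_kj > 0, mix_breadth >= 0, mix_breadth < 1)
  missing_keys <- setdiff(names(food_groups()), names(target_indicators))
  if (length(missing_keys) > 0) {
    abort(glue::glue("target_indicators missing group(s): {paste(missing_keys, collapse = ', ')}"),
          class = "s2s_input_error")
  }
  if (any(target_indicators < 0)) {
    abort("target indicators must be >= 0", class = "s2s_input_error")
  }
  structure(
    list(
      n_stores = as.integer(n_stores), n_weeks = as.integer(n_weeks),
      target_indicators = target_indicators[names(food_groups())],
      noise = noise, product_jitter = product_jitter,
      unsubgrouped_share = unsubgrouped_share,
      weekly_energy_kj = weekly_energy_kj,
      store_scale_sigma = store_scale_sigma,
      start_date = as.Date(start_date), seed = as.integer(seed),
      mix_breadth = mix_breadth
    ),
    class = "scenario_spec"
  )
}

#' Read / write a scenario specification (YAML or JSON)
#'
#' @param path file path; format chosen by extension.
#' @export
read_scenario <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  doc$target_indicators <- unlist(doc$target_indicators)
  if (!is.null(doc$start_date)) doc$start_date <- as.Date(doc$start_date)
  do.call(scenario_spec, doc)
}

#' @rdname read_scenario
#' @param spec a `scenario_spec`.
#' @export
write_scenario <- function(spec, path) {
  doc <- unclass(spec)
  doc$start_date <- format(doc$start_date)
  doc$target_indicators <- as.list(doc$target_indicators)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(doc, path)
  } else {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Built-in food reference and catalogue fixture
#'
#' A synthetic but nutritionally realistic reference of 42 foods spanning all
#' six food groups, all three tiers and all 13 default unhealthy subgroups,
#' plus an alcohol-flagged beer and (in the catalogue) a non-food product.
#' Encodes the shipped classification stances: 100% fruit juice and dried
#' fruit are Less Healthy Choices within Fruit, and high-fibre white bread is
#' a Less Healthy Choice alongside regular white bread. Beverages are
#' tabulated per 100 mL. Serve factors follow Australian Dietary Guidelines
#' serve sizes (about 150 g fresh fruit, 75 g vegetables, 40 g bread, 250 mL
#' milk, ...); energy densities are typical food-composition values.
#'
#' @param scheme a `food_scheme`; subgroup ids are validated against it.
#' @return List with `reference` (a `food_reference`) and `catalog` (tibble).
#' @export
generate_reference_fixture <- function(scheme = default_scheme()) {
  f <- function(code, desc, ed, fr = 0, vg = 0, gr = 0, mt = 0, dy = 0,
                disc = FALSE, sub = NA_character_, tier, alc = FALSE, pack) {
    tibble(
      food_code = code, description = desc, energy_density_kj_per_100g = ed,
      serves_fruit_per_100g = fr, serves_veg_per_100g = vg,
      serves_grains_per_100g = gr, serves_meat_per_100g = mt,
      serves_dairy_per_100g = dy, is_discretionary = disc,
      unhealthy_subgroup = sub, tier = tier, is_alcohol = alc, pack_size_g = pack
    )
  }
  best <- healthiness_tiers()[["best_choice"]]
  less <- healthiness_tiers()[["less_healthy_choice"]]
  unh <- healthiness_tiers()[["unhealthy_foods"]]

  rows <- bind_rows(
    # Fruit (1 serve ~ 150 g fresh / 125 mL juice / 30 g dried)
    f("F_APPLE", "Apples, fresh", 250, fr = 0.667, tier = best, pack = 150),
    f("F_BANANA", "Bananas, fresh", 380, fr = 0.667, tier = best, pack = 120),
    f("F_ORANGE", "Oranges, fresh", 190, fr = 0.667, tier = best, pack = 130),
    f("F_JUICE", "Orange juice, 100% (per 100 mL)", 180, fr = 0.8, tier = less, pack = 1000),
    f("F_DRIED", "Dried fruit mix", 1350, fr = 3.333, tier = less, pack = 250),
    # Vegetables (1 serve ~ 75 g)
    f("F_CARROT", "Carrots, fresh", 150, vg = 1.333, tier = best, pack = 1000),
    f("F_POTATO", "Potatoes, fresh", 290, vg = 1.333, tier = best, pack = 2000),
    f("F_FROZVEG", "Frozen mixed vegetables", 180, vg = 1.333, tier = best, pack = 500),
    f("F_TOMCAN", "Tomatoes, canned", 100, vg = 1.333, tier = best, pack = 400),
    f("F_LETTUCE", "Lettuce, fresh", 60, vg = 1.333, tier = best, pack = 300),
    # Breads and cereals (1 serve ~ 40 g bread, 30 g oats/cereal, 54 g dry rice)
    f("F_WGBREAD", "Bread, wholegrain", 980, gr = 2.5, tier = best, pack = 700),
    f("F_WBREAD", "Bread, white", 1000, gr = 2.5, tier = less, pack = 650),
    f("F_HFWBREAD", "Bread, white, high-fibre", 1010, gr = 2.5, tier = less, pack = 700),
    f("F_OATS", "Rolled oats", 1600, gr = 3.333, tier = best, pack = 750),
    f("F_RICE", "Rice, white, dry", 1530, gr = 1.85, tier = less, pack = 1000),
    f("F_BRICE", "Rice, brown, dry", 1550, gr = 1.85, tier = best, pack = 1000),
    f("F_CEREAL", "Breakfast cereal, flaked corn", 1550, gr = 3.333, tier = less, pack = 500),
    # Meat, fish and eggs (1 serve ~ 65 g cooked lean meat, 2 eggs, 100 g fish)
    f("F_EGGS", "Eggs, dozen", 550, mt = 0.833, tier = best, pack = 600),
    f("F_TUNA", "Tuna, canned in springwater", 440, mt = 1.0, tier = best, pack = 185),
    f("F_CHICKEN", "Chicken breast", 470, mt = 1.538, tier = best, pack = 500),
    f("F_BEEF", "Beef mince, lean", 530, mt = 1.538, tier = best, pack = 500),
    f("F_MINCE", "Beef mince, regular", 700, mt = 1.538, tier = less, pack = 500),
    # Dairy (1 serve ~ 250 mL milk, 200 g yoghurt, 40 g cheese)
    f("F_MILKLF", "Milk, reduced fat, UHT (per 100 mL)", 150, dy = 0.4, tier = best, pack = 1000),
    f("F_MILK", "Milk, full cream, UHT (per 100 mL)", 270, dy = 0.4, tier = less, pack = 1000),
    f("F_YOG", "Yoghurt, natural", 350, dy = 0.5, tier = best, pack = 1000),
    f("F_CHEESE", "Cheese, cheddar", 1650, dy = 2.5, tier = less, pack = 500),
    # Mixed dish: contributes to several groups; primary group by largest factor
    f("F_LASAGNE", "Frozen beef lasagne", 600, vg = 0.4, gr = 0.5, mt = 0.3, dy = 0.2,
      tier = less, pack = 400),
    # Discretionary: one food per default subgroup (serve factors all zero)
    f("F_COLA", "Cola soft drink (per 100 mL)", 180, disc = TRUE,
      sub = "sugar_sweetened_beverages", tier = unh, pack = 375),
    f("F_ENERGY", "Energy drink (per 100 mL)", 195, disc = TRUE,
      sub = "energy_drinks_cordials", tier = unh, pack = 500),
    f("F_LOLLIES", "Lollies, mixed", 1550, disc = TRUE, sub = "confectionery",
      tier = unh, pack = 200),
    f("F_BISCUIT", "Biscuits, sweet", 2000, disc = TRUE, sub = "sweet_biscuits",
      tier = unh, pack = 250),
    f("F_MUFFIN", "Muffins, chocolate", 1600, disc = TRUE, sub = "cakes_muffins_desserts",
      tier = unh, pack = 400),
    f("F_PIE", "Meat pie", 1100, disc = TRUE, sub = "savoury_pastries_pies",
      tier = unh, pack = 175),
    f("F_CRISPS", "Potato crisps", 2200, disc = TRUE, sub = "savoury_snacks",
      tier = unh, pack = 175),
    f("F_BACON", "Bacon rashers", 1100, disc = TRUE, sub = "processed_meats",
      tier = unh, pack = 250),
    f("F_FRIEDCHK", "Takeaway fried chicken", 1200, disc = TRUE, sub = "takeaway_foods",
      tier = unh, pack = 300),
    f("F_HOTCHIPS", "Hot chips, deep fried", 1000, disc = TRUE, sub = "fried_potato_products",
      tier = unh, pack = 300),
    f("F_ICECREAM", "Ice cream, vanilla", 900, disc = TRUE, sub = "ice_cream_frozen_desserts",
      tier = unh, pack = 2000),
    f("F_SUGAR", "Sugar, white", 1700, disc = TRUE, sub = "table_sugar_sweeteners",
      tier = unh, pack = 1000),
    f("F_MAYO", "Mayonnaise", 2500, disc = TRUE, sub = "sauces_spreads_condiments",
      tier = unh, pack = 400),
    # Discretionary without a named subgroup (long-tail discretionary energy)
    f("F_DISCMISC", "Mixed discretionary hamper", 1500, disc = TRUE,
      sub = NA_character_, tier = unh, pack = 500),
    # Alcohol: flagged for wholesale exclusion
    f("F_BEER", "Beer, full strength (per 100 mL)", 150, disc = TRUE,
      sub = NA_character_, tier = unh, alc = TRUE, pack = 375)
  )

  reference <- validate_reference(select(rows, -"pack_size_g"), scheme)
  if (attr(reference, "n_rejected") > 0) {
    abort("internal fixture failed validation", class = "s2s_internal_error")
  }
  catalog <- bind_rows(
    rows %>%
      mutate(product_id = paste0("P_", sub("^F_", "", .data$food_code))) %>%
      select("product_id", "description", "pack_size_g", "food_code"),
    tibble(product_id = "P_SOAP", description = "Laundry soap, bar",
           pack_size_g = 125, food_code = NA_character_)
  )
  list(reference = reference, catalog = catalog)
}

# per-food energy per serve (kJ) for single-group, non-discretionary foods
group_food_economics <- function(reference) {
  sfc <- serve_factor_cols()
  ref <- as_tibble(reference) %>% filter(!.data$is_discretionary, !.data$is_alcohol)
  sf_mat <- as.matrix(ref[unname(sfc)])
  single <- rowSums(sf_mat > 0) == 1
  ref <- ref[single, , drop = FALSE]
  sf_mat <- sf_mat[single, , drop = FALSE]
  gidx <- apply(sf_mat, 1, function(x) which(x > 0))
  tibble(
    food_code = ref$food_code,
    group = names(sfc)[gidx],
    serve_factor = sf_mat[cbind(seq_len(nrow(sf_mat)), gidx)],
    energy_density = ref$energy_density_kj_per_100g,
    tier = ref$tier
  ) %>%
    mutate(energy_per_serve = .data$energy_density / .data$serve_factor)
}

#' Feasible Unhealthy Foods target range for a fixture
#'
#' Given five-food-group targets, the achievable Unhealthy Foods target is
#' bounded by the energy budget: five-group foods carry energy per serve, so
#' high five-group targets leave less energy headroom for discretionary
#' serves (and vice versa).
#'
#' @param fixture list from [generate_reference_fixture()].
#' @param five_targets named serves/person/day for the five food groups.
#' @param mix_breadth see [scenario_spec()].
#' @param discretionary_serve_kj energy per discretionary serve.
#' @param reference_energy basket energy per person-day.
#' @return Numeric `c(min, max)` achievable Unhealthy Foods serves/person/day.
#' @export
feasible_unhealthy_range <- function(fixture, five_targets, mix_breadth = 0.5,
                                     discretionary_serve_kj = 600,
                                     reference_energy = 8900) {
  econ <- group_food_economics(fixture$reference)
  rng <- econ %>%
    group_by(.data$group) %>%
    summarise(
      lo = min(.data$energy_per_serve), hi = max(.data$energy_per_serve),
      m = mean(.data$energy_per_serve), .groups = "drop"
    )
  g <- names(five_food_groups())
  rng <- rng[match(g, rng$group), ]
  s <- five_targets[g]
  e_min <- sum(s * (mix_breadth * rng$m + (1 - mix_breadth) * rng$lo))
  e_max <- sum(s * (mix_breadth * rng$m + (1 - mix_breadth) * rng$hi))
  c(
    max(0, (reference_energy - e_max) / discretionary_serve_kj),
    max(0, (reference_energy - e_min) / discretionary_serve_kj)
  )
}

# Solve the one-person-day unit basket: grams per food per 8 900 kJ of
# classified energy, with group serve totals and total energy exact.
solve_unit_basket <- function(spec, fixture, discretionary_serve_kj = 600,
                              reference_energy = 8900) {
  targets <- spec$target_indicators
  econ <- group_food_economics(fixture$reference)
  groups <- names(five_food_groups())
  absent <- groups[!(groups %in% econ$group) & targets[groups] > 0]
  if (length(absent) > 0) {
    abort(glue::glue("no foods available to supply group(s): {paste(absent, collapse = ', ')}"),
          class = "s2s_generation_error")
  }

  disc_energy <- targets[["unhealthy_foods"]] * discretionary_serve_kj
  e5_needed <- reference_energy - disc_energy
  if (e5_needed < 0) {
    abort("unhealthy_foods target exceeds the whole energy budget",
          class = "s2s_generation_error")
  }

  # serve allocation: mix_breadth spread equally, remainder on the lo/hi foods
  alloc <- list()
  base_energy <- 0
  for (g in groups) {
    s_g <- targets[[g]]
    if (s_g <= 0) next
    foods <- econ %>% filter(.data$group == g) %>% arrange(.data$energy_per_serve)
    eq <- s_g * spec$mix_breadth / nrow(foods)
    alloc[[g]] <- foods %>% mutate(serves = eq, group = g)
    base_energy <- base_energy + eq * sum(foods$energy_per_serve)
  }
  adj <- lapply(alloc, function(a) {
    lo <- a$energy_per_serve[1]; hi <- a$energy_per_serve[nrow(a)]
    s_adj <- sum(a$serves) / spec$mix_breadth * (1 - spec$mix_breadth)
    list(s_adj = s_adj, lo = lo, hi = hi, cap = s_adj * (hi - lo))
  })
  if (spec$mix_breadth == 0) {
    # degenerate: everything adjustable, equal-split part empty
    adj <- lapply(groups[targets[groups] > 0], function(g) {
      foods <- econ %>% filter(.data$group == g) %>% arrange(.data$energy_per_serve)
      list(s_adj = targets[[g]], lo = foods$energy_per_serve[1],
           hi = foods$energy_per_serve[nrow(foods)],
           cap = targets[[g]] * (foods$energy_per_serve[nrow(foods)] - foods$energy_per_serve[1]))
    })
    names(adj) <- groups[targets[groups] > 0]
  }
  deficit <- e5_needed - base_energy - sum(vapply(adj, function(a) a$s_adj * a$lo, double(1)))
  total_cap <- sum(vapply(adj, function(a) a$cap, double(1)))
  if (deficit < -1e-9 || deficit > total_cap + 1e-9) {
    rng <- feasible_unhealthy_range(fixture, targets[groups], spec$mix_breadth,
                                    discretionary_serve_kj, reference_energy)
    abort(glue::glue(
      "targets infeasible with this fixture: unhealthy_foods must lie in [{signif(rng[1], 4)}, {signif(rng[2], 4)}] given the five-group targets"),
      class = "s2s_generation_error")
  }
  deficit <- min(max(deficit, 0), total_cap)

  serves_tbl <- list()
  remaining <- deficit
  for (g in names(alloc)) {
    a <- alloc[[g]]; ad <- adj[[g]]
    take <- if (ad$cap > 0) min(remaining, ad$cap) else 0
    t_g <- if (ad$cap > 0) take / ad$cap else 0
    remaining <- remaining - take
    lo_i <- 1; hi_i <- nrow(a)
    extra <- rep(0, nrow(a))
    if (spec$mix_breadth > 0) {
      extra[lo_i] <- extra[lo_i] + ad$s_adj * (1 - t_g)
      extra[hi_i] <- extra[hi_i] + ad$s_adj * t_g
      a$serves <- a$serves + extra
    } else {
      a$serves <- 0
      a$serves[lo_i] <- ad$s_adj * (1 - t_g)
      a$serves[hi_i] <- a$serves[hi_i] + ad$s_adj * t_g
    }
    serves_tbl[[g]] <- a
  }
  five <- bind_rows(serves_tbl) %>%
    mutate(grams = .data$serves / .data$serve_factor * 100,
           energy = .data$grams * .data$energy_density / 100)

  # discretionary energy: equal split over subgrouped foods, optional share
  # to the unsubgrouped discretionary item
  disc_foods <- as_tibble(fixture$reference) %>%
    filter(.data$is_discretionary, !.data$is_alcohol)
  subbed <- disc_foods %>% filter(!is.na(.data$unhealthy_subgroup))
  unsubbed <- disc_foods %>% filter(is.na(.data$unhealthy_subgroup))
  if (disc_energy > 0 && nrow(subbed) == 0) {
    abort("no subgrouped discretionary foods available", class = "s2s_generation_error")
  }
  if (spec$unsubgrouped_share > 0 && nrow(unsubbed) == 0) {
    abort("unsubgrouped_share > 0 but fixture has no unsubgrouped discretionary food",
          class = "s2s_generation_error")
  }
  disc <- bind_rows(
    subbed %>% mutate(energy = disc_energy * (1 - spec$unsubgrouped_share) / nrow(subbed)),
    if (spec$unsubgrouped_share > 0) {
      unsubbed %>% mutate(energy = disc_energy * spec$unsubgrouped_share / nrow(unsubbed))
    }
  ) %>%
    mutate(grams = .data$energy / .data$energy_density_kj_per_100g * 100) %>%
    select("food_code", "tier", "unhealthy_subgroup", "grams", "energy")

  basket <- bind_rows(
    five %>% mutate(unhealthy_subgroup = NA_character_) %>%
      select("food_code", "group", "tier", "unhealthy_subgroup", "serves", "grams", "energy"),
    disc %>% mutate(group = "unhealthy_foods",
                    serves = .data$energy / discretionary_serve_kj) %>%
      select("food_code", "group", "tier", "unhealthy_subgroup", "serves", "grams", "energy")
  ) %>% filter(.data$grams > 0)

  tier_key <- setNames(names(healthiness_tiers()), unname(healthiness_tiers()))
  truth <- bind_rows(
    basket %>% group_by(indicator = .data$group) %>%
      summarise(value = sum(.data$serves), .groups = "drop") %>%
      tidyr::complete(indicator = names(food_groups()), fill = list(value = 0)) %>%
      mutate(level = "group"),
    basket %>% filter(!is.na(.data$unhealthy_subgroup)) %>%
      group_by(indicator = .data$unhealthy_subgroup) %>%
      summarise(value = sum(.data$serves), .groups = "drop") %>%
      tidyr::complete(indicator = default_scheme()$subgroups$subgroup_id,
                      fill = list(value = 0)) %>%
      mutate(level = "subgroup"),
    basket %>% group_by(indicator = unname(tier_key[.data$tier])) %>%
      summarise(value = sum(.data$serves), .groups = "drop") %>%
      tidyr::complete(indicator = names(healthiness_tiers()), fill = list(value = 0)) %>%
      mutate(level = "tier")
  ) %>% select("level", "indicator", "value")

  list(basket = basket, truth = truth)
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate weekly multi-store sales for a scenario
#'
#' Emits sales whose noise-free indicator values equal the scenario's target
#' indicators exactly in every period; whole-week lognormal noise preserves
#' them exactly too (the indicator is scale invariant), while per-product
#' jitter makes them vary around the target. Deterministic under a fixed
#' seed.
#'
#' @param spec a [scenario_spec()].
#' @param fixture list from [generate_reference_fixture()].
#' @return Sales tibble (`store_id`, `week_start`, `product_id`, `units_sold`,
#'   `dollar_value`) with attribute `ground_truth`: tibble `level`,
#'   `indicator`, `value` of the exact noise-free indicators.
#' @examples
#' fx <- generate_reference_fixture()
#' sales <- generate_sales(scenario_spec(n_stores = 2, n_weeks = 4, seed = 42), fx)
#' attr(sales, "ground_truth")
#' @export
generate_sales <- function(spec, fixture) {
  stopifnot(inherits(spec, "scenario_spec"))
  sol <- solve_unit_basket(spec, fixture)
  basket <- sol$basket %>%
    left_join(select(fixture$catalog, "product_id", "food_code", "pack_size_g"),
              by = "food_code")
  if (anyDuplicated(basket$food_code)) {
    basket <- basket %>% distinct(.data$food_code, .keep_all = TRUE)
  }
  # deterministic pseudo-prices: roughly energy- and pack-linked
  basket <- basket %>%
    mutate(unit_price = round(0.5 + .data$pack_size_g / 250 +
                                .data$energy / 2000, 2))

  weeks <- spec$start_date + 7 * (seq_len(spec$n_weeks) - 1)
  stores <- sprintf("S%02d", seq_len(spec$n_stores))
  person_days <- spec$weekly_energy_kj / 8900

  with_local_seed(spec$seed, {
    store_scale <- if (spec$store_scale_sigma > 0) {
      exp(rnorm(spec$n_stores, 0, spec$store_scale_sigma))
    } else rep(1, spec$n_stores)

    grid <- tidyr::expand_grid(store_i = seq_along(stores), week = weeks)
    week_mult <- if (spec$noise > 0) {
      exp(rnorm(nrow(grid), -spec$noise^2 / 2, spec$noise))
    } else rep(1, nrow(grid))

    out <- purrr::pmap(
      list(grid$store_i, as.list(grid$week), week_mult),
      function(si, wk, wm) {
        scale <- person_days * store_scale[si] * wm
        jit <- if (spec$product_jitter > 0) {
          exp(rnorm(nrow(basket), -spec$product_jitter^2 / 2, spec$product_jitter))
        } else 1
        grams <- basket$grams * scale * jit
        tibble(
          store_id = stores[si],
          week_start = wk,
          product_id = basket$product_id,
          units_sold = grams / basket$pack_size_g,
          dollar_value = round(grams / basket$pack_size_g * basket$unit_price, 2)
        )
      }
    ) %>% bind_rows()
    structure(arrange(out, .data$store_id, .data$week_start, .data$product_id),
              ground_truth = sol$truth)
  })
}

#' Write a complete scenario input set to disk
#'
#' Emits the same CSV dialects the ingest functions consume: `reference.csv`,
#' `catalog.csv`, `sales.csv`, plus `ground_truth.csv` and the scenario
#' itself (`scenario.json`).
#'
#' @inheritParams generate_sales
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_scenario_files <- function(spec, fixture = generate_reference_fixture(), dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sales <- generate_sales(spec, fixture)
  paths <- c(
    reference = file.path(dir, "reference.csv"),
    catalog = file.path(dir, "catalog.csv"),
    sales = file.path(dir, "sales.csv"),
    ground_truth = file.path(dir, "ground_truth.csv"),
    scenario = file.path(dir, "scenario.json")
  )
  write_reference(fixture$reference, paths[["reference"]])
  readr::write_csv(fixture$catalog, paths[["catalog"]], progress = FALSE)
  readr::write_csv(sales, paths[["sales"]], progress = FALSE)
  readr::write_csv(attr(sales, "ground_truth"), paths[["ground_truth"]], progress = FALSE)
  write_scenario(spec, paths[["scenario"]])
  invisible(paths)
}
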