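# Hand-built micro-fixtures and an independent brute-force oracle.

ref_row <- function(code, ed, fr = 0, vg = 0, gr = 0, mt = 0, dy = 0,
                    disc = FALSE, sub = NA_character_,
                    tier = if (disc) "Unhealthy Foods" else "Best Choice",
                    alc = FALSE, desc = code) {
  tibble::tibble(
    food_code = code, description = desc, energy_density_kj_per_100g = ed,
    serves_fruit_per_100g = fr, serves_veg_per_100g = vg,
    serves_grains_per_100g = gr, serves_meat_per_100g = mt,
    serves_dairy_per_100g = dy, is_discretionary = disc,
    unhealthy_subgroup = sub, tier = tier, is_alcohol = alc
  )
}

tiny_reference_df <- function() {
  dplyr::bind_rows(
    ref_row("APPLE", 250, fr = 0.667),
    ref_row("CARROT", 150, vg = 1.333),
    ref_row("COLA", 180, disc = TRUE, sub = "sugar_sweetened_beverages")
  )
}

tiny_catalog <- function() {
  tibble::tibble(
    product_id = c("P_APPLE", "P_CARROT", "P_COLA", "P_SOAP"),
    description = c("apples", "carrots", "cola 375mL", "soap"),
    pack_size_g = c(150, 1000, 375, 125),
    food_code = c("APPLE", "CARROT", "COLA", NA)
  )
}

sales_row <- function(store = "S01", week = "2023-01-02", product, units, dollars = units) {
  tibble::tibble(store_id = store, week_start = as.Date(week),
                 product_id = product, units_sold = units, dollar_value = dollars)
}

write_tmp_csv <- function(df, name = "f.csv") {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
  readr::write_csv(df, path, progress = FALSE)
  path
}

# Independent oracle: explicit per-record loop over plain data frames, no
# aggregation framework, recomputing serves/person/day for one store+period.
oracle_indicators <- function(sales, catalog, reference, store,
                              reference_energy = 8900, disc_kj = 600) {
  serves <- c(fruit = 0, vegetables = 0, breads_cereals = 0,
              meat_fish_eggs = 0, dairy = 0)
  sf_cols <- c(fruit = "serves_fruit_per_100g", vegetables = "serves_veg_per_100g",
               breads_cereals = "serves_grains_per_100g",
               meat_fish_eggs = "serves_meat_per_100g", dairy = "serves_dairy_per_100g")
  disc_energy <- 0
  total_e <- 0
  sub_energy <- list()
  for (i in seq_len(nrow(sales))) {
    if (sales$store_id[i] != store) next
    ci <- which(catalog$product_id == sales$product_id[i])
    if (length(ci) == 0) next
    fc <- catalog$food_code[ci]
    if (is.na(fc)) next
    ri <- which(reference$food_code == fc)
    if (length(ri) == 0) next
    if (reference$is_alcohol[ri]) next
    grams <- sales$units_sold[i] * catalog$pack_size_g[ci]
    energy <- grams * reference$energy_density_kj_per_100g[ri] / 100
    if (reference$is_discretionary[ri]) {
      disc_energy <- disc_energy + energy
      total_e <- total_e + energy
      sg <- reference$unhealthy_subgroup[ri]
      if (!is.na(sg)) sub_energy[[sg]] <- (sub_energy[[sg]] %||% 0) + energy
    } else {
      row_serves <- 0
      for (g in names(sf_cols)) {
        sv <- grams * reference[[sf_cols[[g]]]][ri] / 100
        serves[[g]] <- serves[[g]] + sv
        row_serves <- row_serves + sv
      }
      if (row_serves > 0) total_e <- total_e + energy
    }
  }
  if (total_e <= 0) return(NULL)
  out <- c(serves, unhealthy_foods = disc_energy / disc_kj)
  out <- out * reference_energy / total_e
  subs <- vapply(sub_energy, function(e) e / disc_kj * reference_energy / total_e,
                 numeric(1))
  list(groups = out, subgroups = subs, total_energy = total_e)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
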