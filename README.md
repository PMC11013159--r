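# shelf2serves

Weekly store point-of-sale data in, key dietary indicators and store-facing
reports out.

Remote community stores are often the only food outlet for the community
they serve, so what the store sells is a close proxy for what the community
eats. `shelf2serves` turns the till's weekly product sales into indicators a
store board or nutritionist can act on: **serves of each Australian Dietary
Guidelines food group purchased per person per day**, energy-standardised so
stores of different sizes and periods of different lengths are comparable,
and benchmarked against population-weighted guideline targets.

## The indicator

For store *s* and period *p* (calendar month or quarter), the indicator for
food group *g* is

```
I_g(s, p) = serves_g(s, p) × E_ref / E(s, p)
```

* `serves_g` — serves of group *g* purchased: grams sold × a per-food serve
  factor for the five food groups (Fruit; Vegetables; Breads and Cereals;
  Meat, Fish and Eggs; Dairy), or discretionary energy ÷ 600 kJ for
  "Unhealthy Foods" (the nominal discretionary serve);
* `E(s, p)` — total energy (kJ) of classified food sold, with alcohol and
  non-food items excluded wholesale;
* `E_ref` — the reference estimated energy requirement, 8 900 kJ/person/day
  (8.9 MJ), a population-weighted average for the communities served.

Because numerator and denominator both scale with volume, `I_g` is invariant
to store size — it reads directly as *serves per person per day*.

Classification rules that matter: discretionary ("unhealthy") foods never
contribute to the five food groups (the potato in hot chips buys no
vegetable serves); 100% fruit juice and dried fruit count as Fruit but as
*Less Healthy Choices*; high-fibre white bread sits with regular white bread
as a Less Healthy Choice; foods carry one of three healthiness tiers (Best
Choice / Less Healthy Choice / Unhealthy Foods) and discretionary foods one
of 13 unhealthy subgroups (sugar-sweetened beverages, confectionery,
takeaway foods, ...).

Targets ship with the package (serves/person/day, rounded to the nearest
0.5): Fruit ≥ 2, Vegetables ≥ 5, Breads and Cereals ≥ 5.5, Meat, Fish and
Eggs ≥ 2.5, Dairy ≥ 2.5, and Unhealthy Foods ≤ 2.5 (an upper limit). The
machinery to derive alternative targets from a demographic strata table
(`derive_targets()`, `weighted_eer()`) is included.

## Worked example

Real store sales are restricted, so the package ships a synthetic generator
whose baskets have *known* indicator values. Three stores, 26 weeks, a
typical remote-store pattern (discretionary purchasing far above its limit):

```r
library(shelf2serves)
library(dplyr)

fx    <- generate_reference_fixture()
spec  <- scenario_spec(n_stores = 3, n_weeks = 26, noise = 0.15,
                       unsubgrouped_share = 0.123, seed = 2024)
sales <- generate_sales(spec, fx)
ind   <- link_sales(sales, fx$catalog, fx$reference) |> compute_indicators()

tidy(ind, against = default_targets()) |>
  filter(store_id == "S01", period == "2023-06") |>
  select(indicator, value, target, direction, meets_target)
#> # A tibble: 6 × 5
#>   indicator       value target direction meets_target
#>   <chr>           <dbl>  <dbl> <chr>     <lgl>
#> 1 breads_cereals    4.5    5.5 at_least  FALSE
#> 2 dairy             1      2.5 at_least  FALSE
#> 3 fruit             1      2   at_least  FALSE
#> 4 meat_fish_eggs    2      2.5 at_least  FALSE
#> 5 unhealthy_foods   6      2.5 at_most   FALSE
#> 6 vegetables        2      5   at_least  FALSE
```

The store sells 1 fruit serve/person/day against a target of ≥ 2, and 6
unhealthy serves against an upper limit of 2.5 — every indicator is off
target, which is exactly the purchasing pattern the scenario encodes (the
generator's noise scales whole weeks, so the recovered values equal the
scenario targets exactly). The 13 named subgroups cover 87.7% of
discretionary energy here because the scenario routes 12.3% to an
unsubgrouped item:

```r
discretionary_coverage(link_sales(sales, fx$catalog, fx$reference))
#> # A tibble: 1 × 3
#>   covered_fraction discretionary_energy_kj undefined
#>              <dbl>                   <dbl> <lgl>
#> 1            0.877              234973409. FALSE
```

Render a store's report (self-contained HTML: gauge per indicator against
its target, trend chart with comparator overlays, serve-size guide):

```r
build_report(report_spec("S01", window = 6,
                         comparators = c("guideline-target", "all-store-average")),
             link_sales(sales, fx$catalog, fx$reference),
             file = "report_S01.html")
```

Or drive everything from the shell:

```sh
exec/shelf2serves simulate inst/extdata/demo_scenario.yaml demo_inputs
exec/shelf2serves compute --sales demo_inputs/sales.csv \
    --catalog demo_inputs/catalog.csv --reference demo_inputs/reference.csv \
    --out-dir demo_out
exec/shelf2serves report --sales demo_inputs/sales.csv \
    --catalog demo_inputs/catalog.csv --reference demo_inputs/reference.csv \
    --out-dir demo_out --indicators fruit,vegetables,unhealthy_foods
```

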