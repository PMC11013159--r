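---
title: "From shelf to serves: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From shelf to serves: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shelf2serves)
```

## The measurement model

`shelf2serves` treats a store's point-of-sale stream as a proxy for
community food intake. Each weekly sales record (store, week, product,
units, dollars) is linked through a product catalogue to a flat food
reference — one row per food code carrying an energy density (kJ/100 g, or
per 100 mL for beverages, with millilitres stored in the gram fields at an
assumed density of 1.0), per-food-group serve factors (serves per 100 g), a
discretionary flag, a healthiness tier and, for discretionary foods, an
unhealthy subgroup. The reference is a pre-joined extract of the national
food-composition sources a practitioner would use; the package deliberately
does not attempt free-text product matching — the mapping is an input.

Per linked record, grams = units × pack size, energy = grams × energy
density / 100, and five-food-group serves = grams × serve factor / 100.
Aggregating to store × period and normalising gives the key indicator

$$ I_g(s,p) = \mathrm{serves}_g(s,p)\;\frac{E_\mathrm{ref}}{E(s,p)}, $$

serves per person per day at a reference daily energy requirement
$E_\mathrm{ref}$ of 8 900 kJ. The assumptions worth stating:

* **Energy as denominator.** Total classified food energy stands in for
  person-days of food purchased. This makes the indicator invariant to
  store size and period length, at the cost of being distorted if a large
  share of energy leaves the classification (see exclusions below).
* **Discretionary exclusion.** Discretionary foods never contribute to the
  five food groups, even where composition databases would allow it (hot
  chips contribute no vegetable serves). Validation enforces this at load
  time: a discretionary record with a nonzero five-group serve factor is
  rejected with a named `discretionary-exclusion` diagnostic.
* **Discretionary serves are energy-defined** at 600 kJ/serve, the
  Australian Dietary Guidelines' nominal discretionary serve. The constant
  is a `discretionary_serve_kj` argument throughout.
* **Alcohol is removed wholesale** — neither serves nor denominator energy —
  because its availability varies too much across communities for
  cross-store comparison.
* **Non-food and unclassifiable energy is excluded from the denominator.**
  Whether to count energy from foods that carry no classification is
  genuinely open; we exclude it so that the indicator compares classified
  food against classified food, and report unlinked/unclassifiable rows in
  the linkage report so the analyst can see how much slipped through.

## Taxonomy

Six top-level groups (the five core food groups plus "Unhealthy Foods"),
three healthiness tiers ("Best Choice", "Less Healthy Choice", "Unhealthy
Foods" — the descriptor wording store audiences preferred), and 13 unhealthy
subgroups. The subgroup inventory is configuration, not dogma: the shipped
set is drawn from the Australian Health Survey discretionary classification
(sugar-sweetened beverages, confectionery, sweet biscuits, cakes/muffins,
savoury pastries, savoury snacks, processed meats, takeaway foods, fried
potato products, ice cream, table sugar, sauces/condiments, energy
drinks/cordials), chosen as the biggest contributors to discretionary
energy in this retail setting; `default_scheme()` documents it and
`read_scheme()` replaces it.

Two classification stances are fixed in the default fixture because they
reflect the tool's published-guideline alignment even though they are
contested by practitioners: 100% fruit juice and dried fruit count toward
Fruit but as Less Healthy Choices, and high-fibre white bread is grouped
with regular white bread as a Less Healthy Choice (refined grains with
fibre added back are not wholegrains).

**Mixed dishes.** The reference stores per-group serve factors, and a
multi-group food contributes serves to *all* its groups — apportionment by
recipe decomposition is not attempted. For report grouping and dollar
shares each food also gets a single *primary* group: the largest serve
factor, ties broken alphabetically by group label (deterministic and
inspectable, if arbitrary; the tie-break never affects serve totals).

## Targets

Guideline recommendations vary by age and sex, so store-level targets are
population-weighted means over a demographic strata table, rounded to the
nearest 0.5 serves; the reference energy is the weighted mean EER rounded
to the nearest 100 kJ (so 8.9 MJ is representable exactly). Midpoint
rounding is half-up (2.25 → 2.5) — "nearest half serve" leaves midpoints
unspecified, and half-up keeps targets from quietly relaxing. For Unhealthy
Foods the strata table must carry the *upper limit* of the discretionary
recommendation and the resulting target is an at-most bound, because
observed discretionary purchasing in this setting sits far above any
recommendation and a mid-range target would be meaningless.

The census-derived strata weights behind the packaged defaults are not
re-derivable from public tables shipped here; `default_targets()` is
therefore the authoritative constant set (Fruit ≥ 2, Vegetables ≥ 5, Breads
and Cereals ≥ 5.5, Meat/Fish/Eggs ≥ 2.5, Dairy ≥ 2.5, Unhealthy ≤ 2.5;
reference energy 8 900 kJ), and the weighting machinery ships with a
clearly-labelled *synthetic* example strata table
(`inst/extdata/strata_example_synthetic.csv`) for illustration. Reproducing
the packaged targets from first principles is explicitly not claimed.

## Periods and comparators

Weeks are assigned to months/quarters by their start date: a week straddling
two months belongs wholly to the month containing its start. Deterministic
and simple; any convention distorts boundary weeks equally.

Because the indicator is a ratio, a quarter's value is recomputed from the
quarter's pooled weekly records — never the mean of monthly indicators
(means of ratios ≠ ratio of sums). `trend_series()` therefore takes the
quantified records, not a finished indicator table.

The all-store average is the unweighted mean over stores with a defined
value (each store — each community — gets equal voice); an energy-weighted
pooled mean is available behind `weighted = TRUE`. The focal store is
included in the average: with few participating stores, excluding it would
make the comparator jump between reports. Stores with no sales in a period
are omitted and the contributing count is attached.

## Reports

Each selected indicator renders a gauge (speedometer) panel for the latest
period and a trend chart over the window. Green always sits on the
target-satisfying side, so the orientation flips for the Unhealthy Foods
upper limit; the boundary is inclusive (a store exactly on target is
meeting it). The gauge range is `[0, max(2 × target, observed value)]` so
the needle is always on scale. Tier colours are the colour-blind-safe
Okabe–Ito triple: green `#009E73`, amber `#E69F00`, red `#D55E00`;
undefined values render grey, never red.

Charts are written by the package's own SVG writer with fixed two-decimal
coordinate formatting, and the document carries no timestamp unless
`stamp = TRUE`: identical inputs yield byte-identical HTML, which makes
reports diffable and cacheable and turns "did anything change?" into a
checksum. A JSON payload with every number on the page is embedded in the
document (and optionally written alongside) so a portal or downstream
system can consume the same content. `ggplot2`-based `plot_trend()` /
`plot_gauge()` / `autoplot()` serve interactive analysis.

Bar charts are available as a trend alternative (`chart = "bar"`); line is
the default as the better display of change over time. The classification
scheme can carry extra groups (e.g. bush/traditional foods) but market
sales data cannot observe non-market foods, so none ship.

## The synthetic generator

Real remote-store sales are restricted, so the generator is a first-class
module, not a test convenience. It emulates: a catalogue and reference
spanning the full taxonomy (42 foods, all groups, tiers and 13 subgroups,
plus alcohol and a non-food product); multi-store weekly volumes with
lognormal week-to-week noise and a lognormal between-store size spread; and
— the core property — baskets whose noise-free indicator values equal a
requested target vector *exactly*.

Construction works backwards from the targets. Fix a one-person-day basket
of 8 900 kJ. Discretionary energy is `600 × target_unhealthy`, split
equally across the 13 subgrouped foods (optionally routing a share to an
unsubgrouped discretionary item, which sets the subgroup energy coverage to
`1 − share`). Each five-food group must then supply its serve target while
the total energy closes to 8 900 kJ; the free variable is the within-group
split between low- and high-energy-per-serve foods. A `mix_breadth`
fraction (default 0.5) of each group's serves is spread equally over all
the group's foods for realism, and the remainder moves between the group's
cheapest and dearest foods (in energy per serve) until the energy balance
closes — a one-dimensional waterfill solved exactly. Infeasible targets
fail loudly, naming the achievable Unhealthy Foods interval
(`feasible_unhealthy_range()`).

Weekly noise multiplies whole store-weeks. Because the indicator is scale
invariant, this leaves every per-period indicator *exactly* on target — by
design, so recovery tests are sharp. Per-product jitter
(`product_jitter > 0`) breaks within-basket proportions and produces
indicator-level variability centred on the target; under jitter the match
is statistical, not exact. What the generator does **not** emulate:
seasonality, promotions and price elasticity, product churn, refund
patterns, random-weight produce, or correlated store shocks — so passing
recovery tests demonstrates pipeline correctness, not robustness to real
retail messiness.

Default conditions: 31 stores, 52 weeks, weekly noise σ = 0.15, a target
vector with discretionary purchasing at 2.4× its upper limit and
fruit/vegetables below target — the purchasing profile this surveillance
setting is built to report on. The bundled demo scenario
(`inst/extdata/demo_scenario.yaml`) uses three stores over 26 weeks with
12.3% of discretionary energy unsubgrouped, so named subgroups cover 87.7%
of discretionary energy.

## Numerical choices and degenerate inputs

* Zero-energy periods yield `NA` indicators with a `no_sales` flag —
  never division by zero; reports render "no data" in grey.
* Zero discretionary energy makes subgroup coverage undefined (flagged),
  not zero.
* Negative quantities (refunds) are quarantined by default; `--net-refunds`
  subtracts them instead. Netting can produce negative period totals in
  pathological inputs, which then surface as validation errors rather than
  silently negative serves.
* Duplicate (store, week, product) rows are summed with a warning;
  duplicate food or product codes are rejected, not first-wins.
* Half-serve rounding is `floor(2x + 0.5)/2`; EER rounding
  `floor(x/100 + 0.5) × 100` — both exact in doubles for the relevant range.
* Tests compare the pipeline against an explicit per-record loop oracle at
  1e−9 relative tolerance and against generator ground truth at 1e−6;
  recovery is exact to machine precision in practice.

Problem sizes in the test suite and acceptance script are deliberately
modest — scenarios of one to three stores over two to ten weeks for exact
properties, 52 weeks where a year of history matters, 20 random scenarios
for recovery and 100 random baskets for the oracle — chosen because the
properties they check are scale-free: a two-week scenario exercises exactly
the same arithmetic as a two-year one.

## Known limitations

* Serves are purchased, not consumed: waste, stock shifts, non-store food
  sources and visitors all blur the person-day interpretation.
* The reference energy is a population average; a store serving an atypical
  demographic profile should derive its own targets from a strata table.
* Dollar shares are reported as an auxiliary only — prices move
  independently of quantities, which is why serves are the headline unit.
* Classification disagreements (juice, high-fibre white bread) are encoded,
  documented choices; organisations with different policies can ship their
  own reference table and scheme without code changes.
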