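# sugarsteps

Estimation of **added** and **free sugars** content in food-composition
databases, and of habitual sugars intake in two-day dietary surveys.

Added and free sugars cannot be measured chemically — an added sucrose
molecule is identical to one native to the food — so food-composition tables
carry only *total* sugars (the sum of all mono- and disaccharides). Yet
dietary guidelines are phrased in terms of added sugars (Nordic Nutrition
Recommendations: at most 10 % of energy) and free sugars (WHO: at most 10 %,
conditionally 5 %). `sugarsteps` is for nutrition researchers and
food-database maintainers who need to bridge that gap: it implements a
ten-step decision procedure that assigns every database item an added- and a
free-sugars content (g/100 g) together with the step number that produced
it, and then carries those item values through a survey intake pipeline up
to guideline-adherence statistics.

## The procedure

Single food items are classified by the first applicable rule, separately
for added and for free sugars:

1. **No sugars** — total sugars 0: content 0.
2. **Intrinsic only** — unprocessed/plain groups (raw fruit and vegetables,
   plain dairy, plain meat/fish, fats, pseudocereals): added = free = 0.
   Honey, syrup and fruit juice land here *for added sugars* (their sugars
   are natural), as does vegetable juice for both types.
3. **All sugars added/free** — soft drinks, confectionery, flagged items:
   content = total sugars. Honey, syrup and fruit juice land here *for free
   sugars* (free = total).
4. *(composites, below)*
5. **Counterpart subtraction** — sweetened product with an unsweetened
   counterpart: content = max(0, total − counterpart total).
6. **Fructose subtraction** — fruit/vegetable-containing foods with
   analytical fructose: content = max(0, total − fructose).
7. **Manufacturer/recipe information** — declared values supplied as data.
8. **Proportional scaling** — a ratio applied to a comparable reference
   item's estimate (capped at the item's own total sugars).
9. *(composites, below)*
10. **Border-case fallback** — 50 % of total sugars.

Steps 1–6 are *objective* (rule- and data-driven), steps 7–10 *subjective*.
Plain breads get a dedicated rule: batch sugars below 9 g per 1000 g
pre-baking dough weight (strict) are discounted as fermentation amounts.

Composite foods (recipes) are resolved bottom-up over the ingredient DAG:
each per-100 g nutrient is `sum(raw_weight_i × nutrient_i / 100) /
batch_post_weight × 100`, so water loss in cooking concentrates sugars. A
composite whose components all sit at steps 1–4 is assigned step 4,
otherwise step 9; its content is the same yield-adjusted weighted
aggregation of the component estimates.

## The intake pipeline

Per-participant daily intakes are amount-weighted sums over the day's foods.
Two recall days cannot separate habitual intake from day-to-day noise
person by person, so a usual-intake model in the style of the Multiple
Source Method is fitted per nutrient: Box-Cox/log transform (maximum
likelihood over a coarse λ grid), optional weekday/weekend fixed effect
re-centred at the 4/7–3/7 week composition, one-way random-effects
variance decomposition (σ²_between, σ²_within), and shrinkage of each
person's mean toward the population mean with factor

    σ²_between / (σ²_between + σ²_within / n_i)

followed by a mean-preserving back-transform. Stratified medians (p25; p75)
of g/day and E% (energy percent at 17 kJ/g), guideline-adherence shares and
girl/boy Mann–Whitney tests complete the survey table.

## Worked example

Everything is testable without real survey data through the synthetic-data
module, which plants known sugar sources and variance components:

```r
library(sugarsteps)
library(dplyr)

cfg   <- synth_config(n_single = 120, n_composite = 60, seed = 1)
synth <- generate_food_db(cfg)            # database + planted ground truth
est   <- assign_and_estimate(synth$db, synth$config)
est %>% select(item_id, kind, step_added, step_free, added_g, free_g, total_g) %>% head(5)
#>   item_id kind   step_added step_free added_g free_g total_g
#> 1 S0001   single          3         3    12.0  12.0    12.0
#> 2 S0002   single          2         3     0     8.69    8.69
#> 3 S0003   single          2         2     0     0       7.08
#> 4 S0004   single          1         1     0     0       0
#> 5 S0005   single          2         2     0     0       3.07
```

`S0001` is a soft drink (all 12 g/100 g counted as added and free), `S0002`
a fruit juice (nothing added, all 8.69 g free), `S0003` raw fruit (all
intrinsic), `S0004` a sugar-free item (step 1). The survey side:

```r
survey <- generate_survey(cfg, synth)      # 3099 participants x 2 days
daily  <- daily_intake(survey$records, est, synth$db)
usual  <- usual_intakes(daily)             # habitual intake per participant
glance(attr(usual, "models")$added_g)
#>   value   transform lambda sigma2_between sigma2_within variance_ratio
#> 1 added_g log            0          0.208         0.255          0.815

summarize_intakes(usual, survey$participants) %>%
  filter(sex == "All") %>%
  select(school_year, n, added_E_label, pct_added_E_below_10, p_added_E)
#>   school_year     n added_E_label    pct_added_E_below_10 p_added_E
#> 1 5            1049 10.3 (8.5; 12.5)                   46    0.865
#> 2 8            1050 10.4 (8.5; 12.4)                   45    0.803
#> 3 11           1000 10.5 (8.5; 12.9)                   44    0.0966
#> 4 All          3099 10.4 (8.5; 12.6)                   45    0.344
```

Each row reads: median added-sugars E% with quartiles, the share of
participants below the 10 %-of-energy guideline, and the two-sided
Mann–Whitney p-value for the girl/boy difference within the stratum.

A thin command-line front-end (`inst/cli/sugarsteps.R`) exposes the same
pipeline as `simulate`, `estimate` and `intake` subcommands.

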