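---
title: "Estimating added and free sugars: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating added and free sugars: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sugarsteps)
```

## Why a decision procedure

Added sugars (refined sugars introduced in cooking or manufacturing, under
the strict Nordic definition excluding honey and unsweetened fruit-juice
sugars) and free sugars (added sugars plus the natural sugars of honey,
syrup, fruit juice and juice concentrate, per the WHO definition) are
analytically indistinguishable from intrinsic sugars. Any database value
for them is therefore an *estimate*, and the scientific worth of that
estimate depends on how transparently it was derived. The ten-step
procedure implemented here makes the derivation explicit: every item
carries, next to its g/100 g values, the step number that produced them,
and steps 1–6 are fully determined by recorded data (category, flags,
counterpart links, analytical fructose, dough batch weights) while steps
7–10 require externally supplied judgement encoded as data (overrides,
reference ratios, the 50 % fallback).

Two properties are enforced structurally and verified by tests:

* **Totality** — every item receives exactly one step per sugar type; the
  fallback step guarantees no silent fall-through. Because an item enters
  step 7 or 8 only when its override or reference row exists, the
  "missing subjective data" state is unrepresentable rather than an error;
  the reachable failure modes (circular reference chains, overrides with
  added > free) do raise errors.
* **Ordering** — 0 ≤ added ≤ free ≤ total sugars for every item. Free
  sugars are a superset of added sugars under the default configuration;
  subtraction steps clamp negative differences at zero, and declared or
  proportionally scaled values are capped at the item's measured total.

## Configurable definitions

Definitions of added sugars differ between guideline systems, so the
contested boundaries are configuration, not code (`procedure_config()`):

| parameter | default | meaning |
|---|---|---|
| `bread_discount_threshold` | 9 g / 1000 g | dough-batch sugars below this (strict `<`) are fermentation amounts, not added sugars |
| `honey_in_added` | `FALSE` | some labelling schemes count honey sugars as added |
| `vegetable_juice_in_free` | `FALSE` | vegetable-juice sugars excluded from free sugars by default; flip for definitions that include them |
| `fruit_puree_in_free` | `FALSE` | purees retain the fruit matrix |
| `step10_fraction` | 0.5 | border-case fallback share of total sugars |

The bread boundary is read literally: exactly 9 g per 1000 g pre-baking
weight is *not* discounted. Dough batch data is not part of the per-100 g
food schema, so it enters through the configuration (`bread_batches`);
a discounted bread contributes no added or free sugars, while a bread above
the threshold is treated as deliberately sweetened (all sugars added).
Only fructose is subtracted in the fructose step — no matched-glucose
doubling — so items whose intrinsic sugars include glucose or sucrose may
be slightly overestimated; this is a property of the procedure, not a bug,
and the clamp at zero is logged in the item's notes.

## Recipe resolution

Composite foods are resolved bottom-up in a deterministic topological order
(lexicographic tie-breaks) over the ingredient DAG, in which one item may
appear in many composites. Each per-100 g nutrient of a finished food is

$$\frac{\sum_i w_i \, c_i / 100}{W_{\text{post}}} \times 100,$$

with $w_i$ the raw batch weights, $c_i$ the ingredient concentrations and
$W_{\text{post}}$ the post-cooking batch weight (default: the raw sum).
Cooking losses are modelled as water loss only — sugar retention is 1.0 —
because no retention factors are part of the procedure; concentration
through baking is therefore captured entirely by $W_{\text{post}}$.
`flatten_to_singles()` performs the same computation by full expansion to
leaf items and serves as an independent oracle: tests require agreement
within 10⁻⁹ g/100 g over random DAGs of depth ≤ 4.

## The usual-intake model

Two recall days per person identify population variance components but not
individual day-to-day noise, so habitual intake is estimated in the style
of the amount part of the Multiple Source Method, simplified by the
assumption that everyone is a daily consumer of added and free sugars (an
assumption the all-positive synthetic intakes satisfy by construction; with
real data the logged offset — half the smallest positive value — handles
sporadic zero reporters):

1. **Transform**: Box-Cox with λ chosen by maximum likelihood over the
   coarse grid {−1, −0.5, 0, 1/3, 0.5, 1} (0 = log). A coarse grid is
   deliberate: with two days per person the profile likelihood is flat, and
   a fine grid would only chase noise.
2. **Day-class effect**: a weekday/weekend fixed effect estimated by least
   squares and removed re-centred at the 4/7–3/7 composition of a week, so
   predictions refer to a representative week.
3. **Variance decomposition**: one-way random-effects ANOVA
   method-of-moments estimators (unbalanced formulas); negative
   between-person moments are clamped to zero with a warning. These
   closed-form estimators are computed directly from group sums — at ~3000
   participants a dense fixed-effects fit over participant indicators would
   be needlessly heavy.
4. **Shrinkage**: on the transformed scale each person's mean moves toward
   the population mean with factor σ²_b / (σ²_b + σ²_w / nᵢ) — 2/3 for two
   days at equal components, 1 when σ²_w = 0.
5. **Back-transform**: inverse Box-Cox followed by ratio smearing — all
   habitual values are rescaled by mean(observed)/mean(back-transformed),
   which preserves the population mean on the original scale exactly.

Consequences verified by tests: the habitual distribution's variance and
tail width never exceed those of the raw two-day means (equality only when
σ²_w = 0); habitual values correlate better with the true long-term level
than raw means do; with many days per person the habitual estimate
converges to the person mean. One known bias is documented rather than
corrected: ratio smearing targets the mean, so the *median* of shrunken
habitual values sits a few percent above the true habitual median for
right-skewed intakes (≈ 3–4 % at the default variance components); the
end-to-end median-recovery tests therefore use a 10 % band.

Quantiles use linear interpolation between order statistics (R type 7) and
the convention is recorded on the summary table, because p25/p75 are
convention-sensitive at survey sizes. The Mann–Whitney girl/boy test is
two-sided, exact when both groups have ≤ 20 tie-free observations and a
tie-corrected normal approximation otherwise. The energy conversion for E%
defaults to 17 kJ per gram of sugars (the EU/NNR carbohydrate convention)
and is configurable because survey systems differ here.

## What the synthetic data emulates — and what it does not

`synth_config()` defaults encode the emulated study conditions: 3099
participants (1049/1050/1000 in school years 5/8/11; 559/574/577 girls),
two recall days each with weekend probability 3/7, a 844 + 639 item
database. Intakes are lognormal with habitual medians 100 g/day total
sugars and 8.5 MJ/day energy, between/within log-variances 0.16/0.25
(sugars) and 0.05/0.08 (energy) — chosen once from the reported quartile
spreads and typical recall repeatability — a person-level added share
centred at 0.51 and a free-but-not-added share of the remainder centred at
0.163, so habitual added/free medians sit near 51/59 g/day and added E%
near 10 %. The weekend effect is ×1.1 on sugars.

Two numerical choices deserve note. The config states *habitual medians*;
the generator derives the day-level log location internally by removing the
smearing term σ²_w/2 and the weekday/weekend mixture, so the stated
conditions are on the scale the survey reports. And the sugars and energy
log deviations are drawn with correlation 0.6: marginal variance components
are untouched, but days with very high sugars and very low energy — which
no food basket could realize — become as rare as they are in real diets.

Day totals are generated top-down (draw totals, then realize them as food
lists), so variance components are exact by construction. Each day's
records consist of four basis foods (a soft drink carrying the added part,
fruit juice the free-not-added part, raw fruit the intrinsic part, oil
topping up energy) plus one random garnish food absorbed into the targets
before solving; gram amounts are rounded to 0.01 g. Record sums reproduce
the drawn sugars totals essentially exactly; energy can exceed its target
only on the rare residual days where the sugars basket alone carries more
energy than drawn (well under 1 % of days at the defaults, asserted in
tests at a 97 % bound against small-sample noise).

What passing tests on this generator do **not** show: robustness to
misreporting, seasonality, portion-size error, consumption-probability
structure for episodically consumed foods, correlated food selection
within days, or real brand-level label variation. The generator exists to
verify the *computational* contracts — decision-tree totality and
ground-truth recovery, recipe conservation, variance-component recovery,
shrinkage behaviour — not to claim realism of Swedish adolescent diets.

## Problem sizes and determinism

The shipped test-and-acceptance runs use a 120 + 60 item database with the
full 3099-participant roster for end-to-end checks, 600 + 400 items for the
procedure-invariant sweep, and 100 random depth-≤ 4 DAGs for the recipe
oracle; these sizes give Monte-Carlo error comfortably inside the asserted
bands (the variance-ratio estimator's relative standard error at 3000 × 2
days is about 7 %). Every stochastic routine takes its randomness from the
config seed; identical configs give byte-identical written outputs.

## Known limitations

* Step semantics for the subjective steps are data-driven by design; the
  package cannot flag an item that *should* have had manufacturer data but
  arrived without it — such an item silently receives the fallback step.
* Composite fructose is `NA` whenever any ingredient lacks an analytical
  value, which is the conservative choice but makes the fructose step rare
  for composites.
* The usual-intake model is amount-only (no consumption-probability part)
  and provides no uncertainty intervals on habitual intakes.
* Label-averaging provenance ("average of ≥ 3 supermarket products") is
  carried as a free-text provenance field, never computed.
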