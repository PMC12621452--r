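---
title: "Nutrient density and affordability of aquatic foods: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nutrient density and affordability of aquatic foods: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquanrf)
```

## The model

aquanrf implements Nutrient Rich Food (NRF) profiling for fish and
shellfish composition data. All amounts are per 100 g edible portion. For
a nutrient amount $a$ with reference daily value $DV$, the percent daily
value is

$$\%DV = \min\left(100\,\frac{a}{DV},\; \mathrm{cap}\right)$$

with cap = 100 by default. An NRF variant names $n$ nutrients to
encourage and (here) 2 to limit:

$$\mathrm{NRF}n.2 = \mathrm{NR}n - \mathrm{LIM}
  = \sum_{i \in \mathrm{encourage}} \%DV_i
  - \sum_{j \in \{\mathrm{sodium},\,\mathrm{sat.\ fat}\}} \%DV_j$$

Two profiles are central. **NRF6.2** sums the six priority
micronutrients widely deficient in low- and middle-income-country diets
(iron, zinc, calcium, vitamin A, vitamin B12, folate). The aquatic
**NRF9.2** replaces the classic land-food nine (whose fiber and vitamin C
are negligible in seafood) with protein, selenium, calcium, iron,
potassium, magnesium, vitamin A, vitamin D and total omega-3 fatty acids.
The classic profile is still shipped (`NRF9.2-classic`) with fiber and
vitamin C zero-filled, for comparison only. No protein-digestibility
correction is applied: seafood is a complete protein source.

Scores are computed **per item and then averaged**. Because the cap acts
per item, the group mean of scores is *not* the score of the group-mean
nutrient vector; the two coincide only in the cap-free regime (a property
the test suite checks). This is also why published group-level NRF means
cannot be regenerated from published group-mean nutrient amounts — an
expected consequence of capping, not a defect.

### Daily values

The shipped DV table is the FDA set for ages 4+ (protein 50 g, calcium
1300 mg, iron 18 mg, potassium 4700 mg, magnesium 420 mg, selenium
55 µg, zinc 11 mg, folate 400 µg, vitamin B12 2.4 µg, vitamin A 900 µg
RAE, vitamin D 20 µg, saturated fat 20 g, sodium 2300 mg, total fat
78 g). Total omega-3 fatty acids have no FDA daily value; the default
denominator is **1.6 g** (the adult ALA adequate intake), which is
consistent with seafood groups at ~0.6–1.9 g omega-3/100 g clearing the
20 %DV threshold. Every value is overridable via a YAML/JSON config;
units are fixed package-wide and a config declaring different units is
rejected rather than converted silently.

Capping applies to the limit nutrients too by default: the capping rule
is stated for %DV generally, and nothing exempts LIM. Because older NRF
formulations differ on this point, `cap_limit = "uncapped"` restores the
uncapped behaviour.

### Missing data

Scoring is **strict** by default: a missing amount is an error directing
the caller to impute first, which mirrors a pipeline that fills gaps
before profiling. `missing_policy = "zero"` treats missing as 0 and
biases scores downward; it exists for exploratory use only.

## Imputation

Gaps are filled by donor-record lookup from an ordered cascade of
fallback composition tables (emulating a primary database consulting a
national database, then a secondary one), never by statistical
imputation. The matching rule is deliberately conservative: exact
(species group, state) match first, then the same species group with the
state requirement relaxed, never across species. Ties prefer the most
complete donor, then the lexicographically smallest item id, so results
are deterministic. Filling is per nutrient (rather than whole-record),
which retains the maximum amount of primary data; each filled cell's
provenance records the source (`fallback_1`, `fallback_2`, ...), and
cells no source can fill stay missing as `unresolved`. Because a donor
is a different food, an imputed saturated-fat or omega-3 value can
exceed the item's total fat; imputed values are reconciled to the
compositional invariants after filling (primary values are never
altered). The operation is idempotent.

## Affordability

Prices arrive per kg of whole/landed product. Processing order:

1. currency conversion (EUR -> USD at 1.09, the October-2024 reference
   rate; configurable);
2. yield correction: price per kg edible = price / yield fraction, with
   USDA-style edible-yield fractions in (0, 1];
3. cost per 100 g protein = (edible price per 100 g) / protein per
   100 g × 100 = 10 × edible price per kg / protein;
4. **affordability index** = mean NRF score / edible price per kg
   (score points per USD/kg edible).

The edible-portion denominator is used (not the whole-product price)
because it exactly reproduces the published mackerel and tilapia rows.
Published species-level indices were evidently computed from
species-level mean scores that are not public; recomputation from
group-level means reproduces them within ~1–2% for most species, and the
reproducible cells (mackerel, tilapia) to within 0.5%. Reports round
money and indices to 2 dp; internal arithmetic is unrounded. Species
with no price are carried as explicit N/A rows, not dropped.

## Group statistics

`one_way_anova()` is the classical fixed-effects decomposition;
`tukey_hsd()` uses the studentized-range distribution with pooled
within-group variance (the Tukey–Kramer statistic when group sizes
differ). Pooled-variance machinery is used throughout because Tukey's
HSD presumes it; the two-group wild-vs-farmed comparison is the pooled
t-test (identical to a 2-group ANOVA, F = t²). No multiple-testing
correction is applied across metrics, matching common practice in
composition tables. Compact letters come from the insert-and-absorb
algorithm, seeding letters over groups in descending mean order (ties by
label) so letter strings are reproducible; the letters never contradict
the pairwise table, which the suite verifies on random fixtures against
the reference implementation (`stats::aov`, `stats::TukeyHSD`) and a
Monte-Carlo studentized-range oracle.

## The synthetic world

The generator emulates the group structure of the FAO/INFOODS uFISH
database: 515 items — crustaceans (152), finfish (cichlid 24, cod 48,
demersal 96, small pelagic 12, salmonid 69) and mollusks (bivalve 66,
gastropod 12, cephalopod 36). Where group means and SDs are published
(crustaceans and the five finfish groups, most nutrients) the defaults
transcribe them. Three kinds of values are *not* published and were
chosen once, as documented domain values:

* **sodium, saturated fat, total fat** for all groups (e.g. shellfish
  sodium ~300 mg, small-pelagic total fat 10 ± 4 g with saturated fat
  ~25% of it);
* the **mollusk-subgroup split**: only a mollusk-wide column is
  published, so bivalve/gastropod/cephalopod moments were chosen to
  keep the weighted mollusk-wide means close to the published column
  while respecting the published qualitative contrasts (bivalves highest
  iron/zinc/B12, gastropods highest calcium/magnesium, cephalopods high
  vitamin A/B12, gastropods lowest NRF6.2);
* **state/habitat/salinity mixtures** (e.g. small pelagics wild,
  cichlids and salmonids mostly farmed) and small missingness rates on
  selenium/omega-3/potassium concentrated in crustaceans and bivalves,
  mirroring where the real database needed imputation.

Draws are independent truncated normals (left-truncated at 0);
log-normal is selectable per nutrient for high-CV cases. Truncation
inflates the mean when SD/mean is large (bivalve zinc 12 ± 12 has a
truncated mean of ~15.5), so moment-recovery tests compare against the
analytic truncated-normal moments, not the configured parameters.
Saturated fat and omega-3 are clamped to the drawn total fat, so their
marginals are not exactly the configured family and are excluded from
moment recovery.

What a green test does **not** establish: the generator draws nutrients
independently within an item, so per-item cap interactions differ from
real data, inter-nutrient correlations are absent, and group NRF means
match published ones only in rank order (bivalves first on NRF6.2, small
pelagics first on NRF9.2), never numerically. The wild-vs-farmed
contrast in the synthetic world arises from group composition (wild
small pelagics, farmed salmonids), not from habitat-specific moments.

### Numerical and testing notes

* Seeds are mandatory for every stochastic call; the same seed gives
  bit-identical datasets and the CLI manifest records seed, config
  hashes and row counts so runs replay exactly.
* The moment-recovery acceptance check performs 117 simultaneous
  per-quantity 3-SE comparisons at n = 10⁵ per group. Under a correct
  generator a single ~3σ excursion appears in roughly a quarter of
  seeds, so the per-quantity band is applied jointly (all z < 4.5, at
  most 2 of 117 above 3, median z < 1.5), which keeps the stated
  per-quantity tolerance while making the seeded gate a ~0.4%-level
  test.
* CSV round-trips write numerics at 17 significant digits, so
  write-then-read is exact.
* YAML configs: YAML 1.1 would read a bare `n` key as a boolean; the
  config reader installs handlers so `n: 5` means what it says.

## Known limitations

Prices are a single-month European snapshot; no seasonal or regional
modelling, and no adjustment to local LMIC markets. Per-species protein
for the cost-per-protein column comes from group-level means when
species-level means are not supplied, so species sharing a taxonomic
group share a protein denominator. Dried and canned small fish with
bones — more nutrient-dense than anything modeled here — are outside the
scope of the emulated database.
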