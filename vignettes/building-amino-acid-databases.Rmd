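---
title: "Building amino acid composition databases for FFQ-based cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building amino acid composition databases for FFQ-based cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffqaa)
```

## The problem

Food frequency questionnaires (FFQs) report how often and how much of a
fixed list of food items a participant usually eats.  Turning those
responses into amino acid intakes requires an amino acid content (mg per
100 g edible portion) for every item — but analytical amino acid profiles
exist only for a subset of foods in any national composition table.  A
database builder therefore has to decide, item by item, whether to copy an
analytical profile directly, borrow and rescale a similar food's profile,
or substitute it verbatim, and it has to document which it did.  `ffqaa`
implements that decision process as an auditable, deterministic algorithm
and the downstream intake/adequacy pipeline that consumes its output.

## The matching and substitution algorithm

Each FFQ item is pushed through a fixed sequence of screens against one or
more reference composition tables:

1. **Name concordance.** Reference foods whose normalized name (case-folded,
   whitespace-collapsed) equals the item's are candidates.  Normalization is
   the only string processing performed; synonyms belong in the similarity
   map, not in fuzzy matching.
2. **Preparation form.** Among name matches, only those with the identical
   preparation form (raw, boiled, fried, dried, ...) qualify for direct
   assignment, because preparation changes composition substantially.
3. **Macronutrient tolerance.** The best qualifying candidate (similarity-map
   rank first, id order as tie-break) is compared on energy, carbohydrate,
   protein, fat and moisture.  If every relative difference — measured
   against the *item's* value — is at most the tolerance (default 20%,
   boundary inclusive), the analytical profile is copied verbatim:
   category **ANALYTICAL**.
4. **Nitrogen-corrected calculation.** If the direct screen fails but an
   analytical similar food is available (with a different preparation form
   in the name-matched branch, or any similar food otherwise outside
   tolerance), its profile is rescaled by the nitrogen ratio of target to
   similar food: category **CALCULATED**.  Nitrogen is never measured; it
   is derived from crude protein via the food group's nitrogen-to-protein
   conversion factor, independently for each food:
   \[ N = \mathrm{protein} / f_{\text{group}}, \qquad
      AA_{\mathrm{target}} = AA_{\mathrm{similar}} \times
      N_{\mathrm{target}} / N_{\mathrm{similar}} . \]
5. **Substitution.** Without a name match, an analytical similar food inside
   the tolerance is copied verbatim: category **SUBSTITUTED**.
6. **Deferral.** If no analytical data exist among the candidates the item is
   **DEFERRED** — a first-class terminal state, because real builds resolve
   deferrals in later passes when additional composition tables or
   literature values arrive (`resolve_deferred()` re-classifies only
   deferred entries, so coverage can only grow).

Every node visited is written to the item's decision trace, serialized to
the JSONL ledger, so the provenance of every value in the finished database
can be audited.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `tolerance` | 0.20 | inclusive relative macronutrient screen; base is the target item's value |
| `absolute_zero_band` | 0.5 units | pass band when a target nutrient is exactly 0 (relative difference undefined) |
| `nitrogen_factors` | 6.25 general, 5.83 cereals, 5.71 legumes, 6.38 dairy | nitrogen-to-protein divisors by food group, with a `default` fallback; **placeholders** — national tables publish their own revisions |
| `taa_keys` | 18 amino acids | the total-amino-acid sum; taurine is stored and reported but excluded (its sparse coverage would make TAA incomparable across foods) |
| `eaa_keys` | 10 amino acids | essential set, retaining histidine and arginine per composition-table practice |
| `coverage_variables` | TAA, EAA, 18 + TAU = 21 | denominator of overall coverage (populated cells / all cells) |
| `ear_table` | FAO/WHO/UNU 2007 adult values | **illustrative**; protein EAR is (0.66 g/kg/day)/0.9 × body weight |

Design choices that were genuinely open, and how they were settled:

* **Tolerance base and boundary.** The relative difference is computed
  against the item being matched (the fixed object of assignment), making
  the screen asymmetric but well-defined; exactly-20% differences pass
  (inclusive boundary), pinned by a test.
* **Single best candidate.** Where several analytical similar foods exist,
  the first-ranked similarity-map candidate is used rather than an average;
  averaging rules are not standardized and the single-source choice keeps
  provenance unambiguous.
* **Missing values are absent, never zero.** TAA/EAA are sums over the
  available constituents only, so they are computable for every
  non-deferred item; coverage counts populated cells.
* **Strict below-EAR comparison.** An intake exactly at the EAR counts as
  adequate.  Combined requirements are declared explicitly in the EAR
  table (`PHE+TYR` for the aromatic pair and `MET+CYS` for the sulfur
  pair, the form adult requirement values are published in); intakes of
  the constituents are summed before comparison.
* **Age bins** are the closed intervals 30–49, 50–64, 65–74 years; by
  default a participant outside every bin is an error (lenient mode
  excludes them with a message).
* **Rounding** is half-up to one decimal and happens only at
  report serialization — never inside computation.
* **Config is JSON** (`jsonlite` is universally available); all tabular
  interchange is CSV with empty cells meaning *missing*.

## The intake pipeline

Per-participant intake of amino acid $k$ is standard FFQ arithmetic,

\[ I_k = \sum_{\text{items } j} f_j \cdot \frac{g_j}{100} \cdot c_{jk}, \]

with $f_j$ the consumption frequency (events/day), $g_j$ the portion
(g/event) and $c_{jk}$ the database content (mg/100 g; missing contents
contribute nothing).  Protein intake uses the item protein values, TAA/EAA
are sums over the respective key sets, and the TAA-to-protein ratio
(TAA mg / protein mg × 100) is an internal-consistency diagnostic: summed
amino acids should fall below factor-derived protein because the latter
includes non-protein nitrogen.  `below_ear_proportions()` reports, per
stratum (total / men / women × age bin), the percentage of participants
whose intake falls strictly below their body-weight-scaled EAR.

## What the synthetic generator emulates — and what it does not

`generate_reference_set()` fabricates, for each item, the reference
candidates that force exactly one known path through the decision tree
(nutrient offsets inside ~15% for direct assignment, a ≥25% protein offset
with an analytical similar food for the calculated route, and so on) and
returns the forced category as ground truth; `build_database()` must
recover it for 100% of items at every seed.  Profiles are drawn so the 18
protein amino acids sum to 80–95% of protein × 1000, keeping TAA-to-protein
ratios in the band observed in real diets; default missingness mirrors the
structure of real coverage gaps (tryptophan and tyrosine slightly
incomplete, taurine substantially so).  The default assignment mix —
31% analytical / 64% calculated / 5% substituted / 0 deferred over 475
items — mirrors the composition of a real national-cohort database build.
Proportions are converted to counts by largest-remainder apportionment.

`generate_cohort()` draws 2000 participants (balanced sexes, ages uniform
on 30–74, weights normal by sex: 68 ± 9 kg men, 58 ± 8 kg women, truncated
at 35 kg), item consumption with probability 0.15 per item, log-normal
frequencies with the male scale above the female, and log-normal ~60 g
portions.  One global frequency scale is then calibrated so the realized
fraction of participants below the protein EAR equals `below_ear_target`
(default 25%) up to cohort granularity — the target is part of the stated
world, not a tuned quantity.

A green test on these fixtures establishes that the algorithm, the
arithmetic and the reports behave exactly as specified on inputs whose
truth is known.  It does **not** establish anything about real foods: the
generator does not imitate real food names, real inter-item nutrient
correlations, correlated response patterns, seasonal or energy-adjusted
intakes, or measurement error in FFQ responses, and the shipped EAR and
nitrogen-factor defaults are placeholders for the national values a real
analysis must supply.

## Numerical notes and limitations

* The nitrogen correction is a single multiplicative scalar per food; its
  identity, linearity and inverse-composition properties hold to 1e-9
  relative tolerance and are asserted in the acceptance tests.
* A similar food with zero derived nitrogen cannot be used for the
  calculated route and raises an error; a target nutrient of exactly zero
  switches the tolerance screen to the absolute band.
* Widening the tolerance can only move items from the calculated/deferred
  categories toward direct assignment, never the reverse (tested).
* No usual-intake deattenuation, energy adjustment or survey weighting is
  performed; prevalences are crude proportions.  Deattenuation in
  particular matters for real EAR-inadequacy estimates.
* Name matching is exact post-normalization; multilingual or fuzzy
  matching is out of scope by design.
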