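---
title: "Methods: disproportionality signal detection on spontaneous report data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signal detection on spontaneous report data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jadersignal)
```

## The analysis model

Spontaneous reporting systems collect voluntary reports of suspected
adverse drug reactions. Counts in such a database reflect *reporting*,
not incidence, so the only quantity that can be estimated is
disproportionality: whether a drug–event combination is reported more
often than expected if drug and event were independent within the
database.

`jadersignal` operates on an event-based **pair universe**. Each case is
reduced to its latest report version, the drug table is restricted to
*suspected* drugs (concomitant and interacting drugs are dropped to keep
the drug–event link strong), and the drug and reaction tables are joined
on the case identifier. The analysis unit is the unique
(case, suspected drug, PT) triple: each suspected drug of a multi-drug
report counts as a separate drug–event observation, but the same
drug/PT combination never counts twice within one case. The grand total
N of triples is the 2×2 denominator. An alternative `unit = "row"`
counting mode (every drug-row-by-event-row combination) is available
because public flow counts of this database family do not always state
which unit was used.

For drug D and event E the cells are a (D∧E), b (D∧¬E), c (¬D∧E),
d (remainder), and three statistics are computed:

* **ROR** = ad/bc, with 95% Wald interval
  $\exp(\ln \mathrm{ROR} \pm 1.96\sqrt{1/a+1/b+1/c+1/d})$;
* **PRR** = $[a/(a+b)] \,/\, [c/(c+d)]$;
* **χ²**, Pearson's 2×2 statistic, by default with the Yates continuity
  correction $N(|ad-bc|-N/2)^2/[(a+b)(c+d)(a+c)(b+d)]$, the subtraction
  floored at zero.

A **signal** requires both (a) the CI lower bound of the ROR to exceed
1 and (b) PRR ≥ 2 ∧ χ² ≥ 4 ∧ a ≥ 3. Both criteria sit in
`signal_config()` as data, so sensitivity analyses need no code changes.

## Tunable parameters

| parameter | default | rationale |
|---|---|---|
| `ci_low_threshold` | 1 (exclusive) | the conventional lower-bound rule |
| `prr_threshold`, `chi2_threshold`, `n_min` | 2, 4, 3 | the classical PRR-based triple |
| `yates` | `TRUE` | the PRR/χ²/n triple was originally proposed with the corrected statistic; plain Pearson via flag, since published analyses often omit stating the variant |
| `zero_policy` | `"undefined"` | a zero cell makes ROR (and an empty margin makes χ²) undefined; an undefined metric fails its criterion instead of erroring. `"haldane"` (+0.5 on all cells of affected tables) is offered for exploratory output only and never feeds the verdict |
| `match_on` | `"code"` | PT codes are stable across MedDRA releases while names drift; pairs without codes (as in real JADER reaction rows) fall back to name matching |
| `min_report_floor` | 1 | drugs never co-reported with the PT are omitted rather than emitted as non-signals |
| `dedup_strategy` | `"latest_version"` | later report iterations supersede earlier ones in this database family; `"first_seen"` is available for sensitivity checks |

Numerical choices: z is fixed at 1.96 exactly (not recomputed from a
quantile routine) so results are bit-stable across platforms; cell
counts are promoted to doubles before any product because the χ²
denominator overflows 32-bit integers at realistic database sizes;
output ordering is PT query order, then descending a, then drug name
(a deterministic convention — published tables rarely state theirs).

## Classification stages

Signal drugs are joined to a user-supplied therapeutic-category map
(3-digit Japanese commodity-classification codes). Drugs in categories
with prefix "42" — antineoplastic agents — are set aside, because
appetite and taste events in oncology reports are often attributable to
the underlying disease. The exclusion is applied *after* detection and
both partitions are reported, since public methods descriptions place
the rule in the classification step without stating the order. Drugs
missing from the map are routed to an explicit review list, never
silently dropped or guessed. Combination products are treated as single
drug entities. Package-insert annotation is a user-supplied table of
explicit per-drug flags; drugs without an entry are reported as
un-reviewed rather than defaulted.

## The synthetic generator

`simulation_config()` describes, per case: a zero-truncated Poisson
draw K of distinct drugs (parameter `drugs_per_case_lambda`; realized
mean $\lambda/(1-e^{-\lambda})$), drugs drawn with replacement by Zipf
popularity weight and deduplicated, an i.i.d. role per drug record
(default 70% suspected / 25% concomitant / 5% interacting), and
independent PT occurrences given the drug set — background rate for
ordinary PTs, p1/p0 for planted drug–event pairs depending on whether
the partner drug is present as a suspected drug. Every case also
receives one guaranteed background event drawn *independently of its
drug set*, so each case has at least one reaction row. A fraction
`duplicate_rate` of cases is re-emitted as a content-identical higher
report version. The with-replacement-then-deduplicate drug draw makes
$P(\text{drug present}) = 1 - \mathbb{E}[(1-w)^K]$ available in closed
form, so `planted_truth()` returns exact expectations without
simulation.

Defaults emulate a realistic screening situation: 30 drugs with Zipf
weights so b and d span magnitudes, the seven target appetite/taste PTs
at low background rates (0.001–0.01) plus eight common filler PTs
(0.03–0.06) so the event margin is dominated by non-target reporting.

### What the pair-level ROR actually estimates

Two structural facts, both discovered while validating the generator
and worth knowing when interpreting real analyses:

1. **Shared events leak across co-suspected drugs.** Events belong to
   the case, so when a planted drug shares its cases with other
   suspected drugs, the elevated event rate inflates those drugs'
   c-cell contribution and attenuates the planted drug's measured ROR.
   This is exactly the masking/competition bias described for real
   spontaneous-report databases.
2. **With non-scarce events the estimand is a rate ratio.** In the pair
   universe the "non-event" margin of a drug is its expected count of
   *other* events, not $1-p$; the ROR therefore converges to
   $p_1/p_0$ rather than the odds ratio
   $[p_1/(1-p_1)]/[p_0/(1-p_0)]$ unless both probabilities are small.
   Relatedly, any mechanism that adds events *conditionally* on a case
   having none couples the event margin to drug presence — which is why
   the generator's ≥1-event guarantee is unconditional.

The parameter-recovery study is therefore designed so that its estimand
*is* the planted odds ratio: predominantly single-suspected-drug cases
(`drugs_per_case_lambda = 0.1`, mean 1.05 drugs per case, so leak is
negligible) and rare-event probabilities (p1 ≈ 0.022), under which the
rate ratio and odds ratio agree to ~2%. Under those conditions the test
suite checks that the 95% CI covers a planted odds ratio of 5 in
90–98% of 200 replicates of 5,000 cases (expected a ≈ 20) and that the
geometric-mean ROR lands within 10% of 5. Detection operating
characteristics are measured separately under the multi-drug defaults
(where attenuation does not matter for flagging): a planted odds ratio
of 10 with expected a ≈ 30 must be flagged in ≥95% of 100 replicates of
3,500 cases, and in all-null datasets candidate pairs with expected
a ≥ 3 must be flagged in ≤5% of runs.

### What the generator does not emulate

No demographics, dates, dosages or outcomes; no reporting-trend or
safety-alert dynamics; PT occurrences are conditionally independent
given the drug set, so multi-event syndromes and term-choice drift are
absent; drug co-occurrence has no therapeutic structure (no co-prescription
clusters); and masking is present only to the mild degree implied by
shared cases, not the concentrated form a blockbuster drug causes in a
real database. Passing recovery tests therefore validates the
*machinery* — counting, margins, statistics, criteria — not robustness
to the biases of real spontaneous reporting, which remain the analyst's
responsibility to consider.

## Orchestration and reproducibility

`run_pipeline()` executes ingest → dedup → filter → link → extract →
detect → classify → report from a single `run_config()`, writes
Table-shaped TSVs plus machine-readable JSON, echoes the resolved
configuration (minus the output path) and a stage-count manifest
sufficient to redraw the analysis flow chart, and fails with the stage
name on any error. There is no interactive prompting and no unseeded
randomness anywhere in the analysis path; reruns on identical inputs
are byte-identical. Intermediate artifacts are not cached: every stage
is deterministic and runs in well under a second at desk scale, so a
content-hash cache would add failure modes without benefit. The
package deliberately ships no shell entry point — its users drive
analyses from R, and the exported functions are the stable surface.

Problem sizes in the shipped test suite were chosen to give stable
Monte-Carlo estimates at interactive runtimes: 200 replicates of 5,000
cases for CI coverage, 100 replicates of 3,500 cases each for
sensitivity and the null false-positive rate, an exhaustive
a,b,c,d ∈ {0..6} grid (2,401 tables) plus random tables for oracle
equivalence, and three sizes (1,000 / 4,000 / 16,000 cases) for the
root-n convergence check.

## Known limitations

* Drug identity is an exact normalized-string match (NFKC fold, trim,
  case fold) with an optional synonym map; brand/generic and salt-form
  variants that survive normalization count as distinct drugs.
* PT matching does not traverse the MedDRA hierarchy (no SOC/HLGT/HLT
  expansion, no SMQs); the query set is taken literally, by design —
  narrow PT sets prioritize signal specificity at a known cost in
  sensitivity.
* The χ² monotonicity property (more co-reports never weaken the
  statistic) holds only for tables at or above independence; below it,
  added co-reports move the table toward independence and χ² correctly
  falls.
* A signal is a hypothesis-generating flag. Nothing here adjusts for
  reporting bias, masking, confounding by indication, or multiplicity.
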