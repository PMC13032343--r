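# jadersignal

Disproportionality signal detection for spontaneous adverse drug event
report databases distributed as linked CSV tables in the JADER style
(the PMDA's public Japanese Adverse Drug Event Report dump). The package
was built for pharmacoepidemiologists screening appetite- and
taste-related adverse reactions — drug-induced decreased appetite and
taste disturbance are under-recognized contributors to undernutrition —
but every stage is generic over user-supplied Preferred Term (PT) query
sets, dialects, and classification tables.

## What it computes

Reports are reduced to an event-based **pair universe**: after removing
duplicate report versions (later report iterations supersede earlier
ones) and restricting the drug table to *suspected* drugs, the drug and
reaction tables are joined on the case identifier and collapsed to
unique (case, drug, PT) triples. Each suspected drug of a multi-drug
report is a separate analysis unit.

For a drug D and target event E over the N pairs:

|            | event E | other events |
|------------|---------|--------------|
| drug D     | a       | b            |
| other drugs| c       | d            |

- **ROR** = ad/bc, with the 95% Wald interval
  exp(ln ROR ± 1.96·√(1/a + 1/b + 1/c + 1/d));
- **PRR** = [a/(a+b)] / [c/(c+d)];
- **χ²** = Pearson's 2×2 statistic, Yates-corrected by default:
  N(|ad−bc|−N/2)² / [(a+b)(c+d)(a+c)(b+d)], the subtraction floored at 0.

A **signal** requires both (a) the CI lower bound of the ROR to exceed
1, and (b) PRR ≥ 2, χ² ≥ 4, and a ≥ 3 co-reports. Statistics undefined
on zero cells fail their criterion rather than erroring. Signal-detected
drugs are then classified by Japanese therapeutic category, drugs in
categories beginning "42" (antineoplastic agents) are set aside,
multi-PT drugs are tabulated, and package-insert annotation status is
cross-tabulated.

A seeded synthetic generator (`simulation_config()`,
`generate_dataset()`) emits JADER-format tables with planted drug–event
associations of known odds ratio and a truth registry, so dedup,
linking, extraction, detection and classification are all verifiable
without downloading the real database.

## Worked example

```r
library(jadersignal)
ext <- function(f) system.file("extdata", f, package = "jadersignal")

res <- run_pipeline(run_config(
  drug_path = ext("drug_toy.csv"),
  reac_path = ext("reac_toy.csv"),
  dialect = dialect_ascii(),            # real JADER dumps: dialect_jader()
  category_map_path = ext("category_toy.csv")
))
res$manifest
#> <run_manifest>
#>   drug rows read:      12 -> after dedup: 12 (12 cases)
#>   reac rows read:      14 -> after dedup: 13 (12 cases)
#>   suspected records:   9
#>   drug-event pairs:    10 (target-PT subset: 6)
#>   candidates tested:   3
#>   signals:             0 [Appetite disorder=0, Decreased appetite=0, Abnormal loss of weight=0, Ageusia=0, Dysgeusia=0, Hypogeusia=0, Taste disorder=0]
```

The 12-case toy fixture carries 9 suspected-drug records; linking gives
N = 10 pairs, of which 6 match the packaged appetite/taste PT set.
Three (drug, PT) candidates are evaluated — for example (drugx,
Decreased appetite) has cells (a=3, b=2, c=1, d=4), ROR = 6 with a CI
lower bound far below 1, PRR = 3, Yates χ² = 0.417 — and none meets the
composite criterion, so the run reports zero signals. On a synthetic
dataset with a planted association the same pipeline flags the planted
pair:

```r
cfg <- simulation_config(
  n_cases = 3000,
  planted = tibble::tibble(drug_name = "drug003", pt_name = "Dysgeusia",
                           p1 = 0.12, p0 = 0.004),
  seed = 21
)
paths <- generate_dataset(cfg, tempdir())
res <- run_pipeline(run_config(paths$drug, paths$reac,
                               dialect = dialect_ascii()))
subset(res$signals, signal,
       select = c(drug_name, pt_name, a, ror, ci_low, prr, chi2))
#> # A tibble: 2 × 7
#>   drug_name pt_name        a   ror ci_low   prr   chi2
#> 1 drug003   Dysgeusia     52  7.40   5.12  6.86 149.
#> 2 drug009   Hypogeusia     3  6.63   1.90  6.54   7.48
```

The planted pair dominates (52 co-reports, χ² = 149). The second row is
a chance background flag sitting right at the criterion floor — a
reminder that a signal is a hypothesis-generating flag, not proof of
causality. Note also that the measured ROR (7.4) sits well below the
planted case-level odds ratio (34): with a popular drug, the planted
event leaks into co-suspected drugs' margins and the pair-level
statistic is attenuated — the masking behaviour real databases show.
The methods vignette explains this estimand question and how the
package's parameter-recovery study is designed around it.

To reproduce the published headline counts (2,516,004 linked pairs;
20,638 target-PT reports; 54/14/24/13 signal drugs), download the May
2025 JADER snapshot from the PMDA, then run `run_pipeline()` with
`dialect_jader()`, the packaged PT set, and your therapeutic-category
map; the manifest mirrors the published flow counts stage by stage.

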