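# Toy fixture: hand tabulation

`drug_toy.csv` (12 rows, 12 cases, ASCII dialect) and `reac_toy.csv`
(14 rows; case C01 appears under report versions 1 and 2 with identical
content). All numbers below are derived by hand and frozen into the test
suite; the pipeline must reproduce them exactly.

Flow counts (latest-version dedup, suspected-only, triple counting unit):

| stage                         | count |
|-------------------------------|-------|
| drug rows read                | 12    |
| reac rows read                | 14    |
| drug rows after dedup         | 12    |
| reac rows after dedup         | 13 (C01 keeps version 2 only) |
| cases (both tables)           | 12    |
| suspected drug records        | 9 (C01-C09) |
| drug-event pairs (N)          | 10    |
| target-PT subset              | 6     |

Per-PT (default query set): Decreased appetite 4 reports / 2 drugs
(drugx, drugz); Dysgeusia 2 reports / 1 drug (drugy); all others 0.

Pair list (case, suspected drug, PT): C01 (drugx, Decreased appetite);
C02 (drugx, Decreased appetite), (drugx, Nausea); C03 (drugx, Decreased
appetite); C04 (drugx, Nausea); C05 (drugy, Dysgeusia); C06 (drugy,
Dysgeusia); C07 (drugy, Nausea); C08 (drugz, Decreased appetite);
C09 (drugz, Nausea). Cases C10-C12 carry no suspected drug and
contribute no pairs.

Candidate 2x2 tables against N = 10:

| drug  | PT                 | a | b | c | d |
|-------|--------------------|---|---|---|---|
| drugx | Decreased appetite | 3 | 2 | 1 | 4 |
| drugz | Decreased appetite | 1 | 1 | 3 | 5 |
| drugy | Dysgeusia          | 2 | 1 | 0 | 7 |

Metrics for (drugx, Decreased appetite): ROR = (3*4)/(2*1) = 6;
PRR = (3/5)/(1/5) = 3; chi-squared plain = 10*(12-2)^2/(5*5*4*6)
= 5/3 ~ 1.6667; with Yates = 10*(10-5)^2/600 ~ 0.41667. The CI lower
bound is below 1 and chi-squared is below 4, so nothing in the toy is a
signal (n_signals = 0) — the fixture exercises bookkeeping and
byte-stable reporting, not detection.

For (drugy, Dysgeusia) the c cell is 0, so ROR and PRR are undefined
under the default zero-cell policy.
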