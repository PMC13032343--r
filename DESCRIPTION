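Package: jadersignal
Title: Disproportionality Signal Detection for JADER-Style Spontaneous
    Adverse Event Report Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal detection on spontaneous
    adverse drug reaction report databases distributed as linked CSV
    tables in the style of the Japanese Adverse Drug Event Report (JADER)
    database. Reads drug and reaction tables, removes duplicate report
    versions, restricts to suspected drugs, links tables into a
    case-drug-event pair universe, extracts MedDRA Preferred Term (PT)
    targets, computes reporting odds ratios (ROR) with Wald confidence
    intervals, proportional reporting ratios (PRR) and 2x2 chi-squared
    statistics, applies a composite signal criterion, classifies
    signal-detected drugs by Japanese therapeutic category, and
    cross-tabulates package-insert annotation status. Includes a
    seeded synthetic report generator with planted drug-event
    associations of known odds ratio for end-to-end verification and
    operating-characteristic estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
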