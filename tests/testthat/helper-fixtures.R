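# Shared fixtures and independent oracles for the suite.

extdata <- function(name) {
  system.file("extdata", name, package = "jadersignal", mustWork = TRUE)
}

toy_universe <- function() {
  d <- read_report_table(extdata("drug_toy.csv"), "drug", dialect_ascii())
  r <- read_report_table(extdata("reac_toy.csv"), "reac", dialect_ascii())
  link_drug_event(filter_suspected(deduplicate_cases(d)),
                  deduplicate_cases(r))
}

# write a small Japanese-header, CP932-encoded drug CSV; returns the path
write_cp932_drug_csv <- function(dir, roles = c("被疑薬", "併用薬", "相互作用")) {
  lines <- c(
    "識別番号,報告回数,医薬品連番,医薬品の関与,医薬品（一般名）",
    sprintf("JP%02d,1,1,%s,アセトアミノフェン", seq_along(roles), roles)
  )
  path <- file.path(dir, "drug_jp.csv")
  bytes <- iconv(paste0(paste(lines, collapse = "\n"), "\n"),
                 from = "UTF-8", to = "CP932", toRaw = TRUE)[[1]]
  writeBin(bytes, path)
  path
}

# random record tables for property tests
random_drug_records <- function(n_cases, seed) {
  set.seed(seed)
  n <- sample(1:3, n_cases, replace = TRUE)
  tibble::tibble(
    case_id = rep(sprintf("R%03d", seq_len(n_cases)), n),
    version = sample(1:3, sum(n), replace = TRUE),
    drug_seq = unlist(lapply(n, seq_len)),
    role = sample(drug_roles(), sum(n), replace = TRUE),
    drug_name = sample(sprintf("d%02d", 1:6), sum(n), replace = TRUE)
  )
}

random_event_records <- function(n_cases, seed) {
  set.seed(seed)
  n <- sample(1:3, n_cases, replace = TRUE)
  tibble::tibble(
    case_id = rep(sprintf("R%03d", seq_len(n_cases)), n),
    version = sample(1:3, sum(n), replace = TRUE),
    pt_name = sample(c("Nausea", "Dysgeusia", "Decreased appetite", "Rash"),
                     sum(n), replace = TRUE),
    pt_code = NA_character_
  )
}

# ---- independent oracles (deliberately scalar, second implementations) -----

# brute-force (case, suspected drug, PT) triple universe from raw records:
# dedup by max version, then loop case by case
oracle_pair_triples <- function(drugs, events) {
  keep_latest <- function(tbl) {
    do.call(rbind, lapply(split(tbl, tbl$case_id), function(g) {
      g <- g[g$version == max(g$version), , drop = FALSE]
      g[!duplicated(g, fromLast = TRUE), , drop = FALSE]
    }))
  }
  d <- keep_latest(as.data.frame(drugs))
  d <- d[d$role == "suspected", , drop = FALSE]
  e <- keep_latest(as.data.frame(events))
  out <- character()
  for (cs in intersect(unique(d$case_id), unique(e$case_id))) {
    dn <- unique(d$drug_name[d$case_id == cs])
    pn <- unique(e$pt_name[e$case_id == cs])
    for (x in dn) for (y in pn) out <- c(out, paste(cs, x, y, sep = "|"))
  }
  sort(unique(out))
}

# scalar second implementation of the three statistics and the verdict
oracle_metrics <- function(a, b, c, d, yates) {
  a <- as.double(a); b <- as.double(b); c <- as.double(c); d <- as.double(d)
  N <- a + b + c + d
  ror <- NA_real_; lo <- NA_real_; hi <- NA_real_
  if (min(a, b, c, d) > 0) {
    lor <- log(a) + log(d) - log(b) - log(c)
    s <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    ror <- exp(lor); lo <- exp(lor - 1.96 * s); hi <- exp(lor + 1.96 * s)
  }
  prr <- if ((a + b) > 0 && c > 0) (a * (c + d)) / ((a + b) * c) else NA_real_
  chi <- NA_real_
  if ((a + b) > 0 && (c + d) > 0 && (a + c) > 0 && (b + d) > 0) {
    dev <- abs(a * d - b * c)
    if (yates) dev <- max(dev - N / 2, 0)
    chi <- N * dev * dev / ((a + b) * (c + d) * (a + c) * (b + d))
  }
  list(ror = ror, ci_low = lo, ci_high = hi, prr = prr, chi2 = chi, n = a)
}

oracle_verdict <- function(m) {
  ca <- !is.na(m$ci_low) && m$ci_low > 1
  cb <- !is.na(m$prr) && !is.na(m$chi2) &&
    m$prr >= 2 && m$chi2 >= 4 && m$n >= 3
  list(criterion_a = ca, criterion_b = cb, signal = ca && cb)
}
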