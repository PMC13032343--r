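test_that("configuration validation names the offending field", {
  expect_error(simulation_config(0), "n_cases")
  expect_error(simulation_config(10, drug_catalog = tibble::tibble(
    drug_name = "d", weight = -1)), "drug_catalog")
  expect_error(simulation_config(10, planted = tibble::tibble(
    drug_name = "drug001", pt_name = "Nausea", p1 = 0.1, p0 = 0.5)), "planted")
  expect_error(simulation_config(10, planted = tibble::tibble(
    drug_name = "no-such", pt_name = "Nausea", p1 = 0.5, p0 = 0.1)), "planted")
  expect_error(simulation_config(10, duplicate_rate = 1), "duplicate_rate")
  expect_error(simulation_config(10, role_mix = c(suspected = 1)), "role_mix")
})

test_that("planted truth follows the closed forms", {
  cfg1 <- simulation_config(100, planted = tibble::tibble(
    drug_name = "drug001", pt_name = "Dysgeusia", p1 = 0.5, p0 = 0.01))
  tr <- planted_truth(cfg1)
  expect_equal(tr$implied_or, (0.5 / 0.5) / (0.01 / 0.99))  # 99
  cfg2 <- simulation_config(100, planted = tibble::tibble(
    drug_name = "drug001", pt_name = "Dysgeusia", p1 = 0.2, p0 = 0.2))
  expect_equal(planted_truth(cfg2)$implied_or, 1)

  # singleton-drug catalog: the drug is always present, role mix exact
  single <- tibble::tibble(drug_name = "only", category_code = "119",
                           category_label = "CNS", weight = 1)
  cfg3 <- simulation_config(
    200, drug_catalog = single,
    planted = tibble::tibble(drug_name = "only", pt_name = "Dysgeusia",
                             p1 = 0.3, p0 = 0.01),
    role_mix = c(suspected = 1, concomitant = 0, interacting = 0))
  tr3 <- planted_truth(cfg3)
  expect_equal(tr3$p_present, 1)
  expect_equal(tr3$expected_a, 200 * 0.3)
})

test_that("realized planted counts match their expectation over many seeds", {
  single <- tibble::tibble(drug_name = "only", category_code = "119",
                           category_label = "CNS", weight = 1)
  base <- simulation_config(
    200, drug_catalog = single,
    planted = tibble::tibble(drug_name = "only", pt_name = "Dysgeusia",
                             p1 = 0.3, p0 = 0.01),
    role_mix = c(suspected = 1, concomitant = 0, interacting = 0))
  n_rep <- 400
  a_vals <- vapply(seq_len(n_rep), function(s) {
    cfg <- base; cfg$seed <- 10000L + s
    simulate_reports(cfg)$truth$planted$realized_a
  }, numeric(1))
  expected <- planted_truth(base)$expected_a
  se <- stats::sd(a_vals) / sqrt(n_rep)
  expect_lt(abs(mean(a_vals) - expected), 3 * se + 1e-9)
})

test_that("generation is deterministic and injects the configured duplicates", {
  cfg <- simulation_config(10, duplicate_rate = 0, seed = 1L)
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  p1 <- generate_dataset(cfg, dir1)
  p2 <- generate_dataset(cfg, dir2)
  for (k in c("drug", "reac", "truth")) {
    expect_identical(readBin(p1[[k]], "raw", file.size(p1[[k]])),
                     readBin(p2[[k]], "raw", file.size(p2[[k]])))
  }
  d <- read_report_table(p1$drug, "drug", cfg$dialect)
  r <- read_report_table(p1$reac, "reac", cfg$dialect)
  expect_equal(dplyr::n_distinct(d$case_id), 10)
  expect_equal(dplyr::n_distinct(r$case_id), 10)

  cfg_dup <- simulation_config(500, duplicate_rate = 0.2, seed = 7L)
  sim <- simulate_reports(cfg_dup)
  expect_equal(sim$truth$n_duplicate_cases, 100)
  dd <- deduplicate_cases(sim$drug)
  expect_equal(dplyr::n_distinct(dd$case_id), 500)
  expect_equal(dplyr::n_distinct(sim$drug$case_id), sim$truth$n_cases)
  # duplicated cases carry two versions before dedup, one after
  dup_ids <- sim$truth$duplicate_case_ids
  expect_equal(dplyr::n_distinct(sim$drug$version[sim$drug$case_id %in% dup_ids]), 2)
  expect_equal(unique(dd$version[dd$case_id %in% dup_ids]), 2L)
})

test_that("generated files round-trip through ingestion with zero validation errors", {
  for (dia in list(dialect_ascii(), dialect_jader())) {
    cfg <- simulation_config(60, duplicate_rate = 0.1, seed = 11L,
                             dialect = dia)
    dir <- withr::local_tempdir()
    paths <- generate_dataset(cfg, dir)
    d <- read_report_table(paths$drug, "drug", dia)
    r <- read_report_table(paths$reac, "reac", dia)
    sim <- simulate_reports(cfg)
    expect_equal(nrow(d), nrow(sim$drug))
    expect_equal(nrow(r), nrow(sim$reac))
    expect_setequal(unique(d$role), drug_roles())
  }
})

test_that("per-role counts and pair totals match the truth registry exactly", {
  cfg <- simulation_config(
    300, duplicate_rate = 0.15,
    planted = tibble::tibble(drug_name = "drug003", pt_name = "Taste disorder",
                             p1 = 0.4, p0 = 0.01),
    seed = 7L)
  sim <- simulate_reports(cfg)
  drugs <- deduplicate_cases(sim$drug)
  expect_equal(
    c(table(factor(drugs$role, levels = drug_roles()))),
    c(sim$truth$role_counts)
  )
  suspected <- filter_suspected(drugs)
  expect_equal(nrow(suspected), sim$truth$n_suspected_records)
  u <- link_drug_event(suspected, deduplicate_cases(sim$reac))
  expect_equal(n_total(u), sim$truth$n_pairs)
})

test_that("the pipeline ROR converges to the implied odds ratio with size", {
  # single-suspect, rare-event design: the pair-level ROR estimand then
  # coincides with the planted case-level odds ratio (see vignette)
  pl <- tibble::tibble(drug_name = "drug001", pt_name = "Dysgeusia",
                       p1 = 0.04, p0 = 0.01)
  make_cfg <- function(n_cases, seed) {
    simulation_config(n_cases, planted = pl, drugs_per_case_lambda = 0.1,
                      seed = seed)
  }
  true_lor <- log(planted_truth(make_cfg(10, 1))$implied_or)
  rmse_at <- function(n_cases, n_rep, seed0) {
    errs <- vapply(seq_len(n_rep), function(s) {
      cfg <- make_cfg(n_cases, seed0 + s)
      sim <- simulate_reports(cfg)
      u <- link_drug_event(filter_suspected(deduplicate_cases(sim$drug)),
                           deduplicate_cases(sim$reac))
      res <- detect_signals(u, as_pt_queries(
        cfg$pt_catalog[, c("pt_name", "pt_code")]))
      row <- res[res$drug_name == "drug001" & res$pt_name == "Dysgeusia", ]
      if (nrow(row) == 0 || is.na(row$ror)) return(NA_real_)
      log(row$ror) - true_lor
    }, numeric(1))
    sqrt(mean(errs^2, na.rm = TRUE))
  }
  rmse <- c(rmse_at(1000, 8, 100), rmse_at(4000, 8, 200),
            rmse_at(16000, 8, 300))
  expect_true(all(diff(rmse) < 0))
  # roughly root-n decay: a 16-fold size increase should cut the error
  # by clearly more than half
  expect_lt(rmse[3], rmse[1] / 2)
})
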