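test_that("the balanced table gives ROR = PRR = 1 and chi-squared 0", {
  r <- compute_ror(25, 25, 25, 25)
  expect_equal(r$ror, 1)
  # CI symmetric about 1 on the log scale
  expect_equal(r$ci_low * r$ci_high, 1)
  expect_equal(compute_prr(25, 25, 25, 25), 1)
  expect_equal(compute_chi_squared(25, 25, 25, 25, yates = FALSE), 0)
})

test_that("the reference table reproduces its hand-computed statistics", {
  r <- compute_ror(10, 90, 100, 9800)
  expect_equal(r$ror, 98000 / 9000, tolerance = 1e-12)
  expect_equal(r$ci_low, 5.5033, tolerance = 1e-4)
  expect_equal(r$ci_high, 21.5447, tolerance = 1e-4)
  expect_equal(compute_prr(10, 90, 100, 9800), 9.9, tolerance = 1e-12)
  expect_equal(compute_chi_squared(10, 90, 100, 9800, yates = FALSE),
               73.5455, tolerance = 1e-4)
  expect_equal(compute_chi_squared(10, 90, 100, 9800, yates = TRUE),
               65.5140, tolerance = 1e-4)
})

test_that("zero cells yield undefined metrics under the default policy", {
  expect_true(is.na(compute_ror(0, 10, 10, 100)$ror))
  expect_true(is.na(compute_ror(5, 0, 10, 100)$ci_low))
  expect_true(is.na(compute_prr(5, 10, 0, 100)))   # c = 0
  expect_true(is.na(compute_prr(0, 0, 5, 100)))    # a + b = 0
  expect_true(is.na(compute_chi_squared(0, 0, 5, 100)))  # empty margin
  # Yates subtraction floors at zero when |ad - bc| < N/2
  expect_equal(compute_chi_squared(1, 1, 1, 2, yates = TRUE), 0)
  # Haldane policy defines the exploratory values instead
  h <- compute_ror(0, 10, 10, 100, zero_policy = "haldane")
  expect_equal(h$ror, (0.5 * 100.5) / (10.5 * 10.5))
})

test_that("large counts do not overflow the chi-squared denominator", {
  expect_gt(compute_chi_squared(500, 100000, 2000, 2500000, yates = FALSE), 0)
})

test_that("statistics match an independent scalar oracle on the exhaustive small grid", {
  grid <- expand.grid(a = 0:6, b = 0:6, c = 0:6, d = 0:6)
  for (yates in c(FALSE, TRUE)) {
    got_ror <- compute_ror(grid$a, grid$b, grid$c, grid$d)
    got_prr <- compute_prr(grid$a, grid$b, grid$c, grid$d)
    got_chi <- compute_chi_squared(grid$a, grid$b, grid$c, grid$d, yates)
    verdict <- evaluate_criteria(got_ror$ci_low, got_prr, got_chi, grid$a)
    for (i in seq_len(nrow(grid))) {
      m <- oracle_metrics(grid$a[i], grid$b[i], grid$c[i], grid$d[i], yates)
      expect_equal(got_ror$ror[i], m$ror, tolerance = 1e-9)
      expect_equal(got_ror$ci_low[i], m$ci_low, tolerance = 1e-9)
      expect_equal(got_ror$ci_high[i], m$ci_high, tolerance = 1e-9)
      expect_equal(got_prr[i], m$prr, tolerance = 1e-9)
      expect_equal(got_chi[i], m$chi2, tolerance = 1e-9)
      v <- oracle_verdict(m)
      expect_identical(verdict$criterion_a[i], v$criterion_a)
      expect_identical(verdict$criterion_b[i], v$criterion_b)
      expect_identical(verdict$signal[i], v$signal)
    }
  }
})

test_that("chi-squared agrees with stats::chisq.test on random all-positive tables", {
  set.seed(7)
  for (i in 1:50) {
    a <- sample(1:50, 1); b <- sample(1:500, 1)
    c <- sample(1:100, 1); d <- sample(1:5000, 1)
    tab <- matrix(c(a, c, b, d), 2)
    # chisq.test warns about small expected counts; only the statistic matters
    ref_plain <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    ref_yates <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    expect_equal(compute_chi_squared(a, b, c, d, yates = FALSE),
                 unname(ref_plain$statistic), tolerance = 1e-10)
    expect_equal(compute_chi_squared(a, b, c, d, yates = TRUE),
                 unname(ref_yates$statistic), tolerance = 1e-10)
  }
})

test_that("ROR and its Wald interval agree with an unconditional logistic fit", {
  set.seed(11)
  for (i in 1:10) {
    a <- sample(3:40, 1); b <- sample(10:400, 1)
    c <- sample(3:80, 1); d <- sample(100:4000, 1)
    fit <- stats::glm(cbind(c(a, c), c(b, d)) ~ c(1, 0), family = stats::binomial())
    got <- compute_ror(a, b, c, d)
    # IRLS converges to the closed form only to ~1e-6
    expect_equal(log(got$ror), unname(stats::coef(fit)[2]), tolerance = 1e-5)
    se <- sqrt(stats::vcov(fit)[2, 2])
    expect_equal(got$ci_low, exp(unname(stats::coef(fit)[2]) - 1.96 * se),
                 tolerance = 1e-5)
  }
})

test_that("adding co-reports above independence never weakens any statistic", {
  set.seed(1)
  n_fam <- 0
  while (n_fam < 50) {
    a <- sample(1:20, 1); b <- sample(5:200, 1)
    c <- sample(1:50, 1); d <- sample(200:5000, 1)
    if (a * d < b * c) next
    k_max <- min(b, c, floor(d / 2)) - 1 - a
    if (k_max < 1) next
    n_fam <- n_fam + 1
    k <- 0:k_max
    ror <- compute_ror(a + k, rep(b, k_max + 1), rep(c, k_max + 1), d - k)$ror
    prr <- compute_prr(a + k, rep(b, k_max + 1), rep(c, k_max + 1), d - k)
    ch <- compute_chi_squared(a + k, rep(b, k_max + 1), rep(c, k_max + 1),
                              d - k, yates = FALSE)
    chy <- compute_chi_squared(a + k, rep(b, k_max + 1), rep(c, k_max + 1),
                               d - k, yates = TRUE)
    expect_true(all(diff(ror) > 0))
    expect_true(all(diff(prr) > 0))
    expect_true(all(diff(ch) >= -1e-9))
    expect_true(all(diff(chy) >= -1e-9))
  }
})

test_that("ROR converges to PRR when the drug and event are rare", {
  a <- c(2, 5, 1); b <- c(1e5, 2e5, 5e5); c <- c(3, 8, 2); d <- c(1e6, 3e6, 8e6)
  ror <- compute_ror(a, b, c, d)$ror
  prr <- compute_prr(a, b, c, d)
  expect_true(all(abs(ror - prr) / prr < 1e-3))
})

test_that("build_contingency partitions the universe and tolerates absent drugs", {
  u <- toy_universe()
  q_da <- default_pt_set()[2, ]
  tab <- build_contingency(u, "drugx", q_da)
  expect_equal(unlist(tab), c(a = 3, b = 2, c = 1, d = 4))
  expect_equal(sum(unlist(tab)), n_total(u))

  absent <- build_contingency(u, "no-such-drug", q_da)
  expect_equal(absent$a + absent$b, 0)
  expect_equal(absent$c + absent$d, n_total(u))

  # cells equal four independent filters on random synthetic universes
  for (seed in 1:10) {
    d0 <- deduplicate_cases(random_drug_records(25, seed))
    e0 <- deduplicate_cases(random_event_records(25, seed + 500))
    uu <- link_drug_event(filter_suspected(d0), e0)
    if (n_total(uu) == 0) next
    drug <- sample(unique(uu$drug_name), 1)
    q <- as_pt_queries(tibble::tibble(pt_name = "Dysgeusia",
                                      pt_code = "10013911"))
    tt <- build_contingency(uu, drug, q, match_on = "name")
    is_d <- uu$drug_name == drug
    is_p <- uu$pt_name == "Dysgeusia"
    expect_equal(unlist(tt), c(a = sum(is_d & is_p), b = sum(is_d & !is_p),
                               c = sum(!is_d & is_p), d = sum(!is_d & !is_p)))
  }
})

test_that("detect_signals emits full provenance in deterministic order", {
  u <- toy_universe()
  res <- detect_signals(u)
  expect_equal(nrow(res), 3)
  expect_equal(res$drug_name, c("drugx", "drugz", "drugy"))
  expect_equal(res$a + res$b + res$c + res$d, rep(n_total(u), 3))
  expect_equal(res$n, res$a)
  expect_false(any(res$signal))
  x <- res[res$drug_name == "drugx", ]
  expect_equal(unlist(x[, c("a", "b", "c", "d")]), c(a = 3, b = 2, c = 1, d = 4))
  expect_equal(x$ror, 6)
  expect_equal(x$prr, 3)
  expect_equal(x$chi2, 10 * 25 / 600)  # Yates default
  # a planted strong association is flagged, and only that pair
  cfg <- simulation_config(
    n_cases = 2000,
    planted = tibble::tibble(drug_name = "drug001",
                             pt_name = "Decreased appetite",
                             p1 = 0.5, p0 = 0.01),
    seed = 21L
  )
  sim <- simulate_reports(cfg)
  uu <- link_drug_event(filter_suspected(deduplicate_cases(sim$drug)),
                        deduplicate_cases(sim$reac))
  r2 <- detect_signals(uu, default_pt_set())
  flagged <- r2[r2$signal, ]
  # the planted pair is flagged, and it is the only flag for its PT
  expect_true(any(flagged$drug_name == "drug001" &
                    flagged$pt_name == "Decreased appetite"))
  expect_equal(flagged$drug_name[flagged$pt_name == "Decreased appetite"],
               "drug001")
})

test_that("criteria thresholds are configurable and flip at the documented edges", {
  cfg <- signal_config(prr_threshold = 3)
  v <- evaluate_criteria(1.5, 2.5, 10, 5, cfg)
  expect_false(v$criterion_b)
  expect_error(signal_config(prr_threshold = -1))
})
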