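# Disproportionality statistics on per-(drug, PT) 2x2 tables and the
# composite signal criterion.
#
# For one drug D and one target event E over the pair universe of N
# drug-event pairs:
#     a = pairs with D and E        b = pairs with D, other events
#     c = pairs with E, other drugs d = all remaining pairs
# ROR = ad/bc with a 95% Wald CI on the log-odds scale,
# PRR = [a/(a+b)] / [c/(c+d)],
# chi-squared = Pearson's 2x2 independence statistic, optionally with the
# Yates continuity correction N(|ad-bc|-N/2)^2 / [(a+b)(c+d)(a+c)(b+d)],
# the subtraction floored at zero.
#
# A signal requires BOTH
#   (a) the CI lower bound of the ROR > 1, and
#   (b) PRR >= 2 AND chi-squared >= 4 AND a >= 3 reports.
# A statistic undefined under the zero-cell policy fails its criterion; it
# never errors.

# z for the 95% Wald interval, fixed rather than recomputed from qnorm so
# results are bit-stable across platforms
WALD_Z95 <- 1.96

#' Signal-detection configuration
#'
#' Thresholds and numerical policies of the composite criterion. The
#' defaults are the established frequentist convention for spontaneous
#' report databases: CI lower bound of the ROR above 1, PRR at least 2,
#' chi-squared at least 4, and at least 3 co-reports.
#'
#' @param ci_low_threshold Criterion (a): required lower bound of the ROR's
#'   95% CI (exclusive).
#' @param prr_threshold Criterion (b): minimum PRR (inclusive).
#' @param chi2_threshold Criterion (b): minimum chi-squared (inclusive).
#' @param n_min Criterion (b): minimum number of co-reports `a` (inclusive).
#' @param yates Apply the Yates continuity correction to chi-squared
#'   (default `TRUE`, the form under which the PRR/chi-squared/n triple was
#'   originally proposed); `FALSE` gives the plain Pearson statistic.
#' @param zero_policy `"undefined"` (default): a 2x2 table with an empty
#'   cell yields an undefined ROR (and an empty margin an undefined
#'   chi-squared), which fails the corresponding criterion.
#'   `"haldane"`: add 0.5 to every cell of such tables before computing ROR
#'   and PRR — exploratory output only, never a basis for the headline
#'   verdict.
#' @param match_on How pairs are matched to PT queries; see
#'   [extract_target_pairs()].
#' @param min_report_floor Candidate (drug, PT) pairs must have at least
#'   this many co-reports to be evaluated at all (default 1; drugs never
#'   co-reported with the PT are omitted, not emitted as non-signals).
#' @return A list of class `signal_config`.
#' @export
signal_config <- function(ci_low_threshold = 1, prr_threshold = 2,
                          chi2_threshold = 4, n_min = 3, yates = TRUE,
                          zero_policy = c("undefined", "haldane"),
                          match_on = c("code", "name", "either"),
                          min_report_floor = 1L) {
  zero_policy <- match.arg(zero_policy)
  match_on <- match.arg(match_on)
  stopifnot(ci_low_threshold > 0, prr_threshold > 0, chi2_threshold > 0,
            n_min >= 0, min_report_floor >= 0)
  structure(
    list(ci_low_threshold = ci_low_threshold, prr_threshold = prr_threshold,
         chi2_threshold = chi2_threshold, n_min = n_min, yates = yates,
         zero_policy = zero_policy, match_on = match_on,
         min_report_floor = as.integer(min_report_floor)),
    class = "signal_config"
  )
}

#' Build the 2x2 contingency table for one drug and one PT
#'
#' Partitions the pair universe into the four cells; the cells always sum to
#' `n_total(universe)`. A drug absent from the universe gives `a = b = 0`
#' (not an error).
#'
#' @param universe A [pair_universe].
#' @param drug_name Normalized drug name.
#' @param pt_query One-row PT query (tibble with `pt_name`, `pt_code`).
#' @param match_on See [extract_target_pairs()].
#' @return One-row tibble with columns `a`, `b`, `c`, `d`.
#' @export
build_contingency <- function(universe, drug_name, pt_query,
                              match_on = c("code", "name", "either")) {
  match_on <- match.arg(match_on)
  stopifnot(nrow(universe) > 0)
  is_pt <- pair_matches(universe, pt_query, match_on)
  is_drug <- universe$drug_name == drug_name
  tibble::tibble(
    a = sum(is_drug & is_pt),
    b = sum(is_drug & !is_pt),
    c = sum(!is_drug & is_pt),
    d = sum(!is_drug & !is_pt)
  )
}

apply_zero_policy <- function(a, b, c, d, zero_policy) {
  # doubles throughout: cell products overflow 32-bit integers easily
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  if (zero_policy == "haldane") {
    zero <- a == 0 | b == 0 | c == 0 | d == 0
    list(a = a + 0.5 * zero, b = b + 0.5 * zero,
         c = c + 0.5 * zero, d = d + 0.5 * zero)
  } else {
    list(a = a, b = b, c = c, d = d)
  }
}

#' Reporting odds ratio with 95% Wald confidence interval
#'
#' `ROR = ad/bc`; the interval is
#' `exp(log(ROR) +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`.
#' Vectorized over the cells. Under the default zero-cell policy any empty
#' cell makes all three values `NA` (undefined is a value state, not an
#' error); under `"haldane"` 0.5 is added to every cell of affected tables.
#'
#' @param a,b,c,d 2x2 cell counts (vectors of equal length).
#' @param zero_policy `"undefined"` or `"haldane"`.
#' @return Tibble with columns `ror`, `ci_low`, `ci_high`.
#' @export
compute_ror <- function(a, b, c, d, zero_policy = c("undefined", "haldane")) {
  zero_policy <- match.arg(zero_policy)
  cells <- apply_zero_policy(a, b, c, d, zero_policy)
  ok <- cells$a > 0 & cells$b > 0 & cells$c > 0 & cells$d > 0
  ror <- ifelse(ok, (cells$a * cells$d) / (cells$b * cells$c), NA_real_)
  se <- ifelse(ok,
               sqrt(1 / cells$a + 1 / cells$b + 1 / cells$c + 1 / cells$d),
               NA_real_)
  tibble::tibble(
    ror = ror,
    ci_low = exp(log(ror) - WALD_Z95 * se),
    ci_high = exp(log(ror) + WALD_Z95 * se)
  )
}

#' Proportional reporting ratio
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`, the event's reporting proportion among the
#' drug's pairs over that among all other drugs' pairs. Undefined (`NA`)
#' when `a + b == 0` or `c == 0`.
#'
#' @inheritParams compute_ror
#' @return Numeric vector of PRR values.
#' @export
compute_prr <- function(a, b, c, d, zero_policy = c("undefined", "haldane")) {
  zero_policy <- match.arg(zero_policy)
  cells <- apply_zero_policy(a, b, c, d, zero_policy)
  ok <- (cells$a + cells$b) > 0 & cells$c > 0
  ifelse(ok,
         (cells$a / (cells$a + cells$b)) / (cells$c / (cells$c + cells$d)),
         NA_real_)
}

#' Pearson chi-squared statistic for a 2x2 table
#'
#' `N (ad - bc)^2 / [(a+b)(c+d)(a+c)(b+d)]` with `N = a+b+c+d`; with
#' `yates = TRUE` the Yates continuity correction
#' `N (|ad - bc| - N/2)^2 / [...]` is applied, the subtraction floored at 0.
#' Undefined (`NA`) when any margin is 0.
#'
#' @inheritParams compute_ror
#' @param yates Apply the continuity correction.
#' @return Numeric vector of chi-squared values.
#' @export
compute_chi_squared <- function(a, b, c, d, yates = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  ok <- denom > 0
  dev <- abs(a * d - b * c)
  if (yates) dev <- pmax(dev - n / 2, 0)
  ifelse(ok, n * dev^2 / denom, NA_real_)
}

#' Apply the composite signal criterion
#'
#' Criterion (a): the ROR's CI lower bound exceeds `ci_low_threshold`.
#' Criterion (b): PRR, chi-squared and the co-report count `n` each reach
#' their thresholds. A metric that is undefined (`NA`) makes its criterion
#' `FALSE`. The verdict is the conjunction.
#'
#' @param ci_low,prr,chi2 Metric vectors (may contain `NA`).
#' @param n Co-report counts (cell `a`).
#' @param config A [signal_config()].
#' @return Tibble with logical columns `criterion_a`, `criterion_b`,
#'   `signal`.
#' @export
evaluate_criteria <- function(ci_low, prr, chi2, n, config = signal_config()) {
  crit_a <- !is.na(ci_low) & ci_low > config$ci_low_threshold
  crit_b <- !is.na(prr) & !is.na(chi2) &
    prr >= config$prr_threshold &
    chi2 >= config$chi2_threshold &
    n >= config$n_min
  tibble::tibble(criterion_a = crit_a, criterion_b = crit_b,
                 signal = crit_a & crit_b)
}

#' Detect disproportionality signals for a set of target PTs
#'
#' For each PT query, every drug co-reported with the PT at least
#' `min_report_floor` times becomes a candidate; its 2x2 table is built
#' against the full pair universe, the three statistics are computed, and
#' the composite criterion is applied. The headline verdict always uses the
#' `"undefined"` zero-cell policy regardless of `config$zero_policy`, which
#' affects only the exploratory `ror`/`prr` values reported for
#' zero-cell tables.
#'
#' @param universe The full [pair_universe] (margins come from here).
#' @param queries PT query tibble; default [default_pt_set()].
#' @param config A [signal_config()].
#' @return A tibble with one row per candidate (drug, PT): columns
#'   `drug_name`, `pt_name`, `pt_code`, `a`, `b`, `c`, `d`, `ror`,
#'   `ci_low`, `ci_high`, `prr`, `chi2`, `n`, `criterion_a`, `criterion_b`,
#'   `signal`. Rows are ordered by query order, then descending `a`, then
#'   drug name.
#' @export
detect_signals <- function(universe, queries = default_pt_set(),
                           config = signal_config()) {
  queries <- as_pt_queries(queries)
  stopifnot(nrow(universe) > 0)
  n_univ <- n_total(universe)
  drug_pairs_total <- dplyr::count(tibble::as_tibble(universe),
                                   .data$drug_name, name = "n_drug")

  per_query <- lapply(seq_len(nrow(queries)), function(i) {
    q <- queries[i, ]
    m <- pair_matches(universe, q, config$match_on)
    n_pt <- sum(m)
    if (n_pt == 0) return(NULL)
    cand <- dplyr::count(tibble::as_tibble(universe[m, ]),
                         .data$drug_name, name = "a")
    cand <- cand[cand$a >= config$min_report_floor, , drop = FALSE]
    if (nrow(cand) == 0) return(NULL)
    cand <- dplyr::left_join(cand, drug_pairs_total, by = "drug_name")
    cand$b <- cand$n_drug - cand$a
    cand$c <- n_pt - cand$a
    cand$d <- n_univ - cand$a - cand$b - cand$c
    cand$pt_name <- q$pt_name
    cand$pt_code <- q$pt_code
    cand$n_drug <- NULL
    cand
  })
  cells <- dplyr::bind_rows(per_query)
  if (nrow(cells) == 0) {
    return(empty_signal_results())
  }

  ror_tbl <- compute_ror(cells$a, cells$b, cells$c, cells$d,
                         zero_policy = config$zero_policy)
  prr_vec <- compute_prr(cells$a, cells$b, cells$c, cells$d,
                         zero_policy = config$zero_policy)
  chi2_vec <- compute_chi_squared(cells$a, cells$b, cells$c, cells$d,
                                  yates = config$yates)
  # verdict path: strict zero-cell policy, whatever the exploratory one is
  ror_strict <- compute_ror(cells$a, cells$b, cells$c, cells$d,
                            zero_policy = "undefined")
  prr_strict <- compute_prr(cells$a, cells$b, cells$c, cells$d,
                            zero_policy = "undefined")
  verdict <- evaluate_criteria(ror_strict$ci_low, prr_strict, chi2_vec,
                               cells$a, config)

  out <- tibble::tibble(
    drug_name = cells$drug_name,
    pt_name = cells$pt_name,
    pt_code = cells$pt_code,
    a = cells$a, b = cells$b, c = cells$c, d = cells$d,
    ror = ror_tbl$ror, ci_low = ror_tbl$ci_low, ci_high = ror_tbl$ci_high,
    prr = prr_vec, chi2 = chi2_vec, n = cells$a,
    criterion_a = verdict$criterion_a,
    criterion_b = verdict$criterion_b,
    signal = verdict$signal
  )
  pt_order <- match(out$pt_name, queries$pt_name)
  out[order(pt_order, -out$a, out$drug_name), , drop = FALSE]
}

empty_signal_results <- function() {
  tibble::tibble(
    drug_name = character(), pt_name = character(), pt_code = character(),
    a = integer(), b = integer(), c = integer(), d = integer(),
    ror = numeric(), ci_low = numeric(), ci_high = numeric(),
    prr = numeric(), chi2 = numeric(), n = integer(),
    criterion_a = logical(), criterion_b = logical(), signal = logical()
  )
}
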