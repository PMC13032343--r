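# Seeded generator of JADER-format report tables with known statistical
# structure: background reporting, planted drug-event associations of
# specified odds ratio, duplicate report versions, role mixing, and a truth
# registry for recovery tests.
#
# Sampling model (per case, independently):
#   K ~ zero-truncated Poisson(lambda)      distinct-drug draw budget
#   K drugs drawn with replacement by popularity weight, then deduplicated,
#   so P(drug j in case) = 1 - E[(1-w_j)^K] is available in closed form and
#   planted-pair expectations are exact;
#   each distinct drug record gets an i.i.d. role from role_mix;
#   each PT occurs independently given the drug set: a non-planted PT with
#   its background rate, a planted PT with probability p1 when its partner
#   drug is present as a suspected drug and p0 otherwise (several planted
#   drugs on one PT combine as 1 - prod(1 - q));
#   every case additionally receives one guaranteed background event drawn
#   from the non-planted PTs (independently of the drug set), so a reaction
#   row exists for every case without tying the non-target event margin to
#   drug presence; planted-pair counts are untouched.

# Evaluate code under a given seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Default synthetic drug catalog
#'
#' `n_drugs` fictitious ingredients with Zipf popularity weights
#' (`weight ~ 1/rank^zipf_s`), so the 2x2 `b` and `d` cells span realistic
#' magnitudes, and therapeutic category codes cycling over a small label
#' set in which roughly one drug in ten is an antineoplastic ("42" prefix).
#'
#' @param n_drugs Number of drugs.
#' @param zipf_s Zipf exponent for the popularity weights.
#' @return Tibble with columns `drug_name`, `category_code`,
#'   `category_label`, `weight`.
#' @export
default_drug_catalog <- function(n_drugs = 30, zipf_s = 1) {
  categories <- tibble::tibble(
    category_code = c("119", "625", "249", "113", "421", "332", "235",
                      "614", "117", "396"),
    category_label = c("Other agents affecting central nervous system",
                       "Anti-virus agents",
                       "Other hormone preparations",
                       "Antiepileptics",
                       "Antineoplastics-alkylating agents",
                       "Hemostatics",
                       "Purgatives and clysters",
                       "Acting mainly on gram-positive bacteria",
                       "Psychotropic agents",
                       "Agents affecting metabolism, n.e.c.")
  )
  idx <- ((seq_len(n_drugs) - 1) %% nrow(categories)) + 1
  tibble::tibble(
    drug_name = sprintf("drug%03d", seq_len(n_drugs)),
    category_code = categories$category_code[idx],
    category_label = categories$category_label[idx],
    weight = 1 / seq_len(n_drugs)^zipf_s
  )
}

#' Default synthetic PT catalog
#'
#' The seven target appetite/taste PTs at low background reporting rates,
#' plus common filler PTs (nausea, rash, and the like) at higher rates so
#' the event margin is dominated by non-target reporting, as in a real
#' spontaneous-report database.
#'
#' @return Tibble with columns `pt_name`, `pt_code`, `background_rate`.
#' @export
default_pt_catalog <- function() {
  targets <- default_pt_set()
  targets$background_rate <- c(0.001, 0.010, 0.001, 0.002, 0.004,
                               0.001, 0.004)
  fillers <- tibble::tibble(
    pt_name = c("Nausea", "Rash", "Headache", "Pyrexia", "Diarrhoea",
                "Vomiting", "Dizziness", "Malaise"),
    pt_code = c("10028813", "10037844", "10019211", "10037660",
                "10012735", "10047700", "10013573", "10025482"),
    background_rate = c(0.06, 0.05, 0.04, 0.05, 0.05, 0.04, 0.03, 0.05)
  )
  dplyr::bind_rows(targets, fillers)
}

#' Configuration for the synthetic report generator
#'
#' @param n_cases Number of distinct cases.
#' @param drug_catalog Tibble with `drug_name`, `category_code`,
#'   `category_label`, `weight` (positive popularity weights).
#' @param pt_catalog Tibble with `pt_name`, `pt_code`,
#'   `background_rate` in (0, 1).
#' @param planted Optional tibble of true associations with columns
#'   `drug_name`, `pt_name`, `p1` (PT probability when the drug is present
#'   as suspected), `p0` (otherwise); the implied reporting odds ratio is
#'   `[p1/(1-p1)] / [p0/(1-p0)]`.
#' @param drugs_per_case_lambda Rate of the zero-truncated Poisson drug
#'   budget; the realized mean drugs per case is
#'   `lambda / (1 - exp(-lambda))`.
#' @param role_mix Named probabilities over
#'   suspected/concomitant/interacting, summing to 1.
#' @param duplicate_rate Fraction of cases re-emitted as an extra,
#'   content-identical report version (in `[0, 1)`).
#' @param seed Integer seed; identical configurations generate identical
#'   bytes.
#' @param dialect Output [table_dialect()] for [generate_dataset()].
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_cases,
                              drug_catalog = default_drug_catalog(),
                              pt_catalog = default_pt_catalog(),
                              planted = NULL,
                              drugs_per_case_lambda = 2,
                              role_mix = c(suspected = 0.7,
                                           concomitant = 0.25,
                                           interacting = 0.05),
                              duplicate_rate = 0,
                              seed = 1L,
                              dialect = dialect_ascii()) {
  fail <- function(field, why) {
    stop("invalid simulation config: `", field, "` ", why, call. = FALSE)
  }
  if (!is.numeric(n_cases) || length(n_cases) != 1 || n_cases < 1) {
    fail("n_cases", "must be a positive integer")
  }
  if (!all(c("drug_name", "weight") %in% names(drug_catalog)) ||
      any(drug_catalog$weight <= 0)) {
    fail("drug_catalog", "needs drug_name and positive weight columns")
  }
  if (anyDuplicated(drug_catalog$drug_name) > 0) {
    fail("drug_catalog", "has duplicate drug names")
  }
  if (!all(c("pt_name", "pt_code", "background_rate") %in% names(pt_catalog)) ||
      any(pt_catalog$background_rate <= 0 | pt_catalog$background_rate >= 1)) {
    fail("pt_catalog", "needs pt_name, pt_code and background_rate in (0,1)")
  }
  if (anyDuplicated(pt_catalog$pt_name) > 0) {
    fail("pt_catalog", "has duplicate PT names")
  }
  if (!is.null(planted) && nrow(planted) > 0) {
    if (!all(c("drug_name", "pt_name", "p1", "p0") %in% names(planted))) {
      fail("planted", "needs drug_name, pt_name, p1, p0 columns")
    }
    if (any(planted$p0 <= 0 | planted$p1 >= 1 | planted$p1 < planted$p0)) {
      fail("planted", "requires 0 < p0 <= p1 < 1")
    }
    if (!all(planted$drug_name %in% drug_catalog$drug_name)) {
      fail("planted", "names a drug absent from drug_catalog")
    }
    if (!all(planted$pt_name %in% pt_catalog$pt_name)) {
      fail("planted", "names a PT absent from pt_catalog")
    }
  } else {
    planted <- tibble::tibble(drug_name = character(), pt_name = character(),
                              p1 = numeric(), p0 = numeric())
  }
  if (!is.numeric(drugs_per_case_lambda) || drugs_per_case_lambda <= 0) {
    fail("drugs_per_case_lambda", "must be positive")
  }
  if (length(role_mix) != 3 ||
      !setequal(names(role_mix), drug_roles()) ||
      any(role_mix < 0) || abs(sum(role_mix) - 1) > 1e-8) {
    fail("role_mix", "must be probabilities over suspected/concomitant/interacting summing to 1")
  }
  if (duplicate_rate < 0 || duplicate_rate >= 1) {
    fail("duplicate_rate", "must be in [0, 1)")
  }
  structure(
    list(n_cases = as.integer(n_cases),
         drug_catalog = tibble::as_tibble(drug_catalog),
         pt_catalog = tibble::as_tibble(pt_catalog),
         planted = tibble::as_tibble(planted),
         drugs_per_case_lambda = drugs_per_case_lambda,
         role_mix = role_mix[drug_roles()],
         duplicate_rate = duplicate_rate,
         seed = as.integer(seed),
         dialect = dialect),
    class = "simulation_config"
  )
}

# P(a given drug appears among a case's distinct drugs), exactly:
# with K ~ zero-truncated Poisson(lambda) and normalized weight w,
# E[(1-w)^K] = (exp(lambda*(1-w)) - 1) / (exp(lambda) - 1).
prob_drug_present <- function(config, drug_name) {
  w <- config$drug_catalog$weight / sum(config$drug_catalog$weight)
  w <- w[match(drug_name, config$drug_catalog$drug_name)]
  lam <- config$drugs_per_case_lambda
  1 - (exp(lam * (1 - w)) - 1) / (exp(lam) - 1)
}

#' Closed-form truth for the planted associations
#'
#' A pure function of the configuration (no sampling): for each planted
#' pair, the implied reporting odds ratio and the expected co-report count
#' `a` (cases carrying the drug as suspected times `p1`).
#'
#' @param config A [simulation_config()].
#' @return Tibble with columns `drug_name`, `pt_name`, `p1`, `p0`,
#'   `implied_or`, `p_present`, `expected_a`; attributes `n_cases` and
#'   `expected_suspected_records` (expected suspected drug rows per
#'   dataset).
#' @export
planted_truth <- function(config) {
  pl <- config$planted
  p_present <- prob_drug_present(config, pl$drug_name)
  out <- tibble::tibble(
    drug_name = pl$drug_name,
    pt_name = pl$pt_name,
    p1 = pl$p1,
    p0 = pl$p0,
    implied_or = (pl$p1 / (1 - pl$p1)) / (pl$p0 / (1 - pl$p0)),
    p_present = p_present,
    expected_a = config$n_cases * p_present *
      config$role_mix[["suspected"]] * pl$p1
  )
  attr(out, "n_cases") <- config$n_cases
  attr(out, "expected_suspected_records") <-
    config$n_cases * config$role_mix[["suspected"]] *
    sum(prob_drug_present(config, config$drug_catalog$drug_name))
  out
}

# Expected a-cell for ANY (drug, pt) pair: planted pairs use p1, everything
# else the PT's background rate. Used to pick eligible null pairs for
# false-positive-rate estimation.
expected_pair_count <- function(config, drug_name, pt_name) {
  p_present <- prob_drug_present(config, drug_name)
  pl <- config$planted
  key <- paste(drug_name, pt_name, sep = "\r")
  plkey <- paste(pl$drug_name, pl$pt_name, sep = "\r")
  rate <- config$pt_catalog$background_rate[
    match(pt_name, config$pt_catalog$pt_name)]
  hit <- match(key, plkey)
  rate[!is.na(hit)] <- pl$p1[hit[!is.na(hit)]]
  config$n_cases * p_present * config$role_mix[["suspected"]] * rate
}

# zero-truncated Poisson sampler via the inverse-CDF restricted to k >= 1
rztpois <- function(n, lambda) {
  p0 <- stats::ppois(0, lambda)
  stats::qpois(p0 + stats::runif(n) * (1 - p0), lambda)
}

#' Simulate one dataset in memory
#'
#' Draws the case-level structure described in the package's sampling model
#' and returns canonical drug and reaction record tibbles (including any
#' injected duplicate report versions) together with the realized truth
#' registry. Deterministic given the configuration.
#'
#' @param config A [simulation_config()].
#' @return List with elements `drug` (drug records), `reac` (reaction
#'   records), `truth` (see Details), and `config`.
#' @details `truth` is a list with `n_cases`, `n_duplicate_cases`,
#'   `role_counts` (retained-version drug rows per role),
#'   `n_suspected_records`, `n_pairs` (unique case/suspected-drug/PT
#'   triples), `pt_pair_counts` (named, per PT), and `planted` (the
#'   [planted_truth()] table plus the realized `a` per planted pair).
#' @export
simulate_reports <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    n <- config$n_cases
    cat_d <- config$drug_catalog
    cat_p <- config$pt_catalog
    w <- cat_d$weight / sum(cat_d$weight)
    case_ids <- sprintf("case%06d", seq_len(n))

    # distinct drugs per case
    k <- rztpois(n, config$drugs_per_case_lambda)
    draw_case <- rep.int(seq_len(n), k)
    draw_drug <- sample.int(nrow(cat_d), sum(k), replace = TRUE, prob = w)
    keep <- !duplicated(paste(draw_case, draw_drug, sep = "\r"))
    rec_case <- draw_case[keep]
    rec_drug <- draw_drug[keep]
    rec_role <- sample(drug_roles(), length(rec_case), replace = TRUE,
                       prob = config$role_mix)

    # per-case suspected indicator matrix entries for planted drugs
    suspected <- rec_role == "suspected"

    # PT occurrence probabilities per (case, pt)
    pl <- config$planted
    occ <- matrix(FALSE, nrow = n, ncol = nrow(cat_p))
    for (j in seq_len(nrow(cat_p))) {
      pt <- cat_p$pt_name[j]
      pj <- pl[pl$pt_name == pt, , drop = FALSE]
      if (nrow(pj) == 0) {
        p <- rep(cat_p$background_rate[j], n)
      } else {
        # combine planted opportunities: 1 - prod(1 - q)
        q_not <- rep(1, n)
        for (r in seq_len(nrow(pj))) {
          di <- match(pj$drug_name[r], cat_d$drug_name)
          present <- rep(FALSE, n)
          present[rec_case[rec_drug == di & suspected]] <- TRUE
          q <- ifelse(present, pj$p1[r], pj$p0[r])
          q_not <- q_not * (1 - q)
        }
        p <- 1 - q_not
      }
      occ[, j] <- stats::runif(n) < p
    }

    # every case reports >= 1 event: one guaranteed background event per
    # case, drawn from the non-planted PTs by background weight and
    # independently of the drug set — a conditional fallback would couple
    # the non-target event margin to drug presence and bias the pair-level
    # odds ratio
    pool <- which(!(cat_p$pt_name %in% pl$pt_name))
    if (length(pool) == 0) pool <- seq_len(nrow(cat_p))
    guaranteed <- pool[1 + findInterval(
      stats::runif(n),
      cumsum(cat_p$background_rate[pool]) / sum(cat_p$background_rate[pool])
    )]
    occ[cbind(seq_len(n), guaranteed)] <- TRUE

    ev <- which(occ, arr.ind = TRUE)
    ev <- ev[order(ev[, 1], ev[, 2]), , drop = FALSE]

    drug_base <- tibble::tibble(
      case_id = case_ids[rec_case],
      version = 1L,
      drug_seq = stats::ave(rep(1L, length(rec_case)), rec_case,
                            FUN = seq_along),
      role = rec_role,
      drug_name = cat_d$drug_name[rec_drug]
    )
    drug_base <- drug_base[order(match(drug_base$case_id, case_ids),
                                 drug_base$drug_seq), , drop = FALSE]
    reac_base <- tibble::tibble(
      case_id = case_ids[ev[, 1]],
      version = 1L,
      pt_name = cat_p$pt_name[ev[, 2]],
      pt_code = cat_p$pt_code[ev[, 2]]
    )

    # duplicate report versions: identical content, version incremented
    m <- floor(config$duplicate_rate * n)
    dup_cases <- if (m > 0) sample(case_ids, m) else character()
    add_dup <- function(tbl) {
      extra <- tbl[tbl$case_id %in% dup_cases, , drop = FALSE]
      extra$version <- 2L
      out <- dplyr::bind_rows(tbl, extra)
      out[order(match(out$case_id, case_ids), out$version), , drop = FALSE]
    }
    drug_tbl <- add_dup(drug_base)
    reac_tbl <- add_dup(reac_base)

    # realized truth registry, computed from the case-level state (an
    # independent path from the reader/dedup/join machinery)
    n_susp_per_case <- tabulate(rec_case[suspected], nbins = n)
    events_per_case <- rowSums(occ)
    pt_pair_counts <- colSums(occ * n_susp_per_case)
    names(pt_pair_counts) <- cat_p$pt_name

    planted_tab <- planted_truth(config)
    if (nrow(planted_tab) > 0) {
      planted_tab$realized_a <- vapply(seq_len(nrow(planted_tab)), function(r) {
        di <- match(planted_tab$drug_name[r], cat_d$drug_name)
        j <- match(planted_tab$pt_name[r], cat_p$pt_name)
        present <- rep(FALSE, n)
        present[rec_case[rec_drug == di & suspected]] <- TRUE
        sum(present & occ[, j])
      }, numeric(1))
    }

    truth <- list(
      n_cases = n,
      n_duplicate_cases = m,
      duplicate_case_ids = sort(dup_cases),
      role_counts = c(
        suspected = sum(rec_role == "suspected"),
        concomitant = sum(rec_role == "concomitant"),
        interacting = sum(rec_role == "interacting")
      ),
      n_suspected_records = sum(suspected),
      n_pairs = sum(n_susp_per_case * events_per_case),
      pt_pair_counts = pt_pair_counts,
      planted = planted_tab
    )
    list(drug = drug_tbl, reac = reac_tbl, truth = truth, config = config)
  })
}

#' Generate a dataset on disk
#'
#' Runs [simulate_reports()] and writes the drug table, reaction table and
#' truth registry under the configuration's dialect. Identical
#' configurations produce byte-identical files.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @return Named list of paths: `drug`, `reac`, `truth`.
#' @export
generate_dataset <- function(config, out_dir) {
  sim <- simulate_reports(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- list(drug = file.path(out_dir, "drug.csv"),
                reac = file.path(out_dir, "reac.csv"),
                truth = file.path(out_dir, "truth.json"))
  write_report_table(sim$drug, paths$drug, "drug", config$dialect)
  write_report_table(sim$reac, paths$reac, "reac", config$dialect)
  truth <- sim$truth
  truth$planted <- as.data.frame(truth$planted)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths
}

#' Monte-Carlo operating characteristics of the composite criterion
#'
#' Repeatedly simulates datasets under `config`, runs the full
#' dedup/filter/link/detect pipeline on each, and estimates (i) the
#' sensitivity of the criterion on the planted pairs, (ii) the false
#' positive rate among null candidate pairs whose expected co-report count
#' is at least `null_floor`, and (iii) the coverage of the 95% ROR
#' confidence interval against the implied odds ratio. Rates come with
#' binomial Monte-Carlo standard errors.
#'
#' @param config A [simulation_config()].
#' @param n_reps Number of replicate datasets (>= 2; >= 50 for stable
#'   rates).
#' @param seed Master seed; replicate `r` is simulated under a seed derived
#'   from it.
#' @param criteria A [signal_config()].
#' @param null_floor Minimum expected `a` for a null pair to count toward
#'   the false positive rate (default 3, matching the criterion's report
#'   floor).
#' @return List with `sensitivity`, `sensitivity_se`, `fpr`, `fpr_se`,
#'   `ci_coverage`, `ci_coverage_se`, `n_reps`, `n_null_pairs`,
#'   `log_ror` (per planted pair per rep, for bias checks), and
#'   `per_planted` (flag/coverage tallies per planted pair). Sensitivity
#'   and coverage are `NA` when nothing is planted.
#' @export
estimate_operating_characteristics <- function(config, n_reps = 100,
                                               seed = 1L,
                                               criteria = signal_config(),
                                               null_floor = 3) {
  stopifnot(n_reps >= 2)
  queries <- as_pt_queries(config$pt_catalog[, c("pt_name", "pt_code")])
  pl <- planted_truth(config)

  # null candidate pairs worth watching: expected a >= null_floor, not planted
  grid <- expand.grid(drug_name = config$drug_catalog$drug_name,
                      pt_name = config$pt_catalog$pt_name,
                      stringsAsFactors = FALSE)
  grid$expected_a <- expected_pair_count(config, grid$drug_name, grid$pt_name)
  plkey <- paste(pl$drug_name, pl$pt_name, sep = "\r")
  grid$key <- paste(grid$drug_name, grid$pt_name, sep = "\r")
  null_pairs <- grid[grid$expected_a >= null_floor & !(grid$key %in% plkey), ,
                     drop = FALSE]

  n_flag <- numeric(nrow(pl))
  n_cover <- numeric(nrow(pl))
  log_ror <- matrix(NA_real_, nrow = n_reps, ncol = nrow(pl))
  null_flagged <- 0L

  for (r in seq_len(n_reps)) {
    cfg_r <- config
    cfg_r$seed <- as.integer((as.numeric(seed) + r * 10007) %% 2147483647)
    sim <- simulate_reports(cfg_r)
    drugs <- filter_suspected(deduplicate_cases(sim$drug))
    events <- deduplicate_cases(sim$reac)
    universe <- link_drug_event(drugs, events)
    res <- detect_signals(universe, queries, criteria)
    res_key <- paste(res$drug_name, res$pt_name, sep = "\r")

    if (nrow(pl) > 0) {
      hit <- match(plkey, res_key)
      flagged <- !is.na(hit) & res$signal[hit]
      n_flag <- n_flag + flagged
      covered <- !is.na(hit) & !is.na(res$ci_low[hit]) &
        res$ci_low[hit] <= pl$implied_or & res$ci_high[hit] >= pl$implied_or
      n_cover <- n_cover + covered
      log_ror[r, ] <- log(res$ror[hit])
    }
    if (nrow(null_pairs) > 0) {
      nh <- match(null_pairs$key, res_key)
      null_flagged <- null_flagged + sum(!is.na(nh) & res$signal[nh])
    }
  }

  binom_se <- function(p, n) sqrt(pmax(p * (1 - p), 0) / n)
  sens <- if (nrow(pl) > 0) mean(n_flag / n_reps) else NA_real_
  cover <- if (nrow(pl) > 0) mean(n_cover / n_reps) else NA_real_
  n_null_trials <- n_reps * nrow(null_pairs)
  fpr <- if (n_null_trials > 0) null_flagged / n_null_trials else NA_real_

  list(
    sensitivity = sens,
    sensitivity_se = if (is.na(sens)) NA_real_ else binom_se(sens, n_reps * max(nrow(pl), 1)),
    fpr = fpr,
    fpr_se = if (is.na(fpr)) NA_real_ else binom_se(fpr, n_null_trials),
    ci_coverage = cover,
    ci_coverage_se = if (is.na(cover)) NA_real_ else binom_se(cover, n_reps * max(nrow(pl), 1)),
    n_reps = n_reps,
    n_null_pairs = nrow(null_pairs),
    log_ror = log_ror,
    per_planted = if (nrow(pl) > 0) {
      tibble::tibble(drug_name = pl$drug_name, pt_name = pl$pt_name,
                     implied_or = pl$implied_or,
                     n_flagged = n_flag, n_covered = n_cover)
    } else NULL
  )
}
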