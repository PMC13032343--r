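# Preferred Term (PT) query sets and restriction of the pair universe to
# the adverse events under study.

#' The default appetite- and taste-related PT query set
#'
#' Seven MedDRA Preferred Terms covering drug-induced appetite loss, weight
#' loss, and taste disturbance, with their 8-digit PT codes. This deliberately
#' narrow set prioritizes signal specificity: broader hierarchy terms (and
#' terms reflecting psychiatric or metabolic pathology such as anorexia
#' nervosa) are excluded.
#'
#' @return A tibble of PT queries with columns `pt_name`, `pt_code`.
#' @export
default_pt_set <- function() {
  as_pt_queries(tibble::tibble(
    pt_name = c("Appetite disorder", "Decreased appetite",
                "Abnormal loss of weight", "Ageusia", "Dysgeusia",
                "Hypogeusia", "Taste disorder"),
    pt_code = c("10060961", "10061428", "10000159", "10001480",
                "10013911", "10020989", "10082490")
  ))
}

#' PTs of the default set that describe appetite or weight loss
#' @return Character vector of PT names.
#' @export
appetite_pt_names <- function() {
  c("Appetite disorder", "Decreased appetite", "Abnormal loss of weight")
}

#' PTs of the default set that describe taste disturbance
#' @return Character vector of PT names.
#' @export
taste_pt_names <- function() {
  c("Ageusia", "Dysgeusia", "Hypogeusia", "Taste disorder")
}

#' Validate a PT query table
#'
#' @param queries Data frame with columns `pt_name` and `pt_code`.
#' @return The validated tibble.
#' @export
as_pt_queries <- function(queries) {
  queries <- tibble::as_tibble(queries)
  stopifnot(all(c("pt_name", "pt_code") %in% names(queries)))
  queries$pt_code <- as.character(queries$pt_code)
  bad <- !grepl("^[0-9]{8}$", queries$pt_code)
  if (any(bad)) {
    stop("PT codes must be 8-digit strings; offending: ",
         paste(unique(queries$pt_code[bad]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(queries[, c("pt_name", "pt_code")]) > 0) {
    stop("duplicate (pt_name, pt_code) entries in query set", call. = FALSE)
  }
  queries
}

#' Read a PT query set from a two-column CSV
#'
#' @param path CSV with columns `pt_name`, `pt_code`.
#' @return A validated PT query tibble.
#' @export
read_pt_queries <- function(path) {
  as_pt_queries(readr::read_csv(
    path, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  ))
}

# Logical vector: which pairs of the universe match one query.
# match_on = "code": compare PT codes where the pair carries one, fall back
# to the PT name where it does not (real JADER reaction rows carry names
# only); "name": names only; "either": a code or name match suffices.
pair_matches <- function(universe, query, match_on = c("code", "name", "either")) {
  match_on <- match.arg(match_on)
  by_code <- !is.na(universe$pt_code) & universe$pt_code == query$pt_code
  by_name <- universe$pt_name == query$pt_name
  switch(match_on,
    code = ifelse(is.na(universe$pt_code), by_name, by_code),
    name = by_name,
    either = by_code | by_name
  )
}

#' Restrict the pair universe to target adverse events
#'
#' Keeps the pairs whose PT matches at least one query. The full universe is
#' still needed afterwards for the 2x2 margins, so keep it; this function
#' returns only the subset.
#'
#' @param universe A [pair_universe].
#' @param queries PT query tibble (see [as_pt_queries()]); must be non-empty.
#' @param match_on `"code"` (default; falls back to the name for pairs
#'   without a code), `"name"`, or `"either"`.
#' @return The matching subset, as a [pair_universe]. Idempotent.
#' @export
extract_target_pairs <- function(universe, queries,
                                 match_on = c("code", "name", "either")) {
  match_on <- match.arg(match_on)
  queries <- as_pt_queries(queries)
  if (nrow(queries) == 0) {
    stop("PT query set is empty", call. = FALSE)
  }
  hit <- rep(FALSE, nrow(universe))
  for (i in seq_len(nrow(queries))) {
    hit <- hit | pair_matches(universe, queries[i, ], match_on)
  }
  new_pair_universe(universe[hit, , drop = FALSE])
}

#' Per-PT report and drug counts
#'
#' For each query, the number of matching pairs (reports, since a pair is
#' counted once per case) and the number of distinct drugs among them.
#' Output rows follow the query order.
#'
#' @inheritParams extract_target_pairs
#' @return Tibble with columns `pt_name`, `pt_code`, `n_reports`, `n_drugs`.
#' @export
summarize_pt_counts <- function(universe, queries,
                                match_on = c("code", "name", "either")) {
  match_on <- match.arg(match_on)
  queries <- as_pt_queries(queries)
  rows <- lapply(seq_len(nrow(queries)), function(i) {
    m <- pair_matches(universe, queries[i, ], match_on)
    tibble::tibble(
      pt_name = queries$pt_name[i],
      pt_code = queries$pt_code[i],
      n_reports = sum(m),
      n_drugs = dplyr::n_distinct(universe$drug_name[m])
    )
  })
  dplyr::bind_rows(rows)
}
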