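# Therapeutic-category classification of signal-detected drugs, the
# antineoplastic ("42"-prefix) exclusion, per-category summaries, multi-PT
# overlap, and package-insert annotation cross-tabulation.

#' Read a drug-to-therapeutic-category map
#'
#' The Japanese commodity classification assigns each drug a digit-string
#' therapeutic category code at 3-digit granularity (codes beginning "42"
#' are antineoplastic agents). The official list is user-supplied.
#'
#' @param path CSV with columns `drug_name`, `category_code`,
#'   `category_label`. Drug names are normalized on read.
#' @return Tibble with those three columns.
#' @export
read_category_map <- function(path) {
  m <- readr::read_csv(path,
                       col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE, show_col_types = FALSE)
  stopifnot(all(c("drug_name", "category_code", "category_label") %in% names(m)))
  m$drug_name <- normalize_drug_name(m$drug_name)
  bad <- !grepl("^[0-9]+$", m$category_code)
  if (any(bad)) {
    stop("category_code must be digits only; offending: ",
         paste(unique(m$category_code[bad]), collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(m)
}

#' Exclude antineoplastic agents from a signal list
#'
#' Signals on drugs whose therapeutic category code begins with the given
#' prefix (default `"42"`, antineoplastic agents) are set aside so that
#' adverse reactions attributable to the underlying cancer do not masquerade
#' as drug effects. Drugs absent from the category map are routed to an
#' `unresolved` review list, never dropped silently; the three outputs
#' partition the input exactly.
#'
#' @param signals Tibble with a `drug_name` column (typically the
#'   `signal == TRUE` rows of [detect_signals()] output).
#' @param category_map Tibble from [read_category_map()].
#' @param prefix Category-code prefix to exclude.
#' @return List with tibbles `kept`, `excluded`, `unresolved`, each the
#'   corresponding rows of `signals` augmented with `category_code` and
#'   `category_label` (`NA` for unresolved).
#' @export
exclude_antineoplastics <- function(signals, category_map, prefix = "42") {
  joined <- dplyr::left_join(
    signals, category_map[, c("drug_name", "category_code", "category_label")],
    by = "drug_name"
  )
  unresolved <- joined[is.na(joined$category_code), , drop = FALSE]
  resolved <- joined[!is.na(joined$category_code), , drop = FALSE]
  is_excl <- startsWith(resolved$category_code, prefix)
  list(
    kept = resolved[!is_excl, , drop = FALSE],
    excluded = resolved[is_excl, , drop = FALSE],
    unresolved = unresolved
  )
}

#' Summarize signal drugs by therapeutic category for one PT
#'
#' One row per category present among the signals for the PT, with the drug
#' count, the drug names, and the total co-report count (the sum of the `a`
#' cells). Rows are ordered by descending drug count, then descending total
#' reports, then label.
#'
#' @param signals Signal rows for one PT, post-exclusion, each with
#'   `drug_name`, `a`, and (if not yet joined) resolvable in `category_map`.
#' @param category_map Tibble from [read_category_map()]; ignored when
#'   `signals` already carries `category_label`.
#' @param pt Optional PT name; when given, `signals` is filtered to it.
#' @return Tibble with columns `category_label`, `n_drugs`, `drug_names`
#'   (collapsed, "; "-separated), `total_reports`.
#' @export
summarize_by_category <- function(signals, category_map = NULL, pt = NULL) {
  if (!is.null(pt)) signals <- signals[signals$pt_name == pt, , drop = FALSE]
  if (!"category_label" %in% names(signals)) {
    signals <- dplyr::left_join(
      signals,
      category_map[, c("drug_name", "category_code", "category_label")],
      by = "drug_name"
    )
  }
  out <- signals |>
    dplyr::group_by(.data$category_label) |>
    dplyr::summarise(
      n_drugs = dplyr::n_distinct(.data$drug_name),
      drug_names = paste(sort(unique(.data$drug_name)), collapse = "; "),
      total_reports = sum(.data$a),
      .groups = "drop"
    )
  out[order(-out$n_drugs, -out$total_reports, out$category_label), ,
      drop = FALSE]
}

#' Drugs with signals across multiple PTs
#'
#' Pools signal rows across PTs and returns the drugs flagged for two or
#' more distinct PTs, with their PT sets. The result does not depend on the
#' order PTs were processed in.
#'
#' @param all_signals Signal rows (`signal == TRUE`) pooled across PTs, with
#'   `drug_name` and `pt_name`.
#' @return Tibble with columns `drug_name`, `n_pts`, `pt_names` (list
#'   column of sorted PT names), ordered by descending `n_pts` then drug
#'   name.
#' @export
find_multi_pt_drugs <- function(all_signals) {
  out <- all_signals |>
    dplyr::distinct(.data$drug_name, .data$pt_name) |>
    dplyr::group_by(.data$drug_name) |>
    dplyr::summarise(n_pts = dplyr::n(),
                     pt_names = list(sort(.data$pt_name)),
                     .groups = "drop")
  out <- out[out$n_pts >= 2, , drop = FALSE]
  out[order(-out$n_pts, out$drug_name), , drop = FALSE]
}

#' Read a package-insert annotation table
#'
#' Records, per drug, whether decreased appetite and whether taste-related
#' adverse reactions are described in the official package insert. Only
#' explicitly reviewed drugs appear; anything else is reported as
#' un-reviewed downstream, never silently defaulted.
#'
#' @param path CSV with columns `drug_name`, `appetite_listed`,
#'   `taste_listed` (true/false).
#' @return Tibble with normalized `drug_name` and two logical columns.
#' @export
read_insert_annotations <- function(path) {
  ann <- readr::read_csv(path,
                         col_types = readr::cols(
                           drug_name = readr::col_character(),
                           appetite_listed = readr::col_logical(),
                           taste_listed = readr::col_logical()
                         ),
                         progress = FALSE, show_col_types = FALSE)
  ann$drug_name <- normalize_drug_name(ann$drug_name)
  tibble::as_tibble(ann)
}

#' Cross-tabulate signal drugs against package-insert annotation
#'
#' For the distinct drugs among the given signals, counts how many have the
#' relevant reaction family (appetite or taste) described in their package
#' insert, how many do not, and which drugs were not reviewed at all.
#' `n_listed + n_unlisted + length(unreviewed)` equals the number of
#' distinct signal drugs.
#'
#' @param signals Signal rows for PTs of one family.
#' @param annotation Tibble from [read_insert_annotations()].
#' @param pt_family `"appetite"` (uses `appetite_listed`) or `"taste"`
#'   (uses `taste_listed`).
#' @return List with `n_listed`, `n_unlisted`, `unreviewed` (character
#'   vector of drug names), `pt_family`.
#' @export
annotate_insert_status <- function(signals, annotation,
                                   pt_family = c("appetite", "taste")) {
  pt_family <- match.arg(pt_family)
  flag_col <- if (pt_family == "appetite") "appetite_listed" else "taste_listed"
  drugs <- sort(unique(signals$drug_name))
  idx <- match(drugs, annotation$drug_name)
  flag <- annotation[[flag_col]][idx]
  reviewed <- !is.na(idx) & !is.na(flag)
  list(
    n_listed = sum(flag[reviewed]),
    n_unlisted = sum(!flag[reviewed]),
    unreviewed = drugs[!reviewed],
    pt_family = pt_family
  )
}
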