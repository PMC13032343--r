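# Ingestion of JADER-style table dumps: decode, map columns through the
# dialect, deduplicate report versions, filter to suspected drugs, and link
# the drug and reaction tables into the drug-event pair universe.

# Decode a file's bytes trying each dialect encoding in order; errors carry
# the list of encodings tried so the user can extend the dialect.
read_dialect_text <- function(path, encodings) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) == 0) return("")
  try_enc <- function(enc) {
    tryCatch(iconv(list(raw), from = enc, to = "UTF-8"),
             error = function(e) NA_character_)
  }
  # a non-ASCII file that is valid UTF-8 is UTF-8: legacy double-byte
  # encodings would happily mis-decode it, so check UTF-8 validity first
  # when the dialect allows it
  if ("UTF-8" %in% encodings && any(raw > 0x7f)) {
    txt <- try_enc("UTF-8")
    if (!is.na(txt)) return(txt)
  }
  for (enc in encodings) {
    txt <- tryCatch(iconv(list(raw), from = enc, to = "UTF-8"),
                    error = function(e) NA_character_)
    if (!is.na(txt)) return(txt)
  }
  stop("could not decode '", path, "' with any of: ",
       paste(encodings, collapse = ", "),
       ". Add the file's encoding to the dialect's `encodings`.",
       call. = FALSE)
}

# Canonical drug-name normalization: NFKC compatibility fold (unifies
# full-width/half-width forms common in Japanese dumps), trim, collapse
# internal whitespace, lower-case.
#' Normalize an ingredient name for exact-match drug identity
#'
#' Applies an NFKC compatibility fold, trims and collapses whitespace, and
#' lower-cases, so that full-width/half-width and case variants of the same
#' ingredient string compare equal. Brand versus generic products that share
#' a normalized ingredient string aggregate to one drug entity.
#'
#' @param x Character vector of raw drug-name strings.
#' @return Character vector of normalized names.
#' @export
normalize_drug_name <- function(x) {
  x <- stringi::stri_trans_nfkc(x)
  x <- stringi::stri_replace_all_regex(x, "\\s+", " ")
  x <- stringi::stri_trim_both(x)
  stringi::stri_trans_tolower(x)
}

#' Read a drug or reaction table from a JADER-style CSV dump
#'
#' Decodes the file with the dialect's encodings, maps physical columns to
#' the logical schema, translates the role vocabulary, normalizes drug
#' names, and validates PT codes. Row order is preserved.
#'
#' @param path Path to the CSV file.
#' @param table_kind `"drug"` or `"reac"`.
#' @param dialect A [table_dialect()]; default is the Japanese JADER layout.
#' @param synonyms Optional named character vector mapping normalized drug
#'   names to a preferred synonym (applied after normalization; drug tables
#'   only).
#'
#' @return A tibble. For `table_kind = "drug"`: columns `case_id`,
#'   `version`, `drug_seq`, `role`, `drug_name`. For `"reac"`: `case_id`,
#'   `version`, `pt_name`, `pt_code` (`NA` when the dialect maps no code
#'   column).
#'
#' @details Errors are specific: a mapped column absent from the file is a
#'   schema error naming the column; a role string outside the dialect's
#'   vocabulary is a validation error listing the value and row numbers; an
#'   undecodable file is an encoding error listing the encodings tried.
#' @export
read_report_table <- function(path, table_kind = c("drug", "reac"),
                              dialect = dialect_jader(), synonyms = NULL) {
  table_kind <- match.arg(table_kind)
  txt <- read_dialect_text(path, dialect$encodings)
  raw_tbl <- readr::read_csv(
    I(txt),
    col_types = readr::cols(.default = readr::col_character()),
    na = dialect$na, progress = FALSE, show_col_types = FALSE
  )

  colmap <- if (table_kind == "drug") dialect$drug_cols else dialect$reac_cols
  missing_cols <- setdiff(unname(colmap), names(raw_tbl))
  # pt_code is the one optional mapping
  missing_cols <- setdiff(missing_cols, colmap[names(colmap) == "pt_code"])
  if (length(missing_cols) > 0) {
    stop("schema error in '", path, "': mapped column(s) not found: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  get_col <- function(field) raw_tbl[[colmap[[field]]]]
  version <- parse_version(get_col("version"), path)

  if (table_kind == "drug") {
    role_raw <- get_col("role")
    role <- unname(dialect$role_vocabulary[role_raw])
    bad <- which(is.na(role) & !is.na(role_raw))
    if (length(bad) > 0) {
      vals <- unique(role_raw[bad])
      stop("validation error in '", path, "': unmappable role value(s) ",
           paste0("'", vals, "'", collapse = ", "),
           " at row(s) ", paste(utils::head(bad, 10), collapse = ", "),
           call. = FALSE)
    }
    drug_name <- normalize_drug_name(get_col("drug_name"))
    if (!is.null(synonyms)) {
      hit <- !is.na(match(drug_name, names(synonyms)))
      drug_name[hit] <- unname(synonyms[drug_name[hit]])
    }
    out <- tibble::tibble(
      case_id = get_col("case_id"),
      version = version,
      drug_seq = suppressWarnings(as.integer(get_col("drug_seq"))),
      role = role,
      drug_name = drug_name
    )
  } else {
    pt_code_col <- colmap[names(colmap) == "pt_code"]
    pt_code <- if (length(pt_code_col) == 1 && pt_code_col %in% names(raw_tbl)) {
      raw_tbl[[pt_code_col]]
    } else {
      rep(NA_character_, nrow(raw_tbl))
    }
    bad_code <- which(!is.na(pt_code) & !grepl("^[0-9]{8}$", pt_code))
    if (length(bad_code) > 0) {
      stop("validation error in '", path, "': PT code(s) not 8-digit: ",
           paste0("'", unique(pt_code[bad_code]), "'", collapse = ", "),
           " at row(s) ", paste(utils::head(bad_code, 10), collapse = ", "),
           call. = FALSE)
    }
    out <- tibble::tibble(
      case_id = get_col("case_id"),
      version = version,
      pt_name = stringi::stri_trim_both(get_col("pt_name")),
      pt_code = pt_code
    )
  }
  out
}

parse_version <- function(x, path) {
  v <- suppressWarnings(as.integer(x))
  bad <- which(is.na(v) & !is.na(x))
  if (length(bad) > 0) {
    stop("validation error in '", path, "': non-integer report version ",
         paste0("'", unique(x[bad]), "'", collapse = ", "),
         " at row(s) ", paste(utils::head(bad, 10), collapse = ", "),
         call. = FALSE)
  }
  v
}

#' Write records back out under a dialect
#'
#' Inverse of [read_report_table()]: logical fields are renamed to the
#' dialect's physical columns, canonical roles are translated back through
#' the role vocabulary, and the file is written in the dialect's primary
#' encoding. Reading the result under the same dialect reproduces all mapped
#' fields.
#'
#' @param records Tibble as returned by [read_report_table()].
#' @param path Output path.
#' @param table_kind `"drug"` or `"reac"`.
#' @param dialect A [table_dialect()].
#' @return `path`, invisibly.
#' @export
write_report_table <- function(records, path, table_kind = c("drug", "reac"),
                               dialect = dialect_jader()) {
  table_kind <- match.arg(table_kind)
  colmap <- if (table_kind == "drug") dialect$drug_cols else dialect$reac_cols
  out <- records
  if (table_kind == "drug") {
    inverse <- names(dialect$role_vocabulary)[
      match(out$role, unname(dialect$role_vocabulary))]
    out$role <- inverse
  }
  keep <- intersect(names(colmap), names(out))
  out <- out[unname(keep)]
  names(out) <- unname(colmap[keep])
  write_encoded_csv(out, path, dialect$encodings[[1]])
  invisible(path)
}

# readr cannot write non-UTF-8; format in memory and transcode the bytes.
write_encoded_csv <- function(tbl, path, encoding) {
  txt <- readr::format_csv(tbl, na = "")
  bytes <- iconv(txt, from = "UTF-8", to = encoding, toRaw = TRUE)[[1]]
  writeBin(bytes, path)
  invisible(path)
}

#' Keep one report version per case
#'
#' Spontaneous-report dumps carry the same case under several report
#' iterations (for example with amended onset dates); later versions
#' supersede earlier ones. All rows belonging to the retained version are
#' kept, in file order.
#'
#' @param records Tibble with `case_id` and `version` columns (drug or
#'   reaction records).
#' @param strategy `"latest_version"` (default) keeps each case's maximum
#'   version, ties resolved in favour of the later file position;
#'   `"first_seen"` keeps the version of the case's first row in file order.
#' @return Tibble of the retained rows; idempotent.
#' @export
deduplicate_cases <- function(records,
                              strategy = c("latest_version", "first_seen")) {
  strategy <- match.arg(strategy)
  if (nrow(records) == 0) return(records)
  ord <- seq_len(nrow(records))
  chosen <- if (strategy == "latest_version") {
    # max version per case; all rows carrying that version are one report
    # and are all retained
    stats::ave(records$version, records$case_id, FUN = max)
  } else {
    idx <- stats::ave(ord, records$case_id, FUN = function(i) i[1])
    records$version[idx]
  }
  out <- records[records$version == chosen, , drop = FALSE]
  # a version tie means a byte-identical duplicate block: keep the last copy
  out[!duplicated(out, fromLast = TRUE), , drop = FALSE]
}

#' Keep only suspected-drug records
#'
#' Restricting to drugs the reporter judged associated with the event keeps
#' the drug-event link strong; concomitant and interacting records are
#' dropped. Order is preserved.
#'
#' @param records Drug-record tibble with a `role` column.
#' @return The subset with `role == "suspected"`.
#' @export
filter_suspected <- function(records) {
  records[!is.na(records$role) & records$role == "suspected", , drop = FALSE]
}

#' Link drug and reaction tables into the drug-event pair universe
#'
#' Joins the two (already deduplicated) tables on the case identifier: each
#' case contributes the Cartesian product of its drug records and its event
#' records. Under the default `unit = "triple"` the product is collapsed to
#' unique (case, drug, PT) triples, so a drug listed twice in one case, or a
#' PT recorded twice, counts once per case — each suspected drug of a
#' multi-drug report is a separate analysis unit, but the same drug/PT
#' combination is never double-counted within a case. Cases present in only
#' one table contribute no pairs.
#'
#' @param drugs Drug-record tibble (typically after [deduplicate_cases()]
#'   and [filter_suspected()]).
#' @param events Reaction-record tibble (after [deduplicate_cases()]).
#' @param unit `"triple"` (default) counts distinct (case, drug, PT)
#'   triples; `"row"` keeps every drug-row-by-event-row combination.
#' @return A [pair_universe] tibble with columns `case_id`, `drug_name`,
#'   `pt_name`, `pt_code`.
#' @export
link_drug_event <- function(drugs, events, unit = c("triple", "row")) {
  unit <- match.arg(unit)
  if (!"pt_code" %in% names(events)) events$pt_code <- NA_character_
  pairs <- dplyr::inner_join(
    drugs[, c("case_id", "drug_name")],
    events[, c("case_id", "pt_name", "pt_code")],
    by = "case_id", relationship = "many-to-many"
  )
  if (unit == "triple") {
    pairs <- dplyr::distinct(pairs, .data$case_id, .data$drug_name,
                             .data$pt_name, .keep_all = TRUE)
  }
  new_pair_universe(pairs)
}

# ---- pair universe container ------------------------------------------------

new_pair_universe <- function(pairs) {
  needed <- c("case_id", "drug_name", "pt_name", "pt_code")
  stopifnot(all(needed %in% names(pairs)))
  structure(tibble::as_tibble(pairs[, needed]),
            class = c("pair_universe", class(tibble::tibble())))
}

#' Number of drug-event pairs in a universe
#'
#' The grand total of the 2x2 margin: every disproportionality statistic is
#' computed against this denominator.
#'
#' @param universe A [pair_universe].
#' @return Integer count of pairs.
#' @export
n_total <- function(universe) nrow(universe)

#' @export
print.pair_universe <- function(x, ...) {
  cat("<pair_universe> ", nrow(x), " drug-event pairs, ",
      dplyr::n_distinct(x$case_id), " cases, ",
      dplyr::n_distinct(x$drug_name), " drugs, ",
      dplyr::n_distinct(x$pt_name), " PTs\n", sep = "")
  NextMethod()
}

#' Write a pair universe as TSV
#'
#' @param universe A [pair_universe].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pair_universe <- function(universe, path) {
  readr::write_tsv(tibble::as_tibble(universe), path, na = "")
  invisible(path)
}
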