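# End-to-end orchestration: load -> dedup -> filter -> link -> extract ->
# detect -> classify -> report, with a stage-count manifest sufficient to
# redraw the analysis flow chart.

#' Configuration for a full pipeline run
#'
#' Bundles the input paths, dialect, PT queries, detection criteria and
#' optional classification inputs. Thresholds live in `criteria` so
#' sensitivity analyses never require code edits. The resolved configuration
#' is echoed into the output directory on every run.
#'
#' @param drug_path,reac_path Paths to the drug and reaction CSV tables.
#' @param dialect A [table_dialect()].
#' @param pt_queries PT query tibble; default the packaged
#'   appetite/taste set.
#' @param criteria A [signal_config()].
#' @param category_map_path Optional drug-to-category CSV
#'   (see [read_category_map()]); enables classification stages.
#' @param annotation_path Optional package-insert annotation CSV
#'   (see [read_insert_annotations()]).
#' @param out_dir Optional output directory; when given, report tables and
#'   the manifest are written there.
#' @param dedup_strategy Passed to [deduplicate_cases()].
#' @param unit Counting unit for [link_drug_event()].
#' @param exclusion_prefix Category-code prefix excluded as
#'   antineoplastic.
#' @param synonyms Optional drug synonym map (see [read_report_table()]).
#' @return A list of class `run_config`.
#' @export
run_config <- function(drug_path, reac_path,
                       dialect = dialect_jader(),
                       pt_queries = default_pt_set(),
                       criteria = signal_config(),
                       category_map_path = NULL,
                       annotation_path = NULL,
                       out_dir = NULL,
                       dedup_strategy = c("latest_version", "first_seen"),
                       unit = c("triple", "row"),
                       exclusion_prefix = "42",
                       synonyms = NULL) {
  structure(
    list(drug_path = drug_path, reac_path = reac_path, dialect = dialect,
         pt_queries = as_pt_queries(pt_queries), criteria = criteria,
         category_map_path = category_map_path,
         annotation_path = annotation_path, out_dir = out_dir,
         dedup_strategy = match.arg(dedup_strategy),
         unit = match.arg(unit),
         exclusion_prefix = exclusion_prefix,
         synonyms = synonyms),
    class = "run_config"
  )
}

#' Run the full signal-detection pipeline
#'
#' Reads both tables, removes duplicate report versions, restricts the drug
#' table to suspected records, links into the pair universe, extracts the
#' target-PT subset, detects signals, and — when a category map is
#' configured — applies the antineoplastic exclusion, per-category
#' summaries, multi-PT overlap, and (with an annotation table) the
#' package-insert cross-tab. Identical inputs and configuration give
#' identical outputs; any stage failure aborts with the stage name.
#'
#' @param config A [run_config()].
#' @return List of class `pipeline_result` with elements `manifest` (a
#'   `run_manifest`), `universe`, `target_pairs`, `pt_summary`, `signals`
#'   (all candidates), and when configured `classified` (kept / excluded /
#'   unresolved), `category_summaries` (per PT), `multi_pt`,
#'   `insert_status` (per PT family). Files are written when
#'   `config$out_dir` is set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  drugs_raw <- stage("ingest drug table",
                     read_report_table(config$drug_path, "drug",
                                       config$dialect, config$synonyms))
  events_raw <- stage("ingest reac table",
                      read_report_table(config$reac_path, "reac",
                                        config$dialect))
  drugs <- stage("deduplicate drug table",
                 deduplicate_cases(drugs_raw, config$dedup_strategy))
  events <- stage("deduplicate reac table",
                  deduplicate_cases(events_raw, config$dedup_strategy))
  suspected <- stage("filter suspected", filter_suspected(drugs))
  universe <- stage("link drug-event",
                    link_drug_event(suspected, events, config$unit))
  target <- stage("extract target PTs",
                  extract_target_pairs(universe, config$pt_queries,
                                       config$criteria$match_on))
  pt_summary <- stage("summarize PT counts",
                      summarize_pt_counts(universe, config$pt_queries,
                                          config$criteria$match_on))
  signals <- stage("detect signals",
                   detect_signals(universe, config$pt_queries,
                                  config$criteria))
  flagged <- signals[signals$signal, , drop = FALSE]

  signals_per_pt <- vapply(config$pt_queries$pt_name,
                           function(p) sum(flagged$pt_name == p),
                           integer(1))
  pairs_per_pt <- stats::setNames(pt_summary$n_reports, pt_summary$pt_name)

  result <- list(
    universe = universe,
    target_pairs = target,
    pt_summary = pt_summary,
    signals = signals
  )

  if (!is.null(config$category_map_path)) {
    category_map <- stage("read category map",
                          read_category_map(config$category_map_path))
    classified <- stage("antineoplastic exclusion",
                        exclude_antineoplastics(flagged, category_map,
                                                config$exclusion_prefix))
    result$classified <- classified
    result$category_summaries <- stage("category summaries", {
      pts <- unique(classified$kept$pt_name)
      stats::setNames(
        lapply(pts, function(p) summarize_by_category(classified$kept, pt = p)),
        pts
      )
    })
    result$multi_pt <- stage("multi-PT overlap",
                             find_multi_pt_drugs(classified$kept))
    if (!is.null(config$annotation_path)) {
      annotation <- stage("read insert annotations",
                          read_insert_annotations(config$annotation_path))
      kept <- classified$kept
      result$insert_status <- stage("insert-annotation cross-tab", list(
        appetite = annotate_insert_status(
          kept[kept$pt_name %in% appetite_pt_names(), , drop = FALSE],
          annotation, "appetite"),
        taste = annotate_insert_status(
          kept[kept$pt_name %in% taste_pt_names(), , drop = FALSE],
          annotation, "taste")
      ))
    }
  }

  manifest <- structure(
    list(
      rows_drug_raw = nrow(drugs_raw),
      rows_reac_raw = nrow(events_raw),
      rows_drug_dedup = nrow(drugs),
      rows_reac_dedup = nrow(events),
      cases_drug = dplyr::n_distinct(drugs$case_id),
      cases_reac = dplyr::n_distinct(events$case_id),
      n_suspected_records = nrow(suspected),
      n_pairs = n_total(universe),
      n_target_pairs = n_total(target),
      pairs_per_pt = pairs_per_pt,
      n_candidates = nrow(signals),
      n_signals = nrow(flagged),
      signals_per_pt = signals_per_pt,
      package_version = as.character(utils::packageVersion("jadersignal")),
      config_hash = rlang::hash(config[setdiff(names(config), "out_dir")])
    ),
    class = "run_manifest"
  )
  result$manifest <- manifest

  if (!is.null(config$out_dir)) {
    write_report_tables(result, manifest, config$out_dir)
    echo <- config
    echo$out_dir <- NULL  # keep the echo invariant to where it is written
    echo$dialect <- config$dialect$name
    echo$criteria <- unclass(config$criteria)
    echo$pt_queries <- as.data.frame(config$pt_queries)
    jsonlite::write_json(echo[!vapply(echo, is.null, logical(1))],
                         file.path(config$out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  structure(result, class = "pipeline_result")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>\n")
  cat("  drug rows read:      ", x$rows_drug_raw,
      " -> after dedup: ", x$rows_drug_dedup,
      " (", x$cases_drug, " cases)\n", sep = "")
  cat("  reac rows read:      ", x$rows_reac_raw,
      " -> after dedup: ", x$rows_reac_dedup,
      " (", x$cases_reac, " cases)\n", sep = "")
  cat("  suspected records:   ", x$n_suspected_records, "\n", sep = "")
  cat("  drug-event pairs:    ", x$n_pairs,
      " (target-PT subset: ", x$n_target_pairs, ")\n", sep = "")
  cat("  candidates tested:   ", x$n_candidates, "\n", sep = "")
  cat("  signals:             ", x$n_signals, " [",
      paste(names(x$signals_per_pt), x$signals_per_pt, sep = "=",
            collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' Write the report tables of a pipeline run
#'
#' Emits the per-candidate signal table, the PT summary, and — when the run
#' was classified — per-PT category summaries with a total row, the
#' multi-PT overlap table and the insert-annotation cross-tab, as TSV
#' (floats at full precision in the JSON sidecar, 4 significant digits in
#' the TSVs) plus a machine-readable JSON manifest. Zero signals still
#' produce valid, headers-only tables.
#'
#' @param result A `pipeline_result` (or a list with the same elements).
#' @param manifest The run's `run_manifest`.
#' @param out_dir Output directory, created if needed.
#' @return Character vector of the files written, invisibly.
#' @export
write_report_tables <- function(result, manifest, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character()
  emit_tsv <- function(tbl, name, signif4 = TRUE) {
    path <- file.path(out_dir, name)
    if (signif4) {
      num <- vapply(tbl, is.double, logical(1))
      tbl[num] <- lapply(tbl[num], signif, digits = 4)
    }
    readr::write_tsv(tbl, path, na = "")
    written <<- c(written, path)
  }

  emit_tsv(result$signals, "signals.tsv")
  jsonlite::write_json(as.data.frame(result$signals),
                       file.path(out_dir, "signals.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  written <- c(written, file.path(out_dir, "signals.json"))
  emit_tsv(result$pt_summary, "pt_summary.tsv", signif4 = FALSE)

  if (!is.null(result$category_summaries)) {
    for (pt in names(result$category_summaries)) {
      body <- result$category_summaries[[pt]]
      total <- tibble::tibble(
        category_label = "Total",
        n_drugs = sum(body$n_drugs),
        drug_names = "",
        total_reports = sum(body$total_reports)
      )
      slug <- gsub("[^a-z0-9]+", "_", tolower(pt))
      emit_tsv(dplyr::bind_rows(body, total),
               paste0("category_", slug, ".tsv"), signif4 = FALSE)
    }
  }
  if (!is.null(result$multi_pt)) {
    mp <- result$multi_pt
    mp$pt_names <- vapply(mp$pt_names, paste, character(1), collapse = "; ")
    emit_tsv(mp, "multi_pt_drugs.tsv", signif4 = FALSE)
  }
  if (!is.null(result$insert_status)) {
    cross <- dplyr::bind_rows(lapply(result$insert_status, function(s) {
      tibble::tibble(pt_family = s$pt_family, n_listed = s$n_listed,
                     n_unlisted = s$n_unlisted,
                     unreviewed = paste(s$unreviewed, collapse = "; "))
    }))
    emit_tsv(cross, "insert_annotation.tsv", signif4 = FALSE)
  }

  manifest_out <- unclass(manifest)
  manifest_out$pairs_per_pt <- as.list(manifest_out$pairs_per_pt)
  manifest_out$signals_per_pt <- as.list(manifest_out$signals_per_pt)
  jsonlite::write_json(manifest_out, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  written <- c(written, file.path(out_dir, "manifest.json"))
  invisible(written)
}
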