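# Table dialects: where the physical CSV layout of a spontaneous-report dump
# lives. No physical column name or role string is hard-coded anywhere else.

#' Describe the physical layout of a spontaneous-report CSV dump
#'
#' A table dialect names, for one database distribution, the physical CSV
#' column holding each logical field, the vocabulary used in the drug-role
#' column, and the byte encodings to try when decoding the files. All reading
#' and writing goes through a dialect, so the same pipeline runs unchanged on
#' the Japanese JADER header, on the plain-ASCII layout used by the synthetic
#' generator, or on any other layout the user describes.
#'
#' @param name Short identifier for the dialect.
#' @param encodings Character vector of byte encodings, tried in order when
#'   decoding a file. The first entry is used when writing.
#' @param drug_cols Named character vector mapping the logical drug-table
#'   fields `case_id`, `version`, `drug_seq`, `role`, `drug_name` to physical
#'   column names.
#' @param reac_cols Named character vector mapping the logical reaction-table
#'   fields `case_id`, `version`, `pt_name` (and optionally `pt_code`) to
#'   physical column names.
#' @param role_vocabulary Named character vector translating the physical
#'   role strings to the canonical roles `"suspected"`, `"concomitant"`,
#'   `"interacting"`.
#' @param na Strings read as missing values.
#'
#' @return An object of class `table_dialect`.
#' @seealso [dialect_jader()], [dialect_ascii()]
#' @export
table_dialect <- function(name, encodings, drug_cols, reac_cols,
                          role_vocabulary, na = c("", "NA")) {
  required_drug <- c("case_id", "version", "drug_seq", "role", "drug_name")
  required_reac <- c("case_id", "version", "pt_name")
  missing_drug <- setdiff(required_drug, names(drug_cols))
  if (length(missing_drug) > 0) {
    stop("drug_cols must map: ", paste(missing_drug, collapse = ", "),
         call. = FALSE)
  }
  missing_reac <- setdiff(required_reac, names(reac_cols))
  if (length(missing_reac) > 0) {
    stop("reac_cols must map: ", paste(missing_reac, collapse = ", "),
         call. = FALSE)
  }
  bad_roles <- setdiff(unname(role_vocabulary), drug_roles())
  if (length(bad_roles) > 0) {
    stop("role_vocabulary values must be one of ",
         paste(drug_roles(), collapse = "/"), "; got: ",
         paste(bad_roles, collapse = ", "), call. = FALSE)
  }
  structure(
    list(name = name, encodings = encodings, drug_cols = drug_cols,
         reac_cols = reac_cols, role_vocabulary = role_vocabulary, na = na),
    class = "table_dialect"
  )
}

#' The canonical drug-role levels
#'
#' Spontaneous-report drug tables label each drug record as suspected of
#' causing the event, concomitant at the time of the event, or interacting
#' with a suspected drug. Only suspected records enter the analysis.
#'
#' @return Character vector of the three canonical roles.
#' @export
drug_roles <- function() c("suspected", "concomitant", "interacting")

#' Dialect for the Japanese JADER distribution
#'
#' Physical column names and role vocabulary of the drug (`drug`) and
#' reaction (`reac`) tables as distributed by the PMDA, which ship in a
#' Shift-JIS-family encoding (CP932 is tried first, UTF-8 as fallback).
#' The reaction table carries PT names only; PT codes come from the user's
#' query list.
#'
#' @return A `table_dialect`.
#' @export
dialect_jader <- function() {
  table_dialect(
    name = "jader-ja",
    encodings = c("CP932", "UTF-8"),
    drug_cols = c(case_id = "識別番号",
                  version = "報告回数",
                  drug_seq = "医薬品連番",
                  role = "医薬品の関与",
                  drug_name = "医薬品（一般名）"),
    reac_cols = c(case_id = "識別番号",
                  version = "報告回数",
                  pt_name = "有害事象"),
    role_vocabulary = c("被疑薬" = "suspected",
                        "併用薬" = "concomitant",
                        "相互作用" = "interacting")
  )
}

#' Plain-ASCII test dialect
#'
#' UTF-8 files with English column names and canonical role strings; used by
#' the synthetic generator and the packaged fixtures. The reaction table
#' carries both PT names and 8-digit PT codes.
#'
#' @return A `table_dialect`.
#' @export
dialect_ascii <- function() {
  table_dialect(
    name = "ascii",
    encodings = "UTF-8",
    drug_cols = c(case_id = "case_id", version = "version",
                  drug_seq = "drug_seq", role = "role",
                  drug_name = "drug_name"),
    reac_cols = c(case_id = "case_id", version = "version",
                  pt_name = "pt_name", pt_code = "pt_code"),
    role_vocabulary = c(suspected = "suspected",
                        concomitant = "concomitant",
                        interacting = "interacting")
  )
}

#' @export
print.table_dialect <- function(x, ...) {
  cat("<table_dialect '", x$name, "'> encodings: ",
      paste(x$encodings, collapse = " > "), "\n", sep = "")
  invisible(x)
}
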