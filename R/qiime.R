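# Character vocabularies for the QIIME sample metadata mapping format.
# Sample IDs: alphanumerics and period. Barcodes: unambiguous DNA. Primers:
# the IUPAC nucleotide alphabet (degenerate codes included) plus comma, the
# multi-primer separator.
SAMPLEID_CLASS <- "A-Za-z0-9."
BARCODE_CLASS <- "ACGT"
IUPAC_CLASS <- "ACGTRYSWKMBDHVN"

# Default free-text class: alphanumerics, space and + - % . / : , ; _ =
# This class is a documented, configurable default chosen to match common
# QIIME-era metadata conventions; hyphen sits last so the class body is a
# valid regex fragment.
QIIME_FREE_TEXT_CLASS <- "A-Za-z0-9 +%./:,;_=-"

#' Built-in rule set for QIIME sample metadata mapping files
#'
#' A TSV-dialect rule set implementing the QIIME mapping-file format checks:
#' positional header rules (first column `#SampleID`, last column
#' `Description`), unique sample identifiers, fixed-length unique DNA
#' barcodes, IUPAC-alphabet linker primer sequences, and generic per-cell
#' warnings (empty cells, leading/trailing whitespace, characters outside
#' the free-text class). Rule ids are stable public identifiers usable in
#' override documents:
#'
#' `header_first_sampleid`, `header_last_description`, `header_duplicates`,
#' `sampleid_nonempty`, `sampleid_characters`, `sampleid_unique`,
#' `barcode_characters`, `barcode_uniform_length`, `barcode_unique`,
#' `primer_characters` (all errors); `cell_empty`,
#' `cell_leading_trailing_whitespace`, `cell_invalid_characters` (warnings).
#'
#' The format validates only against the file-format specification — it has
#' no datetime rule, so e.g. an invalid value in a `Date_Time` metadata
#' column passes QIIME validation (but not SRGD validation, see
#' [srgd_ruleset()]).
#'
#' @param free_text_class Regex character-class body of characters allowed
#'   in generic metadata cells.
#' @param exclude_comment_rows Treat rows after the header whose first cell
#'   starts with `#` as comment rows, excluded from all data-cell rules
#'   (QIIME convention).
#' @return A [ruleset()].
#' @examples
#' rs <- qiime_ruleset()
#' rule_ids(rs)
#' @export
qiime_ruleset <- function(free_text_class = QIIME_FREE_TEXT_CLASS,
                          exclude_comment_rows = TRUE) {
  lowercase_ok <- TRUE # sequences are case-insensitive by convention
  rules <- list(
    rule("header_first_sampleid",
         "first header cell must be '#SampleID'",
         severity = "error", scope = "sheet",
         check = function(grid, ctx) {
           if (identical(grid$cells[1, 1], "#SampleID")) return(no_findings())
           findings(1L, 1L, sprintf(
             "first header cell is '%s'; expected '#SampleID'", grid$cells[1, 1]))
         }),
    rule("header_last_description",
         "last header cell must be 'Description'",
         severity = "error", scope = "sheet",
         check = function(grid, ctx) {
           nc <- grid$n_cols
           if (identical(grid$cells[1, nc], "Description")) return(no_findings())
           findings(1L, nc, sprintf(
             "last header cell is '%s'; expected 'Description'", grid$cells[1, nc]))
         }),
    rule("header_duplicates",
         "header names must be unique",
         severity = "error", scope = "sheet",
         check = function(grid, ctx) {
           groups <- split(seq_len(grid$n_cols), grid$cells[1, ])
           groups <- groups[lengths(groups) > 1]
           if (length(groups) == 0L) return(no_findings())
           findings(
             rows = lapply(groups, function(g) rep(1L, length(g))),
             cols = unname(groups),
             reason = sprintf("duplicate header '%s'", names(groups))
           )
         }),
    prim_non_empty("#SampleID", "sampleid_nonempty", severity = "error"),
    prim_character_class("#SampleID", SAMPLEID_CLASS, "sampleid_characters",
                         severity = "error"),
    prim_unique_values("#SampleID", "sampleid_unique", severity = "error",
                       what = "sample identifier"),
    prim_character_class("BarcodeSequence", BARCODE_CLASS, "barcode_characters",
                         severity = "error", case_insensitive = lowercase_ok,
                         what = "unambiguous DNA characters"),
    prim_fixed_length("BarcodeSequence", "barcode_uniform_length",
                      severity = "error", what = "barcode"),
    prim_unique_values("BarcodeSequence", "barcode_unique", severity = "error",
                       what = "barcode sequence"),
    primer_rule(),
    prim_non_empty("all", "cell_empty", severity = "warning"),
    prim_whitespace("all", "cell_leading_trailing_whitespace",
                    severity = "warning"),
    prim_character_class("all", free_text_class, "cell_invalid_characters",
                         severity = "warning")
  )
  filter <- function(grid) {
    rows <- if (grid$n_rows >= 2L) 2:grid$n_rows else integer(0)
    if (exclude_comment_rows && length(rows)) {
      rows <- rows[!startsWith(grid$cells[rows, 1], "#")]
    }
    rows
  }
  ruleset("QIIME mapping file", "tsv", rules, data_row_filter = filter)
}

# Linker primer cells hold one or more comma-separated primer sequences in
# the IUPAC nucleotide alphabet; every component must be non-empty.
primer_rule <- function() {
  rule(
    "primer_characters",
    "linker primer components must be non-empty IUPAC nucleotide sequences",
    severity = "error", scope = "column", columns = "LinkerPrimerSequence",
    check = function(grid, ctx) {
      per_column(grid, ctx, function(v, rows, col) {
        out <- no_findings()
        for (i in which(nzchar(v))) {
          comps <- split_primer(v[i])
          reasons <- character(0)
          if (any(comps == "")) {
            reasons <- "empty primer component (stray comma)"
          }
          bad <- unique(unlist(lapply(toupper(comps[nzchar(comps)]),
                                      offending_chars, IUPAC_CLASS)))
          if (length(bad)) {
            reasons <- c(reasons, sprintf(
              "invalid character(s) %s (allowed: IUPAC nucleotide codes)",
              describe_chars(bad)))
          }
          if (length(reasons)) {
            out <- dplyr::bind_rows(out, findings(rep(rows[i], length(reasons)),
                                                  rep(col, length(reasons)),
                                                  reasons))
          }
        }
        out
      })
    }
  )
}

# strsplit drops trailing empty components; keep them so "ACGT," is flagged
split_primer <- function(s) {
  p <- strsplit(s, ",", fixed = TRUE)[[1]]
  n <- stringr::str_count(s, stringr::fixed(",")) + 1L
  c(p, rep("", n - length(p)))
}
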