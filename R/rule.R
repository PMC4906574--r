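#' @importFrom rlang %||%
NULL

#' Construct a validation rule
#'
#' A rule is one named check with a scope and a default severity. Its check
#' function receives the grid plus a context (resolved column indices and the
#' data-row indices) and returns findings; it never mutates the grid.
#'
#' @param id Unique short name within a rule set (the stable public
#'   identifier used in override documents and reports).
#' @param description One-line human-readable description.
#' @param severity Default severity, `"error"` or `"warning"`. Errors mark
#'   format violations; warnings mark suspect-but-tolerated content.
#' @param scope `"cell"`, `"column"`, or `"sheet"`.
#' @param columns Column selector: a character vector of header names, an
#'   integer vector of positional indices, `"all"` for every column, or
#'   `NULL` for sheet-scope rules that resolve their own targets.
#' @param check A function `function(grid, ctx)` returning a findings tibble
#'   as built by [findings()]. `ctx` has elements `cols` (resolved column
#'   indices), `data_rows` (validatable data-row indices) and `headers`.
#' @param optional_columns If `TRUE`, the rule is skipped silently when its
#'   named columns are absent; if `FALSE` (default) a missing column is
#'   reported as a sheet-scope `missing_column` error and the rule skipped.
#' @return A `sheet_rule` object.
#' @export
rule <- function(id, description, severity = c("error", "warning"),
                 scope = c("cell", "column", "sheet"), columns = NULL,
                 check, optional_columns = FALSE) {
  severity <- match.arg(severity)
  scope <- match.arg(scope)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id), is.function(check))
  structure(
    list(id = id, description = description, severity = severity,
         scope = scope, columns = columns, check = check,
         optional_columns = isTRUE(optional_columns), enabled = TRUE),
    class = "sheet_rule"
  )
}

#' Build a findings table
#'
#' Helper used inside rule check functions. Each finding attaches one reason
#' to one or more cell addresses (multi-address findings link related cells,
#' e.g. a group of duplicate identifiers).
#'
#' @param rows,cols For single-cell findings, parallel integer vectors (one
#'   finding per element). For multi-address findings, lists of integer
#'   vectors.
#' @param reason Character vector of human-readable reasons, recycled.
#' @return A tibble with list-columns `rows`, `cols` and character `reason`.
#' @export
findings <- function(rows, cols, reason) {
  if (!is.list(rows)) rows <- as.list(as.integer(rows))
  if (!is.list(cols)) cols <- as.list(as.integer(cols))
  n <- length(rows)
  tibble::tibble(rows = rows, cols = cols, reason = rep_len(as.character(reason), n))
}

no_findings <- function() {
  tibble::tibble(rows = list(), cols = list(), reason = character(0))
}

#' Construct a rule set
#'
#' An ordered, configurable collection of rules defining a validation format.
#'
#' @param format_name Human-readable format name, e.g.
#'   `"QIIME mapping file"`.
#' @param dialect The file dialect the format uses, `"tsv"` or `"csv"`.
#' @param rules A list of [rule()] objects with unique ids.
#' @param data_row_filter Optional `function(grid)` returning the integer
#'   indices of validatable data rows. The default is every row after the
#'   header.
#' @return A `sheet_ruleset` object.
#' @export
ruleset <- function(format_name, dialect = c("tsv", "csv"), rules = list(),
                    data_row_filter = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(all(vapply(rules, inherits, logical(1), "sheet_rule")))
  ids <- vapply(rules, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate rule ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(rules) <- ids
  structure(
    list(format_name = format_name, dialect = dialect, rules = rules,
         data_row_filter = data_row_filter),
    class = "sheet_ruleset"
  )
}

#' @export
print.sheet_ruleset <- function(x, ...) {
  cat(sprintf("<sheet_ruleset: %s (%s), %d rules>\n",
              x$format_name, x$dialect, length(x$rules)))
  if (length(x$rules)) {
    df <- tibble::tibble(
      rule_id = vapply(x$rules, `[[`, character(1), "id"),
      severity = vapply(x$rules, `[[`, character(1), "severity"),
      scope = vapply(x$rules, `[[`, character(1), "scope"),
      enabled = vapply(x$rules, `[[`, logical(1), "enabled")
    )
    print(df, n = Inf)
  }
  invisible(x)
}

#' List the rule ids of a rule set
#'
#' @param rs A [ruleset()].
#' @return Character vector of rule ids, in rule order.
#' @export
rule_ids <- function(rs) {
  stopifnot(inherits(rs, "sheet_ruleset"))
  unname(vapply(rs$rules, `[[`, character(1), "id"))
}

#' Configure rule stringency
#'
#' Returns a new rule set with rules disabled or their severity overridden;
#' the original is unchanged. Disabling a rule (for example the
#' duplicate-barcode error when a mapping file is assembled from several
#' individual studies) removes its findings entirely; a severity override
#' changes only the effective severity of its findings.
#'
#' @param rs A [ruleset()].
#' @param overrides Named character vector or list mapping rule ids to
#'   `"disabled"`, `"error"` or `"warning"`.
#' @param disable Character vector of rule ids to disable (shorthand merged
#'   with `overrides`).
#' @return A new `sheet_ruleset`.
#' @examples
#' rs <- configure(qiime_ruleset(), disable = "barcode_unique")
#' @export
configure <- function(rs, overrides = NULL, disable = NULL) {
  stopifnot(inherits(rs, "sheet_ruleset"))
  overrides <- c(as.list(overrides %||% list()),
                 stats::setNames(as.list(rep("disabled", length(disable))), disable))
  if (length(overrides) == 0L) return(rs)
  known <- rule_ids(rs)
  unknown <- setdiff(names(overrides), known)
  if (length(unknown) || is.null(names(overrides)) || any(names(overrides) == "")) {
    stop("unknown rule id(s): ", paste(unknown, collapse = ", "),
         "; valid ids are: ", paste(known, collapse = ", "), call. = FALSE)
  }
  for (id in names(overrides)) {
    v <- as.character(overrides[[id]])
    if (v == "disabled") {
      rs$rules[[id]]$enabled <- FALSE
    } else if (v %in% c("error", "warning")) {
      rs$rules[[id]]$severity <- v
    } else {
      stop("override for ", sQuote(id, q = FALSE),
           " must be 'disabled', 'error' or 'warning', not ",
           sQuote(v, q = FALSE), call. = FALSE)
    }
  }
  rs
}

#' Read a rule-override document
#'
#' Override documents are YAML or JSON maps from rule id to `"disabled"`,
#' `"error"` or `"warning"`, applied with [configure()].
#'
#' @param path Path to a `.yml`/`.yaml` or `.json` file.
#' @return A named list of overrides.
#' @export
load_overrides <- function(path) {
  doc <- read_config_doc(path)
  if (!is.list(doc) || is.null(names(doc)) || any(names(doc) == "")) {
    stop("override document must be a map of rule id -> ",
         "'disabled'/'error'/'warning'", call. = FALSE)
  }
  doc
}

read_config_doc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
}
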