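# Parameterised primitive checks. Built-in formats and user-defined formats
# (load_ruleset) are both assembled from these constructors, so a custom
# document's behaviour under validate() is fully determined by its
# declarations.

column_values <- function(grid, ctx, col) grid$cells[ctx$data_rows, col]

# apply fn(values, rows, col) over every resolved column, binding findings
per_column <- function(grid, ctx, fn) {
  if (length(ctx$data_rows) == 0L || length(ctx$cols) == 0L) return(no_findings())
  dplyr::bind_rows(lapply(ctx$cols, function(col) {
    fn(column_values(grid, ctx, col), ctx$data_rows, col)
  }))
}

describe_chars <- function(chars) {
  shown <- vapply(chars, function(ch) {
    if (ch == " ") "space" else if (ch == "\t") "tab" else paste0("'", ch, "'")
  }, character(1))
  paste(shown, collapse = ", ")
}

offending_chars <- function(value, allowed_class) {
  bad <- gsub(sprintf("[%s]", allowed_class), "", value)
  unique(strsplit(bad, "", fixed = TRUE)[[1]])
}

prim_required_header <- function(column, id, severity = "error") {
  rule(
    id = id, severity = severity, scope = "sheet",
    description = sprintf("header row must contain a '%s' column", column),
    check = function(grid, ctx) {
      if (column %in% ctx$headers) return(no_findings())
      findings(1L, 1L, sprintf("required column '%s' not found in header row", column))
    }
  )
}

prim_unique_values <- function(column, id, severity = "error",
                               what = "value", optional = FALSE) {
  rule(
    id = id, severity = severity, scope = "column", columns = column,
    optional_columns = optional,
    description = sprintf("values in column '%s' must be unique", column),
    check = function(grid, ctx) {
      per_column(grid, ctx, function(v, rows, col) {
        keep <- nzchar(v) # missing is not duplicate
        groups <- split(rows[keep], v[keep])
        groups <- groups[lengths(groups) > 1]
        if (length(groups) == 0L) return(no_findings())
        findings(
          rows = unname(groups),
          cols = lapply(groups, function(g) rep(col, length(g))),
          reason = sprintf("duplicate %s '%s' (%s must be unique)",
                           what, names(groups), what)
        )
      })
    }
  )
}

prim_character_class <- function(columns, allowed, id, severity = "error",
                                 case_insensitive = FALSE,
                                 what = "characters") {
  bad_re <- sprintf("[^%s]", allowed)
  rule(
    id = id, severity = severity,
    scope = if (identical(columns, "all")) "cell" else "column",
    columns = columns,
    description = sprintf("cells may contain only the %s [%s]", what, allowed),
    check = function(grid, ctx) {
      per_column(grid, ctx, function(v, rows, col) {
        probe <- if (case_insensitive) toupper(v) else v
        idx <- which(nzchar(v) & grepl(bad_re, probe))
        if (length(idx) == 0L) return(no_findings())
        findings(rows[idx], rep(col, length(idx)), vapply(idx, function(i) {
          sprintf("invalid character(s) %s",
                  describe_chars(offending_chars(probe[i], allowed)))
        }, character(1)))
      })
    }
  )
}

prim_fixed_length <- function(column, id, severity = "error", length = NULL,
                              what = "value") {
  rule(
    id = id, severity = severity, scope = "column", columns = column,
    description = sprintf("non-empty values in column '%s' must share one length", column),
    check = function(grid, ctx) {
      per_column(grid, ctx, function(v, rows, col) {
        keep <- which(nzchar(v))
        if (length(keep) == 0L) return(no_findings())
        lens <- nchar(v[keep])
        target <- length
        if (is.null(target)) {
          tab <- table(lens)
          modal <- as.integer(names(tab)[tab == max(tab)])
          target <- min(modal) # tie broken toward the smaller length
        }
        idx <- keep[lens != target]
        if (base::length(idx) == 0L) return(no_findings())
        findings(rows[idx], rep(col, base::length(idx)),
                 sprintf("%s length %d differs from expected length %d",
                         what, nchar(v[idx]), target))
      })
    }
  )
}

prim_non_empty <- function(columns, id, severity = "warning") {
  rule(
    id = id, severity = severity,
    scope = if (identical(columns, "all")) "cell" else "column",
    columns = columns,
    description = "cells must not be empty or whitespace-only",
    check = function(grid, ctx) {
      per_column(grid, ctx, function(v, rows, col) {
        idx <- which(trimws(v) == "")
        if (length(idx) == 0L) return(no_findings())
        findings(rows[idx], rep(col, length(idx)), "cell is empty")
      })
    }
  )
}

prim_whitespace <- function(columns, id, severity = "warning") {
  rule(
    id = id, severity = severity,
    scope = if (identical(columns, "all")) "cell" else "column",
    columns = columns,
    description = "cells must not have leading or trailing whitespace",
    check = function(grid, ctx) {
      per_column(grid, ctx, function(v, rows, col) {
        idx <- which(nzchar(v) & v != trimws(v))
        if (length(idx) == 0L) return(no_findings())
        findings(rows[idx], rep(col, length(idx)),
                 "cell has leading and/or trailing whitespace")
      })
    }
  )
}

prim_datetime <- function(column, id, severity = "error",
                          spec = datetime_spec(), optional = FALSE) {
  rule(
    id = id, severity = severity, scope = "column", columns = column,
    optional_columns = optional,
    description = sprintf("column '%s' must contain valid datetimes (%s)",
                          column, spec$pattern),
    check = function(grid, ctx) {
      per_column(grid, ctx, function(v, rows, col) {
        idx <- which(nzchar(v))
        reasons <- vapply(idx, function(i) check_datetime(v[i], spec) %||% NA_character_,
                          character(1))
        bad <- !is.na(reasons)
        if (!any(bad)) return(no_findings())
        findings(rows[idx[bad]], rep(col, sum(bad)), reasons[bad])
      })
    }
  )
}

prim_numeric_range <- function(column, id, severity = "error",
                               min = -Inf, max = Inf, optional = FALSE) {
  rule(
    id = id, severity = severity, scope = "column", columns = column,
    optional_columns = optional,
    description = sprintf("column '%s' must be numeric in [%s, %s]", column, min, max),
    check = function(grid, ctx) {
      per_column(grid, ctx, function(v, rows, col) {
        idx <- which(nzchar(v))
        if (length(idx) == 0L) return(no_findings())
        num <- suppressWarnings(as.numeric(v[idx]))
        not_num <- is.na(num) | !grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", v[idx])
        out <- !not_num & (num < min | num > max)
        reasons <- character(length(idx))
        reasons[not_num] <- sprintf("'%s' is not a number", v[idx][not_num])
        reasons[out] <- sprintf("%s is outside the allowed range [%s, %s]",
                                v[idx][out], min, max)
        bad <- not_num | out
        if (!any(bad)) return(no_findings())
        findings(rows[idx[bad]], rep(col, sum(bad)), reasons[bad])
      })
    }
  )
}

# ---------------------------------------------------------------------------
# User-defined formats

PRIMITIVES <- c("required-header", "unique-values-in-column", "character-class",
                "fixed-length-column", "non-empty",
                "no-leading-trailing-whitespace", "datetime-format",
                "numeric-range")

#' Load a user-defined format (rule set) from YAML or JSON
#'
#' Custom formats are declared from a closed vocabulary of parameterised
#' primitive checks, so a format's behaviour under [validate()] is fully
#' determined by the document — no code. The document must declare
#' `format_name`, `dialect` (`tsv`/`csv`) and a `rules` list; each rule names
#' its primitive under `check`, a target `column` (a header name, or `"all"`
#' where the primitive supports it), an optional `id` and `severity`, and the
#' primitive's parameters:
#'
#' * `required-header` — no extra parameters.
#' * `unique-values-in-column` — none.
#' * `character-class` — `characters`: regex character-class body of allowed
#'   characters (e.g. `"A-Za-z0-9."`).
#' * `fixed-length-column` — optional `length` (defaults to the modal length).
#' * `non-empty`, `no-leading-trailing-whitespace` — none; `column` may be
#'   `"all"`.
#' * `datetime-format` — optional `pattern` (default
#'   `"%Y-%m-%d %H:%M:%S"`) and `calendar_aware` flag.
#' * `numeric-range` — `min` and/or `max`.
#'
#' @param path Path to a `.yml`/`.yaml` or `.json` document.
#' @return A [ruleset()].
#' @examples
#' f <- tempfile(fileext = ".yml")
#' writeLines(c("format_name: my format", "dialect: csv", "rules:",
#'              "- check: unique-values-in-column", "  column: ID"), f)
#' load_ruleset(f)
#' @export
load_ruleset <- function(path) {
  doc <- read_config_doc(path)
  for (field in c("format_name", "dialect")) {
    if (!is.character(doc[[field]] <- as.character(doc[[field]] %||% character(0))) ||
        length(doc[[field]]) != 1L) {
      stop("rule-set document must declare '", field, "'", call. = FALSE)
    }
  }
  if (!doc$dialect %in% c("tsv", "csv")) {
    stop("rule-set document: dialect must be 'tsv' or 'csv'", call. = FALSE)
  }
  decls <- doc$rules %||% list()
  if (!is.list(decls)) stop("rule-set document: 'rules' must be a list", call. = FALSE)
  rules <- lapply(seq_along(decls), function(k) {
    build_declared_rule(decls[[k]], sprintf("rules[%d]", k))
  })
  ruleset(doc$format_name, doc$dialect, rules)
}

build_declared_rule <- function(decl, where) {
  if (!is.list(decl) || is.null(decl$check)) {
    stop("missing 'check' primitive at ", where, call. = FALSE)
  }
  prim <- as.character(decl$check)
  if (!prim %in% PRIMITIVES) {
    stop(sprintf("unknown primitive '%s' at %s (known: %s)", prim, where,
                 paste(PRIMITIVES, collapse = ", ")), call. = FALSE)
  }
  need <- function(param) {
    if (is.null(decl[[param]])) {
      stop(sprintf("missing parameter '%s' for primitive '%s' at %s",
                   param, prim, where), call. = FALSE)
    }
    decl[[param]]
  }
  column <- as.character(need("column"))
  severity <- as.character(decl$severity %||% "error")
  if (!severity %in% c("error", "warning")) {
    stop(sprintf("severity must be 'error' or 'warning' at %s", where), call. = FALSE)
  }
  id <- as.character(decl$id %||% paste0(gsub("-", "_", prim), "_", column))
  switch(prim,
    "required-header" = prim_required_header(column, id, severity),
    "unique-values-in-column" = prim_unique_values(column, id, severity),
    "character-class" = prim_character_class(column, as.character(need("characters")),
                                             id, severity),
    "fixed-length-column" = prim_fixed_length(
      column, id, severity,
      length = if (!is.null(decl$length)) as.integer(decl$length) else NULL),
    "non-empty" = prim_non_empty(column, id, severity),
    "no-leading-trailing-whitespace" = prim_whitespace(column, id, severity),
    "datetime-format" = prim_datetime(
      column, id, severity,
      spec = datetime_spec(
        pattern = as.character(decl$pattern %||% "%Y-%m-%d %H:%M:%S"),
        calendar_aware = isTRUE(decl$calendar_aware %||% TRUE))),
    "numeric-range" = prim_numeric_range(
      column, id, severity,
      min = as.numeric(decl$min %||% -Inf), max = as.numeric(decl$max %||% Inf))
  )
}
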