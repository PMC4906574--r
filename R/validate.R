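#' Validate a sheet grid against a rule set
#'
#' Evaluates every enabled rule over its scope and collects the findings into
#' a cell-addressed report of errors and warnings. The report is
#' deterministic for fixed inputs: messages appear in rule order, then in
#' row-major order of each finding's first address, and addresses within a
#' multi-address finding are row-major sorted.
#'
#' A rule set that names a required header absent from the grid produces a
#' single sheet-scope `missing_column` error per missing header (anchored at
#' cell A1) and the dependent column rules are skipped, not crashed. An
#' empty grid yields a single `no_content` error.
#'
#' @param grid A [sheet_grid()].
#' @param rs A [ruleset()] such as [qiime_ruleset()] or [srgd_ruleset()].
#' @return A `sheet_report` object; see [tidy.sheet_report()],
#'   [glance.sheet_report()], [invalid_cells()], [messages_for_cell()] and
#'   [cell_status()] for accessors.
#' @examples
#' g <- parse_delimited("#SampleID\tBarcodeSequence\tLinkerPrimerSequence\tDescription\ns1\tACGT\tACGT\tx\ns1\tTGCA\tACGT\ty\n")
#' validate(g, qiime_ruleset())
#' @export
validate <- function(grid, rs) {
  stopifnot(inherits(grid, "sheet_grid"), inherits(rs, "sheet_ruleset"))
  msgs <- list()
  if (grid$n_rows == 0L || grid$n_cols == 0L) {
    msgs[[1]] <- tibble::tibble(
      rule_id = "no_content", severity = "error",
      reason = "sheet has no content",
      rows = list(1L), cols = list(1L)
    )
    return(new_report(rs$format_name, grid, dplyr::bind_rows(msgs)))
  }
  headers <- grid$cells[1, ]
  data_rows <- if (is.null(rs$data_row_filter)) {
    if (grid$n_rows >= 2L) 2:grid$n_rows else integer(0)
  } else {
    rs$data_row_filter(grid)
  }
  reported_missing <- character(0)
  for (r in rs$rules) {
    if (!r$enabled) next
    cols <- NULL
    if (!is.null(r$columns)) {
      if (identical(r$columns, "all")) {
        cols <- seq_len(grid$n_cols)
      } else if (is.numeric(r$columns)) {
        cols <- intersect(as.integer(r$columns), seq_len(grid$n_cols))
      } else {
        cols <- match(r$columns, headers)
        missing <- r$columns[is.na(cols)]
        if (length(missing)) {
          if (!r$optional_columns) {
            new_missing <- setdiff(missing, reported_missing)
            reported_missing <- c(reported_missing, new_missing)
            for (h in new_missing) {
              msgs[[length(msgs) + 1]] <- tibble::tibble(
                rule_id = "missing_column", severity = "error",
                reason = sprintf(
                  "required column '%s' not found in header row; dependent rules skipped", h),
                rows = list(1L), cols = list(1L)
              )
            }
          }
          next
        }
      }
    }
    ctx <- list(cols = cols, data_rows = data_rows, headers = headers)
    f <- r$check(grid, ctx)
    if (NROW(f) == 0L) next
    # row-major sort of addresses within each finding, then findings by
    # their first address (single-address findings need no inner sort)
    for (k in which(lengths(f$rows) > 1L)) {
      o <- order((f$rows[[k]] - 1) * grid$n_cols + f$cols[[k]])
      f$rows[[k]] <- as.integer(f$rows[[k]][o])
      f$cols[[k]] <- as.integer(f$cols[[k]][o])
    }
    key <- (vapply(f$rows, `[[`, integer(1), 1L) - 1) * grid$n_cols +
      vapply(f$cols, `[[`, integer(1), 1L)
    f <- f[order(key), , drop = FALSE]
    msgs[[length(msgs) + 1]] <- tibble::tibble(
      rule_id = r$id, severity = r$severity, reason = f$reason,
      rows = f$rows, cols = f$cols
    )
  }
  new_report(rs$format_name, grid, dplyr::bind_rows(msgs))
}

new_report <- function(format_name, grid, messages) {
  if (NROW(messages) == 0L) {
    messages <- tibble::tibble(rule_id = character(0), severity = character(0),
                               reason = character(0), rows = list(), cols = list())
  }
  lens <- lengths(messages$rows)
  all_rows <- unlist(messages$rows, use.names = FALSE) %||% integer(0)
  all_cols <- unlist(messages$cols, use.names = FALSE) %||% integer(0)
  labels <- if (length(all_rows)) address_to_a1(all_rows, all_cols) else character(0)
  messages$cells <- if (nrow(messages)) {
    unname(split(labels, factor(rep(seq_len(nrow(messages)), lens),
                                levels = seq_len(nrow(messages)))))
  } else {
    list()
  }
  key <- (all_rows - 1) * max(1L, grid$n_cols) + all_cols
  sev <- rep(messages$severity, lens)
  err_keys <- unique(key[sev == "error"])
  all_keys <- unique(key)
  per_rule <- table(messages$rule_id)
  summary <- list(
    n_invalid_cells = length(all_keys),
    n_error_cells = length(err_keys),
    n_warning_only_cells = length(all_keys) - length(err_keys),
    n_messages = nrow(messages),
    messages_per_rule = stats::setNames(as.integer(per_rule), names(per_rule))
  )
  structure(
    list(format_name = format_name, n_rows = grid$n_rows, n_cols = grid$n_cols,
         messages = messages, summary = summary),
    class = "sheet_report"
  )
}

#' @export
print.sheet_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Validation report: %s\n", x$format_name))
  cat(sprintf("Sheet: %d rows x %d cols\n", x$n_rows, x$n_cols))
  cat(sprintf("Invalid cells: %d (%d with errors, %d warnings only)\n",
              s$n_invalid_cells, s$n_error_cells, s$n_warning_only_cells))
  if (nrow(x$messages)) {
    df <- tibble::tibble(
      cells = vapply(x$messages$cells, paste, character(1), collapse = ", "),
      severity = x$messages$severity,
      rule_id = x$messages$rule_id,
      reason = x$messages$reason
    )
    print(df, n = 50)
  } else {
    cat("No errors or warnings.\n")
  }
  invisible(x)
}

#' Tidy a validation report into one row per message-cell pair
#'
#' @param x A `sheet_report`.
#' @param ... Unused.
#' @return A tibble with columns `message` (index), `rule_id`, `severity`,
#'   `reason`, `row`, `col`, `cell` (A1 label).
#' @method tidy sheet_report
#' @export
tidy.sheet_report <- function(x, ...) {
  m <- x$messages
  lens <- lengths(m$rows)
  tibble::tibble(
    message = rep(seq_len(nrow(m)), lens),
    rule_id = rep(m$rule_id, lens),
    severity = rep(m$severity, lens),
    reason = rep(m$reason, lens),
    row = unlist(m$rows, use.names = FALSE) %||% integer(0),
    col = unlist(m$cols, use.names = FALSE) %||% integer(0),
    cell = unlist(m$cells, use.names = FALSE) %||% character(0)
  )
}

#' One-row summary of a validation report
#'
#' @param x A `sheet_report`.
#' @param ... Unused.
#' @return A one-row tibble with the sheet dimensions, message count and the
#'   invalid-cell counts (cells with at least one error, and cells with
#'   warnings only, partition the invalid cells).
#' @method glance sheet_report
#' @export
glance.sheet_report <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    format_name = x$format_name, n_rows = x$n_rows, n_cols = x$n_cols,
    n_messages = s$n_messages, n_invalid_cells = s$n_invalid_cells,
    n_error_cells = s$n_error_cells,
    n_warning_only_cells = s$n_warning_only_cells
  )
}

#' Distinct invalid cells of a report
#'
#' @param report A `sheet_report`.
#' @return A tibble with columns `row`, `col`, `cell` and `status`
#'   (`"error"` or `"warning"`), row-major sorted. A cell's status is its
#'   highest-severity finding (error outranks warning).
#' @export
invalid_cells <- function(report) {
  stopifnot(inherits(report, "sheet_report"))
  td <- tidy(report)
  if (nrow(td) == 0L) {
    return(tibble::tibble(row = integer(0), col = integer(0),
                          cell = character(0), status = character(0)))
  }
  td |>
    dplyr::group_by(.data$row, .data$col, .data$cell) |>
    dplyr::summarise(
      status = if (any(.data$severity == "error")) "error" else "warning",
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$row, .data$col)
}

check_bounds <- function(report, addr) {
  if (addr[1] > report$n_rows || addr[2] > report$n_cols) {
    stop(sprintf("cell %s is outside the %d x %d grid",
                 address_to_a1(addr[1], addr[2]), report$n_rows, report$n_cols),
         call. = FALSE)
  }
}

#' Messages touching one cell
#'
#' @param report A `sheet_report`.
#' @param cell An A1 label (e.g. `"A3"`) or a `c(row, col)` pair.
#' @return The report's message rows whose address set contains the cell, in
#'   report order; zero rows for a clean cell.
#' @export
messages_for_cell <- function(report, cell) {
  stopifnot(inherits(report, "sheet_report"))
  addr <- as_address(cell)
  check_bounds(report, addr)
  m <- report$messages
  hit <- vapply(seq_len(nrow(m)), function(k) {
    any(m$rows[[k]] == addr[1] & m$cols[[k]] == addr[2])
  }, logical(1))
  m[hit, , drop = FALSE]
}

#' Status of one cell
#'
#' @inheritParams messages_for_cell
#' @return `"error"` if any error-severity message touches the cell,
#'   `"warning"` if only warnings touch it, `"clean"` otherwise.
#' @export
cell_status <- function(report, cell) {
  m <- messages_for_cell(report, cell)
  if (nrow(m) == 0L) return("clean")
  if (any(m$severity == "error")) "error" else "warning"
}

#' Export a validation report as JSON
#'
#' The JSON document carries the format name, grid dimensions, every message
#' with its structured cell addresses, and the summary counts; it
#' round-trips through [report_from_json()].
#'
#' @param report A `sheet_report`.
#' @param pretty Pretty-print the JSON?
#' @return A JSON string.
#' @export
report_to_json <- function(report, pretty = TRUE) {
  stopifnot(inherits(report, "sheet_report"))
  m <- report$messages
  messages <- lapply(seq_len(nrow(m)), function(k) {
    list(
      rule_id = m$rule_id[k], severity = m$severity[k], reason = m$reason[k],
      cells = lapply(seq_along(m$rows[[k]]), function(j) {
        list(row = m$rows[[k]][j], col = m$cols[[k]][j], cell = m$cells[[k]][j])
      })
    )
  })
  doc <- list(
    format_name = report$format_name,
    grid = list(n_rows = report$n_rows, n_cols = report$n_cols),
    messages = messages,
    summary = report$summary
  )
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = pretty, digits = NA))
}

#' Rebuild a validation report from its JSON export
#'
#' @param json A JSON string or path to a JSON file produced by
#'   [report_to_json()]/[write_report()].
#' @return A `sheet_report` equal field-by-field to the exported one.
#' @export
report_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  msgs <- dplyr::bind_rows(lapply(doc$messages, function(mm) {
    tibble::tibble(
      rule_id = mm$rule_id, severity = mm$severity, reason = mm$reason,
      rows = list(vapply(mm$cells, function(c) as.integer(c$row), integer(1))),
      cols = list(vapply(mm$cells, function(c) as.integer(c$col), integer(1)))
    )
  }))
  g <- sheet_grid(matrix("", nrow = doc$grid$n_rows, ncol = doc$grid$n_cols))
  rep <- new_report(doc$format_name, g, msgs)
  rep
}

#' Write a report to disk as JSON or a plain-text table
#'
#' @param report A `sheet_report`.
#' @param path Output file path.
#' @param format `"json"` or `"text"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "text")) {
  format <- match.arg(format)
  if (format == "json") {
    writeLines(report_to_json(report), path)
  } else {
    txt <- utils::capture.output(print(report))
    writeLines(txt, path)
  }
  invisible(path)
}

#' Plot a validation report as a highlighted grid
#'
#' Mimics the highlighted-spreadsheet view: cells with at least one error are
#' red, cells with warnings only are yellow.
#'
#' @param object A `sheet_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sheet_report
#' @export
autoplot.sheet_report <- function(object, ...) {
  cells <- invalid_cells(object)
  base <- tidyr::expand_grid(row = seq_len(object$n_rows),
                             col = seq_len(object$n_cols)) |>
    dplyr::left_join(cells, by = c("row", "col")) |>
    dplyr::mutate(status = dplyr::coalesce(.data$status, "clean"))
  ggplot2::ggplot(base, ggplot2::aes(x = .data$col, y = .data$row,
                                     fill = .data$status)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(clean = "white", warning = "#f6e58d",
                                          error = "#e74c3c")) +
    ggplot2::labs(x = "column", y = "row",
                  title = paste("Validation:", object$format_name)) +
    ggplot2::theme_minimal()
}
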