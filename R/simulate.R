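#' Generate a valid simulated QIIME mapping sheet
#'
#' Produces 'typical' valid mapping-file data: unique sample identifiers,
#' unique DNA barcodes of a fixed length, one commonly used 16S linker primer
#' sequence shared by every row, several columns of unique values (simulating
#' continuous metadata), several columns holding a single constant value
#' (columns without variance) and a final Description column. The default
#' layout is sample id + barcode + primer + 10 unique-value columns + 10
#' constant columns + description = 24 columns. Validating the result with
#' the full [qiime_ruleset()] yields zero messages.
#'
#' @param n_rows Number of sample rows (the sheet gains one header row).
#' @param n_unique_cols,n_constant_cols Counts of unique-value and
#'   constant metadata columns.
#' @param barcode_length Fixed barcode length; the default 12 is the common
#'   Golay-style length in 16S studies. `n_rows` may not exceed the
#'   `4^barcode_length` distinct-barcode capacity.
#' @param primer The shared linker primer (default: the widely used 515F 16S
#'   primer, IUPAC code `M` included).
#' @param seed Integer seed; the same spec and seed always give an identical
#'   grid. The caller's RNG state is left untouched.
#' @return A [sheet_grid()] (tsv dialect) of `n_rows + 1` rows and
#'   `4 + n_unique_cols + n_constant_cols` columns.
#' @examples
#' g <- simulate_mapping_sheet(5, seed = 1)
#' glance(validate(g, qiime_ruleset()))
#' @export
simulate_mapping_sheet <- function(n_rows, n_unique_cols = 10,
                                   n_constant_cols = 10, barcode_length = 12,
                                   primer = "GTGCCAGCMGCCGCGGTAA", seed = 1) {
  stopifnot(n_rows >= 1, n_unique_cols >= 0, n_constant_cols >= 0,
            barcode_length >= 1)
  capacity <- 4^barcode_length
  if (n_rows > capacity) {
    stop(sprintf(
      "cannot draw %d unique barcodes of length %d (capacity %.0f); use barcode_length >= %d",
      n_rows, barcode_length, capacity, ceiling(log(n_rows) / log(4))),
      call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    sample_ids <- sprintf("sample.%d", seq_len(n_rows))
    barcodes <- draw_unique_barcodes(n_rows, barcode_length)
    uniq <- matrix("", n_rows, n_unique_cols)
    for (k in seq_len(n_unique_cols)) uniq[, k] <- draw_unique_numbers(n_rows)
    vocab <- c("stool", "gut", "skin", "soil", "tongue", "water", "control",
               "treatment", "baseline", "followup")
    const <- matrix("", n_rows, n_constant_cols)
    for (k in seq_len(n_constant_cols)) const[, k] <- rep(sample(vocab, 1), n_rows)
    header <- c("#SampleID", "BarcodeSequence", "LinkerPrimerSequence",
                sprintf("unique_meta%d", seq_len(n_unique_cols)),
                sprintf("constant_meta%d", seq_len(n_constant_cols)),
                "Description")
    data <- cbind(sample_ids, barcodes, rep(primer, n_rows), uniq, const,
                  rep("simulated sample", n_rows))
    cells <- rbind(header, data)
    dimnames(cells) <- NULL
    sheet_grid(cells, dialect = "tsv")
  })
}

draw_unique_barcodes <- function(n, len) {
  out <- character(0)
  while (length(out) < n) {
    k <- n - length(out)
    fresh <- apply(matrix(sample(c("A", "C", "G", "T"), k * len, replace = TRUE),
                          nrow = k), 1, paste, collapse = "")
    out <- unique(c(out, fresh))
  }
  out[seq_len(n)]
}

# continuous-looking metadata: fixed-point strings, redrawn until distinct
draw_unique_numbers <- function(n) {
  vals <- sprintf("%.4f", stats::runif(n, 0, 1000))
  while (anyDuplicated(vals)) {
    dup <- which(duplicated(vals))
    vals[dup] <- sprintf("%.4f", stats::runif(length(dup), 0, 1000))
  }
  vals
}

#' The error-injection operator vocabulary
#'
#' @return The three corruption operators the injector draws from:
#'   `"empty"` (make a cell empty), `"whitespace"` (introduce leading and/or
#'   trailing whitespace) and `"invalid_chars"` (introduce an invalid
#'   character).
#' @export
corruption_types <- function() c("empty", "whitespace", "invalid_chars")

# Characters guaranteed invalid everywhere: outside the free-text class, the
# DNA/IUPAC alphabets and the sample-id class, not whitespace, and never '#'
# (which could turn a first-column cell into a comment-row marker).
FORBIDDEN_CHARS <- c("$", "!", "?", "*", "&", "^", "~", "|", "@")

#' Inject random errors into a sheet with ground-truth logging
#'
#' Corrupts `round(error_rate * n_data_cells)` distinct, uniformly chosen
#' data cells (the header row is never corrupted). For each chosen cell one
#' of the three operators in [corruption_types()] is drawn uniformly:
#' emptying the cell, padding it with leading and/or trailing whitespace, or
#' inserting a character from a documented forbidden pool that no column
#' class accepts. Every corruption is detectable by construction (the
#' whitespace and invalid-character operators are only applied to non-empty
#' cells, falling back to the empty operator otherwise), and a corrupted
#' value can never collide with another cell's value, so the ground-truth
#' log is exact.
#'
#' @param grid A [sheet_grid()], normally a valid generated sheet.
#' @param error_rate Fraction of data cells to corrupt, in \[0, 1\].
#' @param seed Integer seed (deterministic; caller RNG untouched).
#' @return A list with elements `grid` (a new corrupted [sheet_grid()]; the
#'   input is not modified) and `records`, a tibble logging one row per
#'   corruption: `row`, `col`, `cell` (A1 label), `error_type`, `original`.
#' @examples
#' g <- simulate_mapping_sheet(10, seed = 1)
#' corr <- inject_errors(g, 0.05, seed = 2)
#' corr$records
#' @export
inject_errors <- function(grid, error_rate, seed = 1) {
  stopifnot(inherits(grid, "sheet_grid"))
  if (!is.numeric(error_rate) || length(error_rate) != 1L ||
      is.na(error_rate) || error_rate < 0 || error_rate > 1) {
    stop("error_rate must be a single number in [0, 1]", call. = FALSE)
  }
  n_data_rows <- max(0L, grid$n_rows - 1L)
  n_data <- n_data_rows * grid$n_cols
  n_corrupt <- round(error_rate * n_data)
  cells <- grid$cells
  if (n_corrupt == 0L) {
    return(list(grid = sheet_grid(cells, grid$dialect), records = empty_records()))
  }
  withr::with_seed(as.integer(seed), {
    picks <- sample.int(n_data, n_corrupt)
    rows <- ((picks - 1L) %/% grid$n_cols) + 2L
    cols <- ((picks - 1L) %% grid$n_cols) + 1L
    types <- sample(corruption_types(), n_corrupt, replace = TRUE)
    original <- cells[cbind(rows, cols)]
    # operators must be no-op-free: only the empty operator applies to an
    # already-empty cell
    types[original == "" | trimws(original) == ""] <- "empty"
    new_vals <- character(n_corrupt)
    for (i in seq_len(n_corrupt)) {
      new_vals[i] <- switch(types[i],
        empty = "",
        whitespace = pad_whitespace(original[i]),
        invalid_chars = insert_forbidden(original[i])
      )
    }
    cells[cbind(rows, cols)] <- new_vals
    records <- tibble::tibble(
      row = as.integer(rows), col = as.integer(cols),
      cell = address_to_a1(rows, cols), error_type = types, original = original
    ) |> dplyr::arrange(.data$row, .data$col)
    list(grid = sheet_grid(cells, grid$dialect), records = records)
  })
}

empty_records <- function() {
  tibble::tibble(row = integer(0), col = integer(0), cell = character(0),
                 error_type = character(0), original = character(0))
}

pad_whitespace <- function(value) {
  switch(sample(c("leading", "trailing", "both"), 1),
         leading = paste0(" ", value),
         trailing = paste0(value, " "),
         both = paste0(" ", value, " "))
}

insert_forbidden <- function(value) {
  ch <- sample(FORBIDDEN_CHARS, 1)
  pos <- sample.int(nchar(value) + 1L, 1) - 1L # insert after position `pos`
  paste0(substr(value, 1, pos), ch, substr(value, pos + 1L, nchar(value)))
}

#' Write a corruption log as JSON
#'
#' @param records The `records` tibble from [inject_errors()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corruption_log <- function(records, path) {
  writeLines(as.character(jsonlite::toJSON(records, dataframe = "rows",
                                           auto_unbox = TRUE, pretty = TRUE)),
             path)
  invisible(path)
}
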