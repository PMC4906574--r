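#' Construct a sheet grid
#'
#' A `sheet_grid` is a rectangular grid of raw text cells, the in-memory
#' stand-in for a spreadsheet. Values are stored verbatim: no trimming, no
#' type coercion, so whitespace rules see the original text. Row 1 is the
#' header row.
#'
#' @param cells A character matrix (row-major grid of raw cell text).
#' @param dialect `"tsv"` or `"csv"`; the delimiter convention the grid was
#'   (or will be) serialised with.
#' @return A `sheet_grid` object.
#' @export
sheet_grid <- function(cells, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (is.null(dim(cells))) cells <- matrix(cells, nrow = NROW(cells))
  if (!is.character(cells)) storage.mode(cells) <- "character"
  cells[is.na(cells)] <- ""
  structure(
    list(cells = cells, n_rows = nrow(cells), n_cols = ncol(cells),
         dialect = dialect),
    class = "sheet_grid"
  )
}

#' @export
dim.sheet_grid <- function(x) c(x$n_rows, x$n_cols)

#' @export
as.matrix.sheet_grid <- function(x, ...) x$cells

#' @export
print.sheet_grid <- function(x, ...) {
  cat(sprintf("<sheet_grid: %d rows x %d cols, dialect %s>\n",
              x$n_rows, x$n_cols, x$dialect))
  if (x$n_rows > 0L) {
    nr <- min(x$n_rows, 6L)
    nc <- min(x$n_cols, 6L)
    preview <- x$cells[seq_len(nr), seq_len(nc), drop = FALSE]
    dimnames(preview) <- list(seq_len(nr), vapply(seq_len(nc), col_to_letters, ""))
    print(preview, quote = TRUE)
    if (nr < x$n_rows || nc < x$n_cols) cat("...\n")
  }
  invisible(x)
}

#' Parse delimited text into a sheet grid
#'
#' Two dialects are supported. `"tsv"` follows the QIIME mapping-file
#' convention: tabs are hard delimiters and there is no quoting. `"csv"`
#' follows standard CSV quoting rules (RFC 4180): fields may be wrapped in
#' double quotes, embedded quotes are doubled, and quoted fields may contain
#' commas and newlines.
#'
#' Short rows are padded with empty strings so the grid is rectangular —
#' real exported sheets are ragged, and a validator must still be able to
#' address every cell. Rows that are entirely empty at the bottom of the
#' file are dropped (they are file artifacts); interior blank rows are kept
#' because they are validatable content.
#'
#' @param text A single string (the file contents) or a character vector of
#'   lines. Must be valid UTF-8.
#' @param dialect `"tsv"` or `"csv"`.
#' @return A [sheet_grid()].
#' @examples
#' parse_delimited("a\tb\nc\td\n", "tsv")
#' parse_delimited("a,\"b,c\"\n", "csv")
#' @export
parse_delimited <- function(text, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (length(text) > 1L) text <- paste(text, collapse = "\n")
  if (length(text) == 0L || is.na(text)) text <- ""
  if (!all(validUTF8(text))) {
    stop(sprintf("input is not valid UTF-8 (first invalid byte at offset %d)",
                 first_invalid_utf8_byte(charToRaw(text))), call. = FALSE)
  }
  rows <- if (dialect == "tsv") split_tsv(text) else split_csv(text)
  if (length(rows) == 0L) {
    return(sheet_grid(matrix(character(0), nrow = 0, ncol = 0), dialect))
  }
  n_cols <- max(vapply(rows, length, integer(1)))
  cells <- matrix("", nrow = length(rows), ncol = n_cols)
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r)) cells[i, seq_along(r)] <- r
  }
  # drop trailing all-empty rows; interior blanks stay
  keep <- max(c(0L, which(apply(cells != "", 1, any))))
  cells <- cells[seq_len(keep), , drop = FALSE]
  if (keep == 0L) cells <- matrix(character(0), nrow = 0, ncol = 0)
  sheet_grid(cells, dialect)
}

split_tsv <- function(text) {
  lines <- strsplit(gsub("\r\n", "\n", text, fixed = TRUE), "\n", fixed = TRUE)[[1]]
  if (length(lines) == 0L) return(list())
  # strsplit drops trailing empty fields, so track the true field count
  nf <- stringr::str_count(lines, stringr::fixed("\t")) + 1L
  fields <- strsplit(lines, "\t", fixed = TRUE)
  lapply(seq_along(lines), function(i) {
    f <- fields[[i]]
    if (length(f) < nf[i]) f <- c(f, rep("", nf[i] - length(f)))
    f
  })
}

# Minimal RFC 4180 tokenizer. Kept explicit (rather than read.csv/readr)
# because cells must survive verbatim: no whitespace trimming, no NA
# coercion, and over-wide rows widen the grid instead of wrapping.
split_csv <- function(text) {
  chs <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chs)
  rows <- list()
  field <- character(0)
  row <- character(0)
  buf <- character(0)
  in_quotes <- FALSE
  i <- 1L
  flush_field <- function() {
    row[[length(row) + 1L]] <<- paste(buf, collapse = "")
    buf <<- character(0)
  }
  flush_row <- function() {
    flush_field()
    rows[[length(rows) + 1L]] <<- row
    row <<- character(0)
  }
  any_content <- FALSE
  while (i <= n) {
    ch <- chs[i]
    if (in_quotes) {
      if (ch == "\"") {
        if (i < n && chs[i + 1L] == "\"") {
          buf[length(buf) + 1L] <- "\""
          i <- i + 1L
        } else {
          in_quotes <- FALSE
        }
      } else {
        buf[length(buf) + 1L] <- ch
      }
    } else if (ch == "\"") {
      in_quotes <- TRUE
    } else if (ch == ",") {
      flush_field()
    } else if (ch == "\n" || ch == "\r") {
      if (ch == "\r" && i < n && chs[i + 1L] == "\n") i <- i + 1L
      flush_row()
      any_content <- FALSE
    } else {
      buf[length(buf) + 1L] <- ch
    }
    if (!ch %in% c("\n", "\r")) any_content <- TRUE
    i <- i + 1L
  }
  if (any_content || length(row) > 0L) flush_row()
  rows
}

# Scan raw bytes with the standard UTF-8 state machine; return the 1-based
# offset of the first byte that cannot start or continue a valid sequence.
first_invalid_utf8_byte <- function(raw) {
  i <- 1L
  n <- length(raw)
  while (i <= n) {
    b <- as.integer(raw[i])
    need <- if (b < 0x80) 0L
    else if (b >= 0xC2 && b <= 0xDF) 1L
    else if (b >= 0xE0 && b <= 0xEF) 2L
    else if (b >= 0xF0 && b <= 0xF4) 3L
    else return(i)
    if (i + need > n) return(i + 1L)
    if (need > 0L) {
      cont <- as.integer(raw[(i + 1L):(i + need)])
      bad <- which(cont < 0x80 | cont > 0xBF)
      if (length(bad)) return(i + bad[1])
    }
    i <- i + need + 1L
  }
  NA_integer_
}

#' Read a delimited file into a sheet grid
#'
#' @param path Path to a TSV or CSV file.
#' @param dialect `"tsv"` or `"csv"`; if `NULL`, inferred from the file
#'   extension (`.csv` means csv, anything else tsv).
#' @return A [sheet_grid()].
#' @export
read_sheet <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  raw <- readBin(path, "raw", n = file.size(path))
  txt <- rawToChar(raw)
  if (!validUTF8(txt)) {
    stop(sprintf("%s is not valid UTF-8 (first invalid byte at offset %d)",
                 path, first_invalid_utf8_byte(raw)), call. = FALSE)
  }
  Encoding(txt) <- "UTF-8"
  parse_delimited(txt, dialect)
}

#' Serialise a sheet grid back to delimited text
#'
#' @param grid A [sheet_grid()].
#' @param path Optional file path; if `NULL` the text is returned instead.
#' @param dialect Delimiter convention; defaults to the grid's own dialect.
#' @return The serialised text (invisibly when written to a file).
#' @export
write_sheet <- function(grid, path = NULL, dialect = NULL) {
  stopifnot(inherits(grid, "sheet_grid"))
  dialect <- dialect %||% grid$dialect
  cells <- grid$cells
  if (dialect == "tsv") {
    if (any(grepl("[\t\n\r]", cells))) {
      stop("tsv dialect cannot represent cells containing tabs or newlines",
           call. = FALSE)
    }
    lines <- apply(cells, 1, paste, collapse = "\t")
  } else {
    quoted <- cells
    needs <- grepl("[\",\n\r]", cells)
    quoted[needs] <- paste0("\"", gsub("\"", "\"\"", cells[needs]), "\"")
    lines <- apply(quoted, 1, paste, collapse = ",")
  }
  txt <- if (grid$n_rows == 0L) "" else paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(path)) return(txt)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(enc2utf8(txt)), con)
  invisible(txt)
}
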