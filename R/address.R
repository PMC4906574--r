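#' Convert row/column positions to A1 notation
#'
#' Spreadsheet A1 notation combines bijective base-26 column letters
#' (A = 1, ..., Z = 26, AA = 27, ...) with a 1-based row number, so the
#' 15th column of row 46 is `"O46"`.
#'
#' @param row,col Positive integer vectors (recycled to a common length).
#'   Row 1 is the header row; column 1 is column A.
#' @return A character vector of A1 labels.
#' @examples
#' address_to_a1(46, 15) # "O46"
#' address_to_a1(3, 28)  # "AB3"
#' @seealso [a1_to_address()] for the inverse.
#' @export
address_to_a1 <- function(row, col) {
  row <- as.integer(row)
  col <- as.integer(col)
  if (length(row) != length(col)) {
    n <- max(length(row), length(col))
    row <- rep_len(row, n)
    col <- rep_len(col, n)
  }
  if (any(is.na(row) | is.na(col)) || any(row < 1L) || any(col < 1L)) {
    stop("cell addresses must have row >= 1 and column >= 1", call. = FALSE)
  }
  paste0(vapply(col, col_to_letters, character(1)), row)
}

# bijective base 26: there is no zero digit, hence the (n - 1) offsets
col_to_letters <- function(n) {
  out <- character(0)
  while (n > 0L) {
    r <- (n - 1L) %% 26L
    out <- c(LETTERS[r + 1L], out)
    n <- (n - 1L) %/% 26L
  }
  paste(out, collapse = "")
}

letters_to_col <- function(s) {
  idx <- match(strsplit(s, "")[[1]], LETTERS)
  sum(idx * 26^(rev(seq_along(idx)) - 1))
}

#' Parse A1 cell labels into row/column positions
#'
#' @param label Character vector of A1 labels such as `"A3"` or `"O46"`.
#'   Lowercase column letters are accepted.
#' @return A tibble with integer columns `row` and `col`, one row per label.
#' @examples
#' a1_to_address(c("A3", "O46", "AB3"))
#' @export
a1_to_address <- function(label) {
  label <- toupper(as.character(label))
  m <- regmatches(label, regexec("^([A-Z]+)([0-9]+)$", label))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop(
      "malformed A1 label(s): ",
      paste(sQuote(label[bad], q = FALSE), collapse = ", "),
      " (expected column letters followed by a row number)",
      call. = FALSE
    )
  }
  row <- vapply(m, function(x) as.integer(x[3]), integer(1))
  col <- vapply(m, function(x) as.integer(letters_to_col(x[2])), integer(1))
  if (any(row < 1L)) {
    stop("malformed A1 label(s): row numbers start at 1", call. = FALSE)
  }
  tibble::tibble(row = row, col = col)
}

# Normalise a user-supplied cell reference (A1 string or c(row, col))
# to a length-2 integer vector.
as_address <- function(cell) {
  if (is.character(cell)) {
    if (length(cell) != 1L) stop("supply a single cell reference", call. = FALSE)
    a <- a1_to_address(cell)
    return(c(a$row, a$col))
  }
  cell <- as.integer(cell)
  if (length(cell) != 2L || any(is.na(cell)) || any(cell < 1L)) {
    stop("cell reference must be an A1 label or c(row, col)", call. = FALSE)
  }
  cell
}
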