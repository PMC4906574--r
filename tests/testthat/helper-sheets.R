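# Fixture builders: minimal valid QIIME mapping grids built in code.

barcode_pool <- function(n, len = 4) {
  pool <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), len),
                            stringsAsFactors = FALSE),
                1, paste, collapse = "")
  pool[seq_len(n)]
}

qiime_fixture <- function(ids, barcodes = NULL, primer = "GTGCCAGCMGCCGCGGTAA",
                          description = "a sample", extra = NULL) {
  n <- length(ids)
  if (is.null(barcodes)) barcodes <- barcode_pool(n)
  data <- cbind(ids, barcodes, rep(primer, n))
  header <- c("#SampleID", "BarcodeSequence", "LinkerPrimerSequence")
  if (!is.null(extra)) { # named list of extra columns
    for (nm in names(extra)) {
      data <- cbind(data, extra[[nm]])
      header <- c(header, nm)
    }
  }
  data <- cbind(data, rep(description, n))
  cells <- rbind(c(header, "Description"), data)
  dimnames(cells) <- NULL
  sheet_grid(cells, dialect = "tsv")
}

srgd_fixture <- function(ids, datetimes = NULL, lat = NULL, lon = NULL) {
  n <- length(ids)
  cells <- rbind(
    c("Individual_ID", "Date_Time", "Latitude", "Longitude"),
    cbind(ids,
          datetimes %||% rep("2008-06-15 10:06:17", n),
          lat %||% rep("35.19", n),
          lon %||% rep("-111.65", n))
  )
  dimnames(cells) <- NULL
  sheet_grid(cells, dialect = "csv")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

flagged_keys <- function(report) {
  ic <- invalid_cells(report)
  paste(ic$row, ic$col)
}

record_keys <- function(records) paste(records$row, records$col)

quiet_cli <- function(args) {
  st <- NULL
  invisible(utils::capture.output(st <- suppressMessages(cli_main(args))))
  st
}
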