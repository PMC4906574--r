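test_that("the QIIME rule set carries the documented rules and severities", {
  rs <- qiime_ruleset()
  sev <- vapply(rs$rules, `[[`, character(1), "severity")
  expect_equal(unname(sev[c("header_first_sampleid", "header_last_description",
                            "header_duplicates", "sampleid_nonempty",
                            "sampleid_characters", "sampleid_unique",
                            "barcode_characters", "barcode_uniform_length",
                            "barcode_unique", "primer_characters")]),
               rep("error", 10))
  expect_equal(unname(sev[c("cell_empty", "cell_leading_trailing_whitespace",
                            "cell_invalid_characters")]),
               rep("warning", 3))
})

test_that("header position and duplication rules fire on malformed headers", {
  cells <- rbind(c("SampleID", "BarcodeSequence", "LinkerPrimerSequence",
                   "BarcodeSequence", "Notes"),
                 c("s1", "ACGT", "ACGT", "TGCA", "x"))
  report <- validate(sheet_grid(cells), qiime_ruleset())
  td <- tidy(report)
  expect_true(all(c("header_first_sampleid", "header_last_description",
                    "header_duplicates") %in% td$rule_id))
  dup <- report$messages[report$messages$rule_id == "header_duplicates", ]
  expect_equal(dup$cells[[1]], c("B1", "D1"))
})

test_that("sample identifiers allow only alphanumerics and period", {
  g <- qiime_fixture(c("ok.id1", "bad_id", "bad id"))
  td <- tidy(validate(g, qiime_ruleset()))
  chars <- td[td$rule_id == "sampleid_characters", ]
  expect_equal(chars$cell, c("A3", "A4"))
  expect_match(chars$reason[1], "'_'")
  expect_match(chars$reason[2], "space")
})

test_that("barcode rules flag non-ACGT characters, length outliers and duplicates", {
  g <- qiime_fixture(c("s1", "s2", "s3", "s4", "s5"),
                     barcodes = c("ACGT", "ACXT", "ACG", "GGTT", "GGTT"))
  td <- tidy(validate(g, qiime_ruleset()))
  expect_match(td$reason[td$rule_id == "barcode_characters"], "'X'")
  # modal-length oracle: lengths 4,4,3,4,4 -> mode 4, only the length-3 cell flagged
  lens <- nchar(c("ACGT", "ACXT", "ACG", "GGTT", "GGTT"))
  modal <- as.integer(names(which.max(table(lens))))
  expect_equal(td$cell[td$rule_id == "barcode_uniform_length"],
               address_to_a1(1 + which(lens != modal), 2))
  dup <- td[td$rule_id == "barcode_unique", ]
  expect_equal(dup$cell, c("B5", "B6"))
})

test_that("a modal-length tie breaks toward the smaller length", {
  g <- qiime_fixture(c("s1", "s2", "s3", "s4"),
                     barcodes = c("ACG", "TGA", "ACGT", "TGCA"))
  td <- tidy(validate(g, qiime_ruleset()))
  expect_equal(td$cell[td$rule_id == "barcode_uniform_length"], c("B4", "B5"))
})

test_that("lowercase nucleotides are accepted in barcodes and primers", {
  g <- qiime_fixture(c("s1", "s2"), barcodes = c("acgt", "TGCA"),
                     primer = "gtgccagcMgccgcggtaa")
  td <- tidy(validate(g, qiime_ruleset()))
  expect_false(any(td$rule_id %in% c("barcode_characters", "primer_characters")))
})

test_that("primer cells validate comma-separated IUPAC components", {
  # per-character membership oracle over the IUPAC alphabet
  iupac <- strsplit("ACGTRYSWKMBDHVN", "")[[1]]
  ok <- function(s) all(strsplit(toupper(s), "")[[1]] %in% iupac)
  expect_true(ok("GTGCCAGCMGCCGCGGTAA"))
  expect_true(all(vapply(c("ACGT", "ANNT"), ok, logical(1))))

  g <- qiime_fixture(c("s1", "s2", "s3"),
                     primer = "GTGCCAGCMGCCGCGGTAA")
  g$cells[3, 3] <- "ACGT,ANNT"
  g$cells[4, 3] <- "ACGT,,A1"
  report <- validate(g, qiime_ruleset())
  primer_msgs <- report$messages[report$messages$rule_id == "primer_characters", ]
  expect_equal(unlist(primer_msgs$cells), c("C4", "C4"))
  expect_match(primer_msgs$reason[1], "empty primer component")
  expect_match(primer_msgs$reason[2], "'1'")
})

test_that("generic cell rules flag empties, padding and out-of-class characters", {
  g <- qiime_fixture(c("s1", "s2", "s3"),
                     extra = list(meta = c("", " ok", "a$b")))
  td <- tidy(validate(g, qiime_ruleset()))
  meta <- td[td$col == 4, ]
  expect_equal(meta$rule_id[meta$row == 2], "cell_empty")
  expect_equal(meta$rule_id[meta$row == 3], "cell_leading_trailing_whitespace")
  expect_equal(meta$rule_id[meta$row == 4], "cell_invalid_characters")
  expect_match(meta$reason[meta$row == 4], "\\'\\$\\'")
  expect_true(all(td$severity[td$col == 4] == "warning"))
})

test_that("comment rows after the header are excluded unless asked otherwise", {
  g <- qiime_fixture(c("s1", "s2"))
  cells <- rbind(g$cells[1:2, ], c("#a comment row", "", "", ""), g$cells[3, ])
  g2 <- sheet_grid(cells)
  expect_equal(nrow(validate(g2, qiime_ruleset())$messages), 0L)
  with_comments <- validate(g2, qiime_ruleset(exclude_comment_rows = FALSE))
  expect_gt(nrow(with_comments$messages), 0L)
})

test_that("QIIME mode places no datetime restriction on metadata columns", {
  g <- qiime_fixture(c("s1", "s2"),
                     extra = list(Date_Time = c("2008-06-15 10:06:17",
                                                "2008-13-01 00:00:00")))
  expect_equal(nrow(validate(g, qiime_ruleset())$messages), 0L)
})
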