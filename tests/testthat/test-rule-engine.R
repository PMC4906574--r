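test_that("duplicate sample identifiers are flagged as one linked message", {
  g <- qiime_fixture(c("s1", "dup", "s3", "dup"))
  report <- validate(g, qiime_ruleset())
  dup <- report$messages[report$messages$rule_id == "sampleid_unique", ]
  expect_equal(nrow(dup), 1L)
  expect_equal(dup$severity, "error")
  expect_equal(dup$cells[[1]], c("A3", "A5"))
  # the per-cell index fans the linked finding out to both members
  expect_equal(messages_for_cell(report, "A3")$rule_id, "sampleid_unique")
  expect_equal(messages_for_cell(report, "A5")$reason,
               messages_for_cell(report, "A3")$reason)
})

test_that("cell status ranks error over warning and clean cells return no messages", {
  g <- qiime_fixture(c(" s1", "s2")) # leading space: character error + whitespace warning
  report <- validate(g, qiime_ruleset())
  m <- messages_for_cell(report, "A2")
  expect_setequal(m$rule_id, c("sampleid_characters",
                               "cell_leading_trailing_whitespace"))
  expect_equal(cell_status(report, "A2"), "error")
  expect_equal(cell_status(report, "A3"), "clean")
  expect_equal(nrow(messages_for_cell(report, "A3")), 0L)
  # warnings-only cell
  g2 <- qiime_fixture(c("s1", "s2"), extra = list(x = c("ok", " pad ")))
  r2 <- validate(g2, qiime_ruleset())
  expect_equal(cell_status(r2, c(3, 4)), "warning")
  expect_error(cell_status(report, "Z99"), "outside")
})

test_that("configure disables rules and overrides severity without other effects", {
  g <- qiime_fixture(c("s1", "s2"), barcodes = c("ACGT", "ACGT"))
  rs <- qiime_ruleset()
  base <- validate(g, rs)
  expect_equal(base$messages$rule_id, "barcode_unique")

  off <- validate(g, configure(rs, disable = "barcode_unique"))
  expect_equal(nrow(off$messages), 0L)

  demoted <- validate(g, configure(rs, list(barcode_unique = "warning")))
  expect_equal(demoted$messages$cells, base$messages$cells)
  expect_equal(demoted$messages$reason, base$messages$reason)
  expect_equal(demoted$messages$severity, "warning")
  expect_equal(glance(demoted)$n_warning_only_cells, 2L)

  # identity and error paths
  expect_identical(validate(g, configure(rs))$messages, base$messages)
  expect_error(configure(rs, list(frob = "disabled")), "valid ids are")
  expect_error(configure(rs, list(barcode_unique = "loud")), "must be")
})

test_that("disabling all rules yields an empty report; empty grids report no content", {
  g <- qiime_fixture(c(" bad$", ""))
  rs <- qiime_ruleset()
  all_off <- configure(rs, stats::setNames(as.list(rep("disabled", length(rule_ids(rs)))),
                                           rule_ids(rs)))
  expect_equal(nrow(validate(g, all_off)$messages), 0L)

  empty <- validate(parse_delimited("", "tsv"), rs)
  expect_equal(empty$messages$rule_id, "no_content")
  expect_equal(empty$messages$severity, "error")
})

test_that("a missing required header becomes a sheet-scope error, not a crash", {
  cells <- rbind(c("#SampleID", "LinkerPrimerSequence", "Description"),
                 c("s1", "ACGT", "x"))
  report <- validate(sheet_grid(cells), qiime_ruleset())
  miss <- report$messages[report$messages$rule_id == "missing_column", ]
  expect_equal(nrow(miss), 1L)
  expect_match(miss$reason, "BarcodeSequence")
  expect_equal(miss$cells[[1]], "A1")
  # no barcode rule output, and nothing crashed
  expect_false(any(grepl("^barcode", report$messages$rule_id)))
})

test_that("message order is rule order then row-major address order", {
  g <- qiime_fixture(c("s1", "s2", "s3"),
                     extra = list(m1 = c("x", " y", ""), m2 = c("", "z", " w")))
  report <- validate(g, qiime_ruleset())
  td <- tidy(report)
  rule_order <- match(td$rule_id, rule_ids(qiime_ruleset()))
  expect_true(all(diff(rule_order) >= 0))
  for (rid in unique(td$rule_id)) {
    sub <- td[td$rule_id == rid, ]
    key <- (sub$row - 1) * report$n_cols + sub$col
    expect_true(all(diff(key) > 0))
  }
})

test_that("reports are deterministic and the summary re-derives from messages", {
  g <- inject_errors(simulate_mapping_sheet(40, seed = 5), 0.2, seed = 6)$grid
  rs <- qiime_ruleset()
  r1 <- validate(g, rs)
  r2 <- validate(g, rs)
  expect_identical(tidy(r1), tidy(r2))
  expect_identical(glance(r1), glance(r2))

  td <- tidy(r1)
  cells <- unique(paste(td$row, td$col))
  err_cells <- unique(paste(td$row, td$col)[td$severity == "error"])
  expect_equal(r1$summary$n_invalid_cells, length(cells))
  expect_equal(r1$summary$n_error_cells, length(err_cells))
  expect_equal(r1$summary$n_warning_only_cells, length(setdiff(cells, err_cells)))
  expect_equal(r1$summary$n_messages, nrow(r1$messages))
  expect_equal(as.integer(table(r1$messages$rule_id)[names(r1$summary$messages_per_rule)]),
               unname(r1$summary$messages_per_rule))
})

test_that("findings are the union of independent single-rule runs", {
  rs <- qiime_ruleset()
  ids <- rule_ids(rs)
  for (seed in 1:5) {
    g <- inject_errors(simulate_mapping_sheet(25, seed = seed), 0.15,
                       seed = seed + 100)$grid
    full <- tidy(validate(g, rs))[, c("rule_id", "severity", "reason", "row", "col")]
    single <- dplyr::bind_rows(lapply(ids, function(keep) {
      solo <- configure(rs, stats::setNames(as.list(rep("disabled", length(ids) - 1)),
                                            setdiff(ids, keep)))
      tidy(validate(g, solo))[, c("rule_id", "severity", "reason", "row", "col")]
    }))
    ord <- function(d) d[order(d$rule_id, d$row, d$col, d$reason), ]
    expect_equal(ord(single), ord(full), ignore_attr = TRUE)
  }
})

test_that("disabling a rule never increases the invalid-cell count", {
  g <- inject_errors(simulate_mapping_sheet(30, seed = 9), 0.2, seed = 10)$grid
  rs <- qiime_ruleset()
  full_n <- glance(validate(g, rs))$n_invalid_cells
  for (rid in rule_ids(rs)) {
    n <- glance(validate(g, configure(rs, disable = rid)))$n_invalid_cells
    expect_lte(n, full_n)
  }
})

test_that("JSON report export round-trips all fields", {
  g <- qiime_fixture(c("dup", "dup", " s3"), extra = list(m = c("", "x", "y$")))
  report <- validate(g, qiime_ruleset())
  back <- report_from_json(report_to_json(report))
  expect_equal(back$format_name, report$format_name)
  expect_equal(tidy(back), tidy(report))
  expect_equal(glance(back), glance(report))
  expect_equal(back$summary, report$summary)
  # and via a file
  f <- tempfile(fileext = ".json")
  write_report(report, f, "json")
  expect_equal(tidy(report_from_json(f)), tidy(report))
})

test_that("custom rule sets load from YAML and JSON with load errors located", {
  yml <- tempfile(fileext = ".yml")
  writeLines(c(
    "format_name: my format",
    "dialect: csv",
    "rules:",
    "- check: unique-values-in-column",
    "  column: ID",
    "  id: id_unique"
  ), yml)
  rs <- load_ruleset(yml)
  expect_equal(rs$format_name, "my format")
  cells <- rbind(c("ID", "x"), c("a", "1"), c("b", "2"), c("a", "3"))
  report <- validate(sheet_grid(cells, "csv"), rs)
  # brute-force duplicate scan oracle
  ids <- cells[-1, 1]
  dup_rows <- which(ids %in% ids[duplicated(ids)]) + 1L
  expect_equal(sort(tidy(report)$row), sort(dup_rows))
  expect_equal(unique(tidy(report)$col), 1L)

  jsn <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(
    format_name = "j", dialect = "csv",
    rules = list(list(check = "numeric-range", column = "x", min = 0, max = 1))
  ), auto_unbox = TRUE), jsn)
  rsj <- load_ruleset(jsn)
  rj <- validate(sheet_grid(rbind(c("ID", "x"), c("a", "2")), "csv"), rsj)
  expect_match(tidy(rj)$reason, "outside the allowed range")

  empty <- tempfile(fileext = ".yml")
  writeLines(c("format_name: none", "dialect: tsv", "rules: []"), empty)
  expect_equal(nrow(validate(qiime_fixture("s1"), load_ruleset(empty))$messages), 0L)

  bad <- tempfile(fileext = ".yml")
  writeLines(c("format_name: bad", "dialect: tsv", "rules:",
               "- check: unique-values-in-column", "  column: ID",
               "- check: frobnicate", "  column: ID"), bad)
  expect_error(load_ruleset(bad), "unknown primitive 'frobnicate' at rules\\[2\\]")

  missing_param <- tempfile(fileext = ".yml")
  writeLines(c("format_name: bad", "dialect: tsv", "rules:",
               "- check: character-class", "  column: ID"), missing_param)
  expect_error(load_ruleset(missing_param), "missing parameter 'characters'")
})
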