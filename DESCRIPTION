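Package: sheetlint
Title: Cell-Level Validation of Tabular Bioinformatics Metadata Files
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A rule engine for validating tabular bioinformatics files
    cell by cell, reporting errors and warnings with spreadsheet-style A1
    cell addresses. Ships built-in rule sets for the QIIME sample metadata
    mapping file format (TSV) and the Spatially Referenced Genetic Data
    (SRGD) CSV format, supports user-defined formats declared in YAML or
    JSON from a closed vocabulary of primitive checks, and lets users tune
    validation stringency by disabling rules or overriding severities.
    Includes a seeded generator of realistic valid QIIME mapping sheets,
    a ground-truth-logged error injector, and scaling benchmarks for
    validation runtime versus sheet size and rule count.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
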