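---
title: "Cell-level validation of tabular metadata: model, rules and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-level validation of tabular metadata: model, rules and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sheetlint)
```

## The validation model

`sheetlint` treats a delimited file as a rectangular grid of raw text cells
(`sheet_grid`). Values are stored verbatim — no trimming, no type coercion —
because several rules (leading/trailing whitespace, empty cells) are defined
on the original text. Row 1 is the header; every other row is data. Short
rows are padded to the grid width rather than rejected, since real exported
sheets are ragged and a validator must still address every cell. Trailing
all-empty rows are dropped as file artifacts; *interior* blank rows are kept
because they are content a user can be warned about (this is a documented
choice of ours — spreadsheet tools differ here).

A *format* is an ordered `ruleset` of named, independent, pure rules. Each
rule declares a scope (cell, column or sheet), a column selector, a default
severity and a check returning zero or more *findings*: one reason attached
to one or more cell addresses. Linked problems — a group of duplicate sample
identifiers — are one multi-address message; the per-cell index fans it out,
so clicking either member shows the same reason. A cell's status is its
highest-severity finding: error outranks warning.

Because rules are pure and independent, two useful properties hold and are
asserted in the test suite:

* **determinism** — identical grid and rule set give field-identical
  reports; message order is rule order, then row-major address order;
* **union** — the full report equals the union of single-rule runs, so
  disabling a rule never changes other rules' findings, and rule-count
  scaling benchmarks measure a fixed per-rule cost.

Stringency is configured per run with `configure()`: any rule can be
disabled or have its severity overridden, and the same overrides can be
loaded from a YAML/JSON document. Severity is a property of the rule (with
per-run override), not of the finding, which is what makes this
configuration well-defined.

### Error contracts

An empty grid yields a single sheet-scope `no_content` error. A rule set
naming a required header that the grid lacks yields one `missing_column`
error per missing header and the dependent column rules are skipped. Both
sheet-scope messages are anchored at cell A1 so every message keeps a
non-empty address set.

## The QIIME mapping-file format

`qiime_ruleset()` (TSV dialect: hard tab delimiters, no quoting) checks:

| rule id | severity | check |
|---|---|---|
| `header_first_sampleid` | error | first header cell is `#SampleID` |
| `header_last_description` | error | last header cell is `Description` |
| `header_duplicates` | error | header names unique |
| `sampleid_nonempty` | error | sample ids present |
| `sampleid_characters` | error | ids use alphanumerics and `.` only |
| `sampleid_unique` | error | ids unique |
| `barcode_characters` | error | barcodes over `A C G T` |
| `barcode_uniform_length` | error | barcodes share one length |
| `barcode_unique` | error | barcodes unique |
| `primer_characters` | error | primer components non-empty, IUPAC codes |
| `cell_empty` | warning | any empty/whitespace-only data cell |
| `cell_leading_trailing_whitespace` | warning | cell differs from trimmed self |
| `cell_invalid_characters` | warning | characters outside the free-text class |

Choices worth stating explicitly, all configurable:

* The positional header layout follows the QIIME mapping-file specification.
* The default free-text class is alphanumerics, space and `+ - % . / : , ; _ =`.
  There is no authoritative published class for QIIME-era metadata, so ours
  is a documented default chosen to match common conventions; the simulator
  draws its "invalid characters" from *outside* this class so the detection
  tests do not depend on its exact boundary.
* Barcode length is checked against the modal length of the column; a
  frequency tie breaks toward the smaller length (deterministic).
* Nucleotides are case-insensitive: barcodes and primers are uppercased
  before membership tests.
* Rows after the header whose first cell starts with `#` are QIIME comment
  rows, excluded from data rules (`exclude_comment_rows = FALSE` disables
  this).
* Uniqueness rules skip empty values — missing is not duplicate; emptiness
  is flagged by the non-empty rules instead.
* QIIME mode validates only against the file-format specification: it has no
  datetime rule, so an impossible timestamp in a `Date_Time` metadata column
  passes QIIME validation but fails SRGD validation of the same grid. We
  count warning-only cells in the "invalid cells" summary (they are
  highlighted content), with errors and warnings partitioned in `glance()`.

## The SRGD format

`srgd_ruleset()` (CSV dialect, standard quoting) checks a required,
unique record-identifier column, calendar-aware `Date_Time` values,
`Latitude` in [-90, 90] and `Longitude` in [-180, 180] (closed intervals),
plus the generic empty/whitespace warnings. Only the datetime requirement is
pinned down by the format's published contrast with QIIME validation; the
column inventory (`Individual_ID`, `Date_Time`, `Latitude`, `Longitude`) is
a reconstructed default following SRGD.csv usage in the geneGIS/Wildbook
ecosystem — every column name is a parameter and every rule can be disabled.
Missing optional columns are not findings; a missing identifier column is a
sheet-scope error.

`datetime_spec()` defines the strict template: `%Y-%m-%d %H:%M:%S` by
default, zero-padded fixed-width fields, calendar-aware (Feb 30 and month 13
are rejected; leap years handled by the Gregorian rule). Two deliberate
strictnesses: hour 24 and leap-second 60 are rejected even though glibc's
`strptime` tolerates them, and any value the validator accepts re-renders to
the identical text (asserted as a property test), so accepted data is
canonical as-is.

## The simulator and error injector

`simulate_mapping_sheet()` emulates typical valid mapping data: unique
sample identifiers, unique random barcodes of fixed length 12 (the common
Golay-style length; capacity `4^12` is checked), one shared 16S linker
primer (`GTGCCAGCMGCCGCGGTAA`, degenerate code M included), 10 columns of
unique continuous-looking values, 10 constant columns and a Description
column — 24 columns total, the geometry used throughout the benchmarks. The
exact split of unique versus constant metadata columns is our default (it is
not externally fixed) and is a parameter.

`inject_errors()` corrupts `round(rate * n_data_cells)` distinct uniformly
chosen data cells — we define "error rate" as the fraction of data cells
corrupted, one operator per cell — drawing uniformly from three operators:
empty the cell, pad with leading and/or trailing whitespace, insert one
character from a documented forbidden pool. The header row is never
corrupted. Corruptions are detectable *by construction*:

* the whitespace and invalid-character operators apply only to non-empty
  cells (an already-empty cell falls back to the empty operator);
* the forbidden pool (`$ ! ? * & ^ ~ | @`) lies outside the free-text class,
  the DNA and IUPAC alphabets and the sample-id class, is not whitespace,
  and excludes `#` — inserting `#` at the start of a first-column cell would
  silently turn the row into a comment row and desynchronise the ground
  truth;
* padded or symbol-bearing variants can never equal another cell's value in
  a generated sheet, so no spurious duplicate findings arise.

This yields the package's core testable property, *detection equality*: the
set of cells the QIIME rule set flags in a corrupted sheet equals the
injector's logged address set, across row counts {10, 100, 1000}, rates
{0.01, 0.05, 0.25} and 20+ seeds per combination. What passing does **not**
show about real data: real errors are not uniformly scattered, not limited
to three operators, and not guaranteed detectable (a plausible-but-wrong
barcode is invisible to format validation). The simulation measures the
engine's bookkeeping and the rules' soundness, not real-world recall.

## Benchmarks and numerical choices

`benchmark_rows()` times full QIIME validations of freshly generated (and
optionally corrupted) sheets over a grid of row counts and error rates;
`benchmark_rules()` times one fixed valid 1000-row x 24-column sheet under N
copies of the invalid-characters rule, so each added rule has a fixed cost.
Timings are walltime seconds, reported but never compared to absolute
reference values, which are hardware-bound; the meaningful check — asserted
in the tests — is the scaling *shape*: median runtime non-decreasing in rows
and in rule count, and a log-log slope of runtime versus rows at
{100, 1000, 10000} of at most ~1.5 (near-linear; in this implementation
fixed per-run overhead makes the measured slope well below 1). Default
problem sizes (10^2–10^4 rows, 3 replicates, medians) keep the whole suite
quick on a laptop while spanning two decades of sheet size; timings below
the clock's resolution are floored at 0.1 ms before the log fit.

Other numerical/tie-break choices: the modal-length tie-break (above);
uniform operator choice in the injector; `round()` (banker's rounding, as R
defines it) for the corruption count; sub-seeds for benchmark combinations
derived arithmetically from the user seed and kept below `2^31`.

## Limitations

* Formats are validated one sheet at a time; cross-file consistency (e.g.
  sample ids shared between a mapping file and a manifest) is out of scope.
* The rule vocabulary for user-defined formats is a closed set of
  primitives, not arbitrary predicates — deliberately, so a declared format
  fully determines behaviour.
* No auto-correction: the report says what is wrong and where, never mutates
  the grid.
* TSV mode cannot represent cells containing tabs or newlines (the QIIME
  dialect has no quoting); `write_sheet()` refuses rather than corrupt.
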