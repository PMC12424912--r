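---
title: "ClarID identifiers: encoding model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ClarID identifiers: encoding model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(claridr)
```

## Why structured identifiers

Subjects and biospecimens are usually tracked with opaque accessions or
UUIDs: unique, but silent about species, tissue, diagnosis or assay.
ClarID identifiers embed that context directly. Each identifier is a
fixed sequence of components drawn from controlled vocabularies in a
YAML codebook, in one of two formats:

* **human** — verbose, hyphen-delimited codebook codes, readable at a
  glance;
* **stub** — a compact, delimiter-free concatenation of short codes,
  suited to filenames, labels and database keys.

The same record produces both:

```{r}
cb <- load_codebook()
icd <- load_icd10()
rec <- list(project = "CNAG_Test", species = "Human", subject_id = 1,
            tissue = "Liver", sample_type = "Tumor", assay = "RNA_seq",
            condition = "C22.0", timepoint = "Treatment", duration = "P1W",
            batch = 1, replicate = 5)
encode_biosample(rec, cb, icd, "human")
encode_biosample(rec, cb, icd, "stub")
```

## The identifier model

**Biosample, human format** — nine mandatory hyphen-separated fields
plus two optional ones:

```
project-species-subject_id-tissue-sample_type-assay-condition-timepoint-duration[-Bbb][-Rrr]
```

`subject_id` is zero-padded to five digits (1..99999), `condition` is an
ICD-10 code carried verbatim (or the sentinel `NA`), `duration` is an
ISO 8601-style token of at most three characters relative to the
timepoint event (`P1W` = one week; `P0N` = not available), and batch /
replicate are two-digit integers prefixed `B` / `R`.

**Subject, human format** — six mandatory fields:

```
study-subject_id-type-condition-sex-age_group
```

`study` is free form (a hyphen in the raw study name is replaced by an
underscore, since the hyphen is the delimiter); age groups are decade
bins `A0_9` ... `A90_99`.

**Stub format** — the same components as fixed-width short codes, no
delimiters:

| component    | width | encoding                                   |
|--------------|------:|--------------------------------------------|
| project/study| varies| project `stub_code` from the codebook; study verbatim |
| species      | 2     | `stub_code` (Base62 index order)            |
| subject_id   | 3     | Base62 over `0-9A-Za-z` (max 238327)        |
| tissue, sample_type, assay, timepoint, subject type, sex | 1 | `stub_code` |
| condition    | 5     | Base62(rank in ICD-10 table, width 3) + `"01"` |
| age_group    | 2     | `A` + decade digit                          |
| duration     | 1–2   | human token minus the leading `P`           |
| batch, replicate | 3 | `B`/`R` + two digits, in that order, last   |

A biosample stub is therefore
`|project stub| + 14 + |duration payload| + 3 × (#optionals)`
characters, and a subject stub is `|study| + 12`. The fixed widths are
what make delimiter-free parsing decidable.

### Conditions and the rank-based stub

Clinical conditions are not enumerated in the codebook; they come from a
JSON lookup table of ICD-10 `{code, name}` pairs. On load the table is
canonicalized — the `NA` sentinel first, remaining codes sorted
lexicographically — and each code's 0-based position is its *rank*. The
stub format encodes the rank in three Base62 characters plus a reserved
`"01"` suffix, mirroring how species are compressed by their order in
the codebook. Because ranks are relative to the table, stub condition
bytes are only comparable between installations using the same table;
the bundled table is a ~50-entry excerpt covering common conditions and
is user-replaceable. Decoding can attach the condition name
(`with_condition_name`), with `"not available"` for the sentinel.

### Duration grammar

`"P"` + one digit + one unit letter among `D/W/M/Y`, or the sentinel
`P0N`; at most three characters in total, so `P10W` is rejected. A
consequence worth noting: the stub duration payload is always exactly
two characters, so the biosample stub core after the project prefix has
a fixed length (16). Since two distinct project stub codes that both
prefix a core would leave remainders of different lengths, project
prefix resolution can never be ambiguous under this grammar — the
decoder still carries a distinct "ambiguous stub" diagnostic for
codebooks paired with laxer rules.

### Missing values

`condition` falls back to `NA` (rank 0), `duration` to `P0N`, `assay`
to the `Not_available` term (`NAV`/`n`); batch and replicate are simply
omitted. All other components are mandatory and an absent value is a
row-level error, not a silent blank.

## Decoding

Human subject identifiers are parsed **right-anchored**: the last five
tokens are fixed, everything before them is the study. Human biosample
identifiers are left-anchored with the trailing optionals recognized by
shape (`Bnn`, then `Rnn`). Stub decoding strips optional suffixes
greedily from the right (replicate, then batch) with a re-parse guard —
if the stripped core fails to lay out but a less-stripped variant
parses, the latter wins — then resolves the variable-length project
prefix by trying every project stub code that prefixes the core and
keeping the unique full parse. Decoding is strict: no case folding, no
whitespace inside identifiers; every failure is a classified condition
(`clarid_structure_error`, `clarid_vocabulary_error`, ...) rather than a
partial record.

## Batch processing and mapping configs

`clarid_encode()` / `clarid_decode()` are data-frame-first and
vectorized; `clarid_batch()` adds CSV/TSV file handling (dialect by
extension, UTF-8, header row), per-row failure collection and
deterministic output (no timestamps in data files). Real-world tables
rarely carry canonical columns, so a YAML mapping config can rename
columns, recode values into vocabulary terms, declare missing-value
spellings, derive `subject_id` from UUIDs by order of first appearance,
and bin ages (floor semantics, so 49.9 years falls in `A40_49`) into
the codebook's decade groups:

```{r}
raw <- readr::read_csv(clarid_example("example-subjects-raw.csv"),
                       show_col_types = FALSE)
mapping <- load_mapping(clarid_example("example-mapping.yaml"))
mapped <- apply_mapping(raw, mapping, cb)
res <- clarid_encode(mapped, "subject", "human", cb, icd, on_error = "na")
res$clarid[1:4]
```

## Codebook validation

`validate_codebook()` checks a codebook twice: against a JSON Schema
(draft 2020-12; the package includes a validator for the keyword subset
the schema uses — type, required, properties, patternProperties,
additionalProperties, pattern, minLength, enum, items, local `$ref`s)
and against the invariants a schema cannot express: uniqueness of
`code`s and `stub_code`s within a component, fixed stub widths, no
hyphen in a `code`, well-formed rule regexes. Findings carry a severity
and a path into the document; unknown keys are warnings, because the
codebook is deliberately user-extensible.

## QR codes

The package includes a purpose-built QR codec rather than binding an
external library: byte mode, error-correction level L, symbol versions
1–5 (up to 106 identifier characters), one Reed–Solomon block per
symbol, mask pattern 0 on write. The reader handles what the writer
produces — clean, axis-aligned symbols at any integer scale with any
quiet zone — plus all eight mask patterns and full Reed–Solomon error
correction (Berlekamp–Massey, Chien search, Forney), so symbols with
module damage within the level-L budget still read back. It is not a
general-purpose camera-image scanner: perspective distortion,
rotation and uneven lighting are out of scope.

```{r}
png_file <- tempfile(fileext = ".png")
qr_generate("COPDStudy-01001-Case-J44.9-Male-A40_49", png_file)
qr_read(png_file)
```

## The synthetic record generator

`generate_records()` samples valid records uniformly from the codebook
vocabularies and the condition table under a fixed seed: subject IDs
from 1..99999, durations from a fixed valid pool, batch/replicate each
present with probability `optional_rate` (default 0.3, a realistic
share of replicated samples), and the "not available" encodings drawn
with probability `na_rate` (default 0.1, in line with the missing-data
levels typical of clinical exports). It emulates the *structure* of
real metadata — vocabulary membership, ID ranges, missingness — not its
statistics: real tables have skewed tissue/condition frequencies,
correlated fields and free-text noise. Passing round-trip tests on
generated records therefore demonstrates correctness of the coding
layer, not robustness to arbitrarily dirty inputs; the mapping config
plus per-row error collection are the tools for the latter.

## Problem sizes and numerical choices

The test suite and the reproduction script use 1,000 records per entity
and format for round-trip checks, the exhaustive 238,328-value sweep
for Base62, 100 identifiers per entity × format for QR round trips, and
a 10,000-row synthetic subject table for the batch path — sizes chosen
so the full suite completes in well under a minute while still
exercising every vocabulary entry and condition code many times over.
Other fixed choices: the Base62 alphabet is `0-9`, `A-Z`, `a-z` in that
order (the digit values the printed subject stub `0G9` = 1001 implies);
identifiers are ASCII with human-format tokens restricted to
`[A-Za-z0-9_.]`; decoding trims leading/trailing whitespace of the
whole string only.

## Known limitations

* One condition per identifier; multi-morbidity needs multiple records.
* Stub condition bytes depend on the installed ICD-10 table's ordering;
  two sites must share a table to exchange stubs losslessly.
* A study whose codebook `stub_code` differed from its name could not be
  recovered from a stub (the study is carried verbatim), so the bundled
  codebook leaves `study` free-form.
* Identifiers are metadata snapshots: if the underlying metadata
  changes, the identifier must be regenerated — they complement, not
  replace, stable primary keys such as UUIDs.
* Technical provenance (plate, vial, center, reagent lot) is
  deliberately out of scope; link it through external systems keyed by
  primary IDs.
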