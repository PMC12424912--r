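# claridr

Structured, self-describing identifiers for biomedical subjects and
biospecimens.

Most repositories track subjects and samples with opaque accessions or
UUIDs; the metadata that gives them meaning (species, tissue, diagnosis,
assay, timepoint) lives in separate tables. claridr implements the
ClarID identifier scheme: each identifier is a fixed sequence of
components drawn from a controlled-vocabulary YAML codebook, so the ID
itself answers "what is this sample?" It supports two formats —

* **human**: `project-species-subject_id-tissue-sample_type-assay-condition-timepoint-duration[-Bbb][-Rrr]`
  for biosamples (9 mandatory + 2 optional hyphen-separated fields) and
  `study-subject_id-type-condition-sex-age_group` for subjects (6 fields);
* **stub**: the same information as a compact, delimiter-free string of
  fixed-width short codes, with numeric parts (subject ID, ICD-10
  condition rank) compressed in Base62 over `0-9A-Za-z`.

Conditions are ICD-10 codes resolved against a bundled JSON lookup
table; durations are ISO 8601-style tokens of at most 3 characters
(`P1W`; `P0N` = not available). The package provides data-frame-first
encoding/decoding, batch CSV/TSV processing with per-row error
collection, external YAML mapping configs (column renames, value
recodes, UUID-to-numeric subject IDs, decade age binning), codebook
validation against a JSON Schema, QR code generation/reading, and a
command-line interface.

## Worked example

```r
library(claridr)
library(tibble)

cb  <- load_codebook()   # bundled example codebook
icd <- load_icd10()      # bundled ICD-10 mini table

samples <- tibble(
  project = "CNAG_Test", species = "Human", subject_id = 1,
  tissue = "Liver", sample_type = "Tumor", assay = "RNA_seq",
  condition = "C22.0", timepoint = "Treatment", duration = "P1W",
  batch = 1, replicate = 5
)

samples |> clarid_encode("biosample", "human", cb, icd) |> _$clarid
#> [1] "CNAG_Test-HomSap-00001-LIV-TUM-RNA-C22.0-TRT-P1W-B01-R05"

samples |> clarid_encode("biosample", "stub", cb, icd) |> _$clarid
#> [1] "CT01001LTR00601T1WB01R05"
```

Reading the human identifier back: `CNAG_Test` project, *Homo sapiens*
(`HomSap`), subject 1, liver (`LIV`), tumor (`TUM`), RNA-seq (`RNA`),
ICD-10 C22.0 (liver cell carcinoma), sampled one week (`P1W`) after the
treatment event (`TRT`), batch 1, replicate 5. The 24-character stub
packs the same fields at fixed widths (`CT` project, `01` species,
`001` Base62 subject ID, `L`/`T`/`R` single-char codes, `00601` =
Base62 rank of C22.0 in the bundled table + the reserved `01` suffix,
`T` timepoint, `1W` duration, `B01R05` optionals).

Decoding inverts either format, optionally translating the condition:

```r
clarid_decode("COPDStudy-01001-Case-J44.9-Male-A40_49",
              entity = "subject", format = "human",
              with_condition_name = TRUE)
#> # A tibble: 1 × 7
#>   study     subject_id type  condition sex   age_group condition_name
#>   <chr>          <dbl> <chr> <chr>     <chr> <chr>     <chr>
#> 1 COPDStudy       1001 Case  J44.9     Male  A40_49    chronic obstructive pulmonary disease, unspecified
```

Batch files, mapping configs and QR codes:

```r
res <- clarid_batch(clarid_example("example-subjects.csv"),
                    action = "encode", format = "stub", entity = "subject")
glance(res)
#> # A tibble: 1 × 6
#>   action entity  format rows_in rows_encoded rows_failed
#>   <chr>  <chr>   <chr>    <int>        <int>       <int>
#> 1 encode subject stub        10           10           0

qr_generate("CT01001LTR00601T1WB01R05", "sample.png")
qr_read("sample.png")
#> [1] "CT01001LTR00601T1WB01R05"
```

The same operations are available from a shell via the CLI script:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/clarid.R", package = "claridr"))') \
  code --action encode --format human --entity subject -i subjects.csv -o out.csv
```

See `vignette("clarid-identifiers")` for the full encoding model,
design notes and limitations.

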