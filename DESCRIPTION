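Package: claridr
Title: Codebook-Driven Encoding, Decoding and Validation of ClarID
    Subject and Biosample Identifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the ClarID structured-identifier specification for
    biomedical subjects and biospecimens. Identifiers embed key metadata
    (project, species, tissue, assay, ICD-10 condition, timepoint, ...)
    drawn from a user-extensible YAML codebook, in two formats: a verbose
    hyphen-delimited human-readable form and a compact delimiter-free
    "stub" form built from fixed-width short codes and Base62 transforms.
    Provides data-frame-first encoding and decoding for batch CSV/TSV
    processing, external column-mapping configurations with age binning,
    codebook validation against a JSON Schema, ICD-10 condition name
    translation, QR code generation and read-back, and a command-line
    interface.
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
    png,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
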