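Package: degradomeR
Title: Plasma Degradome Analysis from Endogenous Tryptic Peptide Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of the ex vivo degradome of blood plasma from
    peptide-spectrum-match (PSM) tables: a deduplication and filtering
    cascade from raw MS/MS-to-peptide correlations to a gene-symbol-level
    protein inventory, gene-level cumulative p-values with
    Benjamini-Hochberg FDR control, comparison of observed
    peptide-per-protein distributions against a random-assignment null
    model, contaminant flagging, room-temperature versus ice enrichment
    ratios with a fivefold filter, cross-algorithm consensus, generic
    category enrichment, and a fully seeded synthetic-data generator with
    exported ground truth so every stage is testable without raw
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
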