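Package: ampliaudit
Title: Audit Availability and Reusability of Amplicon Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing the public availability and reusability of 16S
    rRNA gene amplicon sequencing data. Mines article full texts for INSDC
    accession numbers, primer mentions and alternative-database mentions;
    validates accessions, resolves within-article accession ranges and
    extrapolates non-deposition rates; audits run-level and biosample-level
    repository metadata for public status, library-strategy labeling and
    layout consistency; audits sampled FASTQ reads for quality-score
    presence, retained degenerate primers, inferred barcodes and
    demultiplexing state; classifies each study's data fate (reusable,
    partially usable, or not available) from a per-study fault ledger;
    computes corpus summaries and chi-squared tests for trend in
    proportions; and generates fully synthetic offline test corpora with
    planted faults and known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    tidyr,
    purrr,
    tibble,
    stringr,
    readr,
    rlang,
    jsonlite,
    xml2,
    withr,
    ggplot2,
    Biostrings,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
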