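Package: clonetrace
Title: Clonal Tracking and Genomic Dynamics of Multi-Organ Metastasis in
    Barcoded Xenografts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping metastatic clonal dynamics in lentivirally
    barcoded patient-derived xenograft (PDX) experiments. Implements a
    barcode quantification pipeline for paired half-barcode reads (spacer
    filtering, end-tolerant half-barcode alignment, paired counting and
    counts-per-million normalization), clonal-architecture metrics
    (dominant-barcode sets, Shannon diversity, seeding clones, Jaccard
    overlap, tumor-initiating-cell frequency), single-hit Poisson
    limiting-dilution estimation of metastasis-initiating frequency,
    mutant-allele-frequency dynamics between primary tumors and metastases
    (consensus variant filters, delta-MAF enrichment classification,
    de novo mutation criteria, a chi-square read co-occurrence artifact
    filter, qPCR human-fraction estimation), and a co-assignment-based
    robustness test for mutation clusters from MCMC clustering traces.
    A synthetic-data generator emulates the full experimental design so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
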