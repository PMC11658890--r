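Package: pamkin
Title: PAM Depletion Profiling and Exponential Cleavage Kinetics for Cas9 Nucleases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for in vitro characterization of Cas9 PAM
    specificity and DNA-cleavage kinetics. Extracts randomized PAM tetramers
    from amplicon sequencing reads of a plasmid depletion assay, normalizes
    frequencies to sequencing depth, computes log2 fold changes against an
    untreated library, derives a depletion-significance threshold from
    non-targeting controls, and summarizes significant PAMs as a sequence
    logo and IUPAC consensus. Fits single-exponential models to cleavage
    fraction and 2-aminopurine fluorescence time courses with the
    amplitude-floor "nd" rules, aggregates replicates and computes rate
    fold changes. Includes seeded synthetic-data generators for both assays
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
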