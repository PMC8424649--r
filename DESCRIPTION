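Package: repeatlens
Title: Somatic Repeat Instability, MSI Classification, and Crosslink
    Validation
Version: 0.1.0
Authors@R:
    person("repeatlens", "developers", email = "repeatlens@example.org",
           role = c("aut", "cre"))
Description: Quantifies somatic CAG-repeat instability from capillary
    electrophoresis fragment-analysis peak tables: modal-allele calling with a
    20 percent-of-modal inclusion threshold, instability and expansion
    indices, expansion-rate regression over time courses, and group
    comparisons (one-way ANOVA, Brown-Forsythe, t tests) with
    Benjamini-Hochberg false discovery rate control.  Classifies
    microsatellite instability across a mono-/di-/tetra-nucleotide marker
    panel with pentanucleotide control loci (EMAST flagging).  Validates
    crosslinking mass-spectrometry residue pairs by score filtering, unique
    pair counting, and Calpha-Calpha distance checks against PDB/mmCIF
    structures, with alignment consensus and motif utilities.  Includes a
    seeded stochastic generator of repeat-expansion dynamics rendered as
    realistic peak tables (PCR stutter, sizing noise) so the whole pipeline
    is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
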