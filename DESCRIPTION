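Package: obocScreen
Title: Design, Decoding and Triage of One-Bead-One-Compound Peptide Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for combinatorial one-bead-one-compound (OBOC) peptide
    library screens built on a gramicidin A scaffold: library enumeration with
    nominal, average and monoisotopic mass bookkeeping, bead-coverage
    statistics for split-and-mix synthesis, constrained de novo sequencing of
    MALDI-type singly charged b/y fragment ladders, multi-assay hit
    classification into cytotoxic and non-cytotoxic groups with
    hydrogen-bond-residue subgrouping, representative-compound selection
    rules, amino-acid composition tables, Hill dose-response fitting
    (EC50/IC50/HC10), microdilution MIC calling, and a fully seeded synthetic
    screen generator that provides ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
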