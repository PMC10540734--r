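Package: dielprot
Title: Diel Rhythm Analysis of Proteomes and Phosphoproteomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for label-free diel (light-dark cycle)
    time-course proteomics and phosphoproteomics. Merges technical
    phosphopeptide variants into uniquely keyed phosphopeptide motifs,
    normalizes and quality-controls replicated abundance tables, scores
    rhythmicity by cubic polynomial regression with Benjamini-Hochberg
    false discovery control and a fold-change gate, tests non-change by
    exhaustive pairwise equivalence (TOST), characterizes temporal
    patterns by PCA and Ward clustering with a dynamic hybrid tree cut,
    simulates protein dynamics under light-stimulated translation to
    predict peak-phase distributions, estimates protein degradation
    rates from partial 15N metabolic labelling, and computes
    position-specific binomial (pLogo-style) and kinase-consensus motif
    enrichment by peak phase. Includes a synthetic-data generator that
    emulates a 6-timepoint x 5-replicate design for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    deSolve,
    jsonlite,
    yaml,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
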