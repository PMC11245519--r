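Package: dCachePU
Title: Purine-Binding Motif Discovery and Binding-Assay Analysis for
    dCache_1 Sensor Domains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for deriving, scanning and summarizing the
    structure-anchored purine-binding sequence motif of bacterial
    dCache_1 sensor domains (the dCache_1PU subfamily), together with
    the supporting quantitative assay analyses.  The package extracts
    ligand-contacting residues from a protein-ligand structure, tracks
    reference positions through multiple sequence alignments, computes
    per-column conservation, applies a gap-fraction trimming rule,
    classifies sensor sequences by motif variant, rolls up cohorts by
    receptor class and taxonomy, fits one-binding-site isothermal
    titration calorimetry isotherms, and calls melting temperatures
    from thermal-shift fluorescence curves.  A synthetic-data module
    generates planted-motif sequence cohorts, one-site titrations and
    two-state melt curves with known ground truth so that every stage
    of the pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    bio3d,
    minpack.lm,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse, withr, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
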