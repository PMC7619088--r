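Package: mutland
Title: Mutational Landscape Classification and Sensitivity Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Offline toolkit for interpreting protein mutational landscapes
    from evolutionary information. Reads multiple sequence alignments in
    A2M, A3M or aligned FASTA with an ungapped query on top, ingests or
    computes a 19 x L matrix of per-substitution evolutionary scores,
    classifies variants as impactful, mild or neutral with a three-component
    Gaussian mixture, flags residues with insufficient alignment support,
    segments the per-residue mutational sensitivity profile with a weighted
    functional-pruning changepoint algorithm (penalty alpha * sigma^2 *
    log n, pLDDT-aware weights) to highlight putative functional peptides
    in disordered regions, and modulates scores by relative solvent
    accessibility computed with the Shrake-Rupley algorithm from a PDB
    structure (free and complexed contexts). Includes synthetic generators
    for alignments, landscapes and toy structures so every step is testable
    without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    seqinr,
    jsonlite,
    withr,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
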