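Package: otudelim
Title: Integrative Single-Locus Species Delimitation for DNA Barcodes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Delimits operational taxonomic units (OTUs) from aligned COI
    barcode matrices by combining three lines of evidence: morphospecies
    labels, a refined-single-linkage (RESL/BIN style) clustering of Kimura
    2-parameter distances, and a single-threshold general mixed
    Yule-coalescent (GMYC) model fitted to an ultrametric tree. Includes
    alignment quality control (length filtering, stop-codon screening,
    site classification, base composition), pairwise K2P distances with
    transition/transversion accounting, barcoding-gap summaries, UPGMA
    tree construction, a Markov-clustering refinement step, a consensus
    layer that labels OTUs with agreement patterns, and a synthetic-data
    generator (Yule species tree, within-species coalescents, two-rate
    sequence evolution) so every stage can be tested without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    igraph,
    jsonlite,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
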