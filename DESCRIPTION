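Package: PanGeneKit
Title: Pan-Gene Construction and Characterization from Multi-Genome Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds pan-gene sets (clusters of syntenic orthologs) from
    per-genome gene annotations and cross-genome lifted gene intervals.
    Provides merging of overlapping annotation sets for a reference genome,
    strand-aware overlap clustering into pan-genes, occupancy classification
    (core/softcore/shell/cloud) with core-genome growth-curve extrapolation
    over genome-order permutations, reference-relative pseudo-position
    assignment, minting and release-to-release remapping of stable pan-gene
    identifiers, protein-domain occupancy variability analysis with
    hypergeometric enrichment, in-silico tryptic peptide mapping with
    parsimonious protein inference, and comparison against external cluster
    sets. A synthetic multi-genome simulator with known ground-truth cluster
    structure supports end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    minpack.lm,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
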