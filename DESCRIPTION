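Package: hotspotsel
Title: Branch-Model Tests of Positive Selection and Genomic Hotspot Clustering
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detection of lineage-specific diversifying selection and of its
    genomic clustering. Implements Goldman-Yang codon substitution models with
    F3x4 equilibrium frequencies, maximum-likelihood fitting of one-ratio and
    two-ratio (foreground/background) branch models by Felsenstein pruning,
    likelihood-ratio tests with Benjamini-Hochberg false-discovery control, a
    permutation null for the count of selection candidates in fixed-length
    genomic windows drawn over randomly concatenated chromosomes, cross-species
    synteny-block comparison (gene order, orientation, linkage, breakpoint
    distance), GC composition of coding sequences, and read-coverage
    normalization with detection of X-like bimodal scaffolds. Includes seeded
    generators for synthetic codon alignments, genome annotations with planted
    candidate clusters, rearranged gene blocks, and coverage matrices, so the
    whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    phangorn,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
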