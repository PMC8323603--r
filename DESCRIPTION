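Package: contigDamage
Title: Ancient DNA Damage Identification and Estimation for Assembled Contigs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Automated identification and estimation of ancient DNA damage on
    de novo assembled contigs. Counts position-dependent C-to-T
    misincorporations from read alignments, fits a position-independent null
    model and a geometrically decaying damage model to the per-position
    transition proportions, tests damage significance per contig with a
    likelihood-ratio test against a chi-squared distribution with two degrees
    of freedom, adjusts for multiple testing across contigs with the
    Benjamini-Hochberg procedure, predicts per-contig call accuracy with a
    logistic model of damage, coverage and contig length, and filters contigs
    on q-value, decay rate and predicted accuracy. Ships a deterministic
    simulator of damaged ancient DNA reads with ground-truth alignments for
    testing and model training.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
biocViews: Metagenomics, Microbiome, Alignment, Sequencing, StatisticalMethod
RoxygenNote: 7.3.3
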