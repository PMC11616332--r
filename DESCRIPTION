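Package: cagrepair
Title: Classification of Cas9 Editing Outcomes at CAG-Repeat Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of CRISPR/Cas9 double-strand-break repair products at
    CAG-repeat amplicons. Simulates edited amplicon sequencing reads with
    ground truth; filters, merges and aligns reads against the amplicon;
    genotypes the CAG tract per read and classifies editing outcomes into
    six categories with repair-signature annotation (microhomology-flanked
    whole-tract deletions, templated insertions, staggered-cut single-base
    insertions, PCR stutter). Companion calculators cover
    restriction-protection qPCR resection levels, ChIP/DRIP-qPCR percent
    input and fold enrichment, capillary-electrophoresis contraction
    fractions, and label-free proteomics differential abundance with
    downshifted-normal imputation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
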