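Package: strainpop
Title: Strain-Level Population Genetics from Mapped Metagenomic Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for metagenome-resolved population genetics of abundant
    marine microbial populations. Builds per-site pileups from mapped
    paired-end reads, calls and classifies single nucleotide variants,
    and computes nucleotide diversity, pN/pS, read-pair linkage
    disequilibrium with rarefaction, Hudson-style FST between pooled
    samples, Heaps-law pangenome openness, and allele-frequency
    trajectories correlated with environmental covariates. Includes a
    forward simulator of strain communities (mosaic haplotypes,
    paired-end reads, two-deme differentiation, accessory-gene pools,
    temperature-coupled alleles) with ground truth for validating every
    stage of the analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    ape,
    Rsamtools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
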