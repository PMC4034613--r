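Package: HomoeoSort
Title: Subgenome Assignment and Phylogenomic Preparation for
    Allopolyploid Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Resolves allopolyploid transcriptome reads into their two
    homoeologous subgenomes by preferential mapping against a joined
    progenitor reference, and prepares the downstream population-genomic
    and phylogenomic datasets. Includes a synthetic progenitor/
    allopolyploid triad generator with full truth labels, read
    demultiplexing and quality processing, a seeded ungapped aligner with
    best/second-best score semantics, pileup-based SNP calling and
    multi-sample genotype matrices with VCF/HapMap/Structure export,
    species-group consensus transcriptome assembly, electronic chromosome
    painting of subgenome-tagged SNPs, and phylogenomic utilities (OTU
    construction with subgenome splitting, SNP supermatrix export, gene
    selection and outgroup screening, ultrametric tree calibration,
    minimum divergence extraction, and the Evanno delta-K statistic).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    yaml,
    rtracklayer
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
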