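#' @rdname TriadSimulation-class
#' @param x,object a TriadSimulation (or other HomoeoSort object).
#' @export
setGeneric("referenceGenome", function(x) standardGeneric("referenceGenome"))

#' @rdname TriadSimulation-class
#' @export
setGeneric("geneModels", function(x) standardGeneric("geneModels"))

#' @rdname TriadSimulation-class
#' @export
setGeneric("ddpCatalog", function(x) standardGeneric("ddpCatalog"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("siteInfo", function(x) standardGeneric("siteInfo"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("sampleNames", function(x) standardGeneric("sampleNames"))

#' @rdname ConsensusSet-class
#' @export
setGeneric("consensusSequences",
           function(x) standardGeneric("consensusSequences"))

#' @rdname PaintTrack-class
#' @export
setGeneric("paintBins", function(x) standardGeneric("paintBins"))

setMethod("referenceGenome", "TriadSimulation", function(x) x@reference)
setMethod("geneModels", "TriadSimulation", function(x) x@genes)
setMethod("ddpCatalog", "TriadSimulation", function(x) x@ddp)
setMethod("genotypes", "GenotypeMatrix", function(x) {
  m <- x@geno
  dimnames(m) <- list(NULL, x@samples)
  m
})
setMethod("siteInfo", "GenotypeMatrix", function(x) x@sites)
setMethod("sampleNames", "GenotypeMatrix", function(x) x@samples)
setMethod("consensusSequences", "ConsensusSet", function(x) x@sequences)
setMethod("paintBins", "PaintTrack", function(x) x@bins)

setMethod("show", "SimulationConfig", function(object) {
  gl <- paste(object@geneLength, collapse = "-")
  cat("SimulationConfig\n",
      "  ", object@nChromosomes, " chromosome(s) x ", object@chromLength,
      " bp; ", object@nGenes, " genes (", gl, " bp)\n",
      "  progenitor divergence d = ", object@progenitorDivergence,
      "; reference divergence = ", object@referenceDivergence, "\n",
      "  paleo-duplicates: ", object@paleoDupFraction, " of genes at ",
      object@paleoDivergence, " subst/site\n",
      "  reads: ", object@nReads, " x ", object@readLength,
      " nt, error rate ", object@errorRate, "; seed ", object@seed, "\n",
      sep = "")
})

setMethod("show", "TriadSimulation", function(object) {
  cat("TriadSimulation\n",
      "  reference: ", length(object@reference), " chromosome(s), ",
      sum(Biostrings::width(object@reference)), " bp\n",
      "  genes: ", nrow(object@genes), " (",
      sum(object@genes$class == "paleo_dup"), " paleo-duplicates)\n",
      "  DDP catalog: ", nrow(object@ddp), " sites\n",
      "  lost genes: A=", length(object@lostGenes$A),
      ", B=", length(object@lostGenes$B), "\n", sep = "")
})

setMethod("show", "ScoringScheme", function(object) {
  cat("ScoringScheme: match 0, mismatch -", object@mismatchPenalty,
      ", ambiguous -", object@ambiguousPenalty, " (AS = 0 is perfect)\n",
      sep = "")
})

setMethod("show", "SeedIndex", function(object) {
  cat("SeedIndex: ", length(object@targets), " target(s), k = ", object@k,
      ", ", .cpp_index_positions(object@ptr), " seed positions\n", sep = "")
})

setMethod("show", "VariantCallSet", function(object) {
  cat("VariantCallSet '", object@sample, "': ", nrow(object@calls),
      " calls over ", length(object@targets), " target(s)\n", sep = "")
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix: ", nrow(object@sites), " sites x ",
      length(object@samples), " samples (",
      round(100 * mean(is.na(object@geno)), 2), "% missing)\n", sep = "")
})

setMethod("show", "ConsensusSet", function(object) {
  cat("ConsensusSet '", object@group, "': ", length(object@sequences),
      " gene(s), median N fraction ",
      round(stats::median(object@stats$n_fraction), 4), "\n", sep = "")
})

setMethod("show", "ProgenitorReference", function(object) {
  cat("ProgenitorReference [", object@labels[1], " + ", object@labels[2],
      "]: ", sum(!is.na(object@seqA)), " + ", sum(!is.na(object@seqB)),
      " targets over ", length(object@genes), " gene(s)\n", sep = "")
})

setMethod("show", "PaintTrack", function(object) {
  cat("PaintTrack: ", length(object@bins), " bins of ", object@binSize,
      " bp; labels: ", paste(object@labels, collapse = ", "), "\n", sep = "")
})

setMethod("show", "TimeTree", function(object) {
  cat("TimeTree: ", length(object@tree$tip.label),
      " tips, root age ", object@rootAge, " Myr\n", sep = "")
})

setMethod("show", "SuperMatrix", function(object) {
  cat("SuperMatrix: ", length(object@sequences), " OTUs x ",
      nrow(object@sites), " SNP columns\n", sep = "")
})
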