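#' Simulation configuration for a synthetic progenitor/allopolyploid triad
#'
#' Holds every knob of the triad generator. Defaults describe two selfing
#' (near-homozygous) diploid progenitors diverged at ~2% of transcribed
#' sites, an allopolyploid that is the fixed union of the two progenitor
#' genomes with a small amount of post-merger mutation, a congeneric
#' reference genome ~3% diverged from the triad ancestor, a ~10% fraction of
#' genes with a retained paleo-duplicate from an older whole-genome
#' duplication, and single-end 100 nt reads with a low error rate.
#'
#' @slot nChromosomes number of chromosomes.
#' @slot chromLength chromosome length (bp).
#' @slot nGenes number of primary (non-duplicate) gene models.
#' @slot geneLength gene length (bp); length-1 (fixed) or length-2 (range).
#' @slot progenitorDivergence substitutions/site between the two progenitor
#'   lineages at transcribed sites; every differing site is a
#'   diploid-distinguishing polymorphism (DDP).
#' @slot withinSpeciesPolymorphism heterozygosity rate/site within each
#'   diploid accession (low for selfers; default 0).
#' @slot referenceDivergence substitutions/site between the mapping reference
#'   lineage and the triad ancestor (the reference plays the role of a
#'   congeneric reference genome).
#' @slot paleoDupFraction fraction of genes with a retained paleo-duplicate.
#' @slot paleoDivergence substitutions/site between paleo-duplicate pairs.
#' @slot postMergerRate substitutions/site added to each allopolyploid
#'   subgenome after its formation.
#' @slot lossBlocks data.frame (chrom, start, end, subgenome) of intervals
#'   deleted from one subgenome of the allopolyploid.
#' @slot readLength read length in nt (88 or 100 are typical).
#' @slot nReads number of reads to simulate per sample.
#' @slot errorRate sequencing errors per base.
#' @slot seed integer seed; identical seeds give bit-identical output.
#'
#' @seealso [SimulationConfig()] for the constructor with defaults.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    nChromosomes = "integer",
    chromLength = "integer",
    nGenes = "integer",
    geneLength = "integer",
    progenitorDivergence = "numeric",
    withinSpeciesPolymorphism = "numeric",
    referenceDivergence = "numeric",
    paleoDupFraction = "numeric",
    paleoDivergence = "numeric",
    postMergerRate = "numeric",
    lossBlocks = "data.frame",
    readLength = "integer",
    nReads = "integer",
    errorRate = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  rates <- c(
    progenitorDivergence = object@progenitorDivergence,
    withinSpeciesPolymorphism = object@withinSpeciesPolymorphism,
    referenceDivergence = object@referenceDivergence,
    paleoDupFraction = object@paleoDupFraction,
    paleoDivergence = object@paleoDivergence,
    postMergerRate = object@postMergerRate,
    errorRate = object@errorRate
  )
  bad <- rates < 0 | rates > 1
  if (any(bad)) {
    msg <- c(msg, paste0("rates must lie in [0, 1]: ",
                         paste(names(rates)[bad], collapse = ", ")))
  }
  counts <- c(object@nChromosomes, object@chromLength, object@nGenes,
              object@geneLength, object@readLength)
  if (any(counts <= 0L)) {
    msg <- c(msg, "lengths and counts must be strictly positive")
  }
  if (object@nReads < 0L) msg <- c(msg, "nReads must be non-negative")
  if (!length(object@geneLength) %in% 1:2) {
    msg <- c(msg, "geneLength must be a single value or a (min, max) range")
  }
  lb <- object@lossBlocks
  if (nrow(lb)) {
    need <- c("chrom", "start", "end", "subgenome")
    if (!all(need %in% names(lb))) {
      msg <- c(msg, "lossBlocks needs columns chrom, start, end, subgenome")
    } else {
      if (any(lb$start < 0L) || any(lb$end > object@chromLength) ||
          any(lb$start >= lb$end)) {
        msg <- c(msg, "lossBlocks intervals must lie within chromosomes")
      }
      if (!all(lb$subgenome %in% c("A", "B"))) {
        msg <- c(msg, "lossBlocks subgenome must be 'A' or 'B'")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Synthetic triad: reference, progenitor haplotypes, allopolyploid, truth
#'
#' Output of [generateTriad()]. Chromosome-level sequences are stored for the
#' mapping reference, both haplotypes of each diploid progenitor accession,
#' and the two subgenomes of the allopolyploid. The truth is carried by the
#' DDP catalog (every site at which the founding haplotypes of the two
#' progenitors differ) and the gene-model table.
#'
#' @slot reference DNAStringSet of reference chromosomes (mapping target).
#' @slot genes gene-model table: gene_id, chrom, start, end (0-based,
#'   half-open), strand, cds_frame, class ("primary"/"paleo_dup"),
#'   paleo_pair.
#' @slot progenitorA,progenitorB founding haplotype (haplotype 1) chromosomes.
#' @slot progenitorA2,progenitorB2 second haplotype of each diploid accession
#'   (identical to haplotype 1 when withinSpeciesPolymorphism is 0).
#' @slot polyploidA,polyploidB allopolyploid subgenome chromosomes.
#' @slot ddp DDP catalog: chrom, pos (0-based), allele_A, allele_B, gene_id,
#'   tpos (position within the transcript).
#' @slot lostGenes list(A=, B=) of gene ids deleted from each subgenome by
#'   loss blocks.
#' @slot config the [SimulationConfig-class] used.
#' @exportClass TriadSimulation
setClass("TriadSimulation",
  representation(
    reference = "DNAStringSet",
    genes = "data.frame",
    progenitorA = "DNAStringSet",
    progenitorB = "DNAStringSet",
    progenitorA2 = "DNAStringSet",
    progenitorB2 = "DNAStringSet",
    polyploidA = "DNAStringSet",
    polyploidB = "DNAStringSet",
    ddp = "data.frame",
    lostGenes = "list",
    config = "SimulationConfig"
  )
)

#' Alignment scoring scheme
#'
#' End-to-end ungapped scoring: a perfect alignment scores 0 (AS = 0) and
#' each penalty subtracts from the score, so AS = -(sum of penalties).
#'
#' @slot match score of a matching column (fixed at 0).
#' @slot mismatchPenalty penalty per mismatching base pair (default 6).
#' @slot ambiguousPenalty penalty per column involving a non-ACGT base
#'   (default 1); such columns are not counted as mismatches.
#' @exportClass ScoringScheme
setClass("ScoringScheme",
  representation(match = "numeric", mismatchPenalty = "integer",
                 ambiguousPenalty = "integer")
)

setValidity("ScoringScheme", function(object) {
  if (object@match != 0) return("match score is fixed at 0")
  if (object@mismatchPenalty < 0L || object@ambiguousPenalty < 0L)
    return("penalties must be >= 0")
  TRUE
})

#' Seed index over a set of target sequences
#'
#' Exact k-mer index used by [alignReads()]. The index holds an external
#' pointer and is only valid within the R session that built it.
#'
#' @slot ptr external pointer to the k-mer map.
#' @slot k seed length.
#' @slot targets target (transcript) names.
#' @slot widths target lengths.
#' @exportClass SeedIndex
setClass("SeedIndex",
  representation(ptr = "externalptr", k = "integer", targets = "character",
                 widths = "integer")
)

#' Per-sample variant calls plus the coverage needed to merge samples
#'
#' @slot calls data.frame: target, pos (0-based), ref, alt (comma-separated),
#'   genotype ("X/Y", alleles sorted), depth.
#' @slot coverage named list (by target) of per-position depth vectors.
#' @slot sample sample identifier.
#' @slot targets names/lengths of the reference targets used.
#' @exportClass VariantCallSet
setClass("VariantCallSet",
  representation(calls = "data.frame", coverage = "list",
                 sample = "character", targets = "integer")
)

#' Samples-by-sites diploid genotype matrix
#'
#' Sites are rows, samples are columns (features-by-samples). Genotypes are
#' unordered allele pairs encoded "X/Y" (alleles sorted alphabetically);
#' missing cells are NA.
#'
#' @slot geno character matrix, sites x samples.
#' @slot sites data.frame: chrom, pos (0-based), ref, alt (comma-separated
#'   alternative alleles observed across samples).
#' @slot samples sample identifiers (column order of `geno`).
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  representation(geno = "matrix", sites = "data.frame",
                 samples = "character")
)

setValidity("GenotypeMatrix", function(object) {
  if (nrow(object@geno) != nrow(object@sites))
    return("geno and sites disagree on the number of sites")
  if (ncol(object@geno) != length(object@samples))
    return("geno and samples disagree on the number of samples")
  if (anyDuplicated(object@samples)) return("duplicate sample ids")
  o <- order(object@sites$chrom, object@sites$pos)
  if (!identical(o, seq_len(nrow(object@sites))))
    return("sites must be sorted by (chrom, pos)")
  if (anyDuplicated(paste(object@sites$chrom, object@sites$pos)))
    return("duplicate sites")
  TRUE
})

#' Per-group consensus transcriptome
#'
#' One majority-base sequence per reference gene, with N at positions whose
#' coverage is below the masking depth.
#'
#' @slot sequences DNAStringSet, one per gene, same length as the reference
#'   gene.
#' @slot group species-group label.
#' @slot stats data.frame: gene_id, length, n_count, n_fraction,
#'   covered_length.
#' @exportClass ConsensusSet
setClass("ConsensusSet",
  representation(sequences = "DNAStringSet", group = "character",
                 stats = "data.frame")
)

#' Joined progenitor reference for preferential mapping
#'
#' The two consensus transcript sets of the putative progenitors, aligned on
#' shared gene ids. Genes present in only one set are kept (reads on them can
#' only be assigned to that side).
#'
#' @slot genes union of gene ids (coordinate frame for classification).
#' @slot seqA,seqB consensus sequence per gene (NA when a gene is absent
#'   from that side), parallel to `genes`.
#' @slot labels the two progenitor labels, e.g. c("D3", "D4").
#' @exportClass ProgenitorReference
setClass("ProgenitorReference",
  representation(genes = "character", seqA = "character", seqB = "character",
                 labels = "character")
)

setValidity("ProgenitorReference", function(object) {
  if (length(object@labels) != 2L || anyDuplicated(object@labels))
    return("exactly two distinct progenitor labels are required")
  if (length(object@genes) != length(object@seqA) ||
      length(object@genes) != length(object@seqB))
    return("genes, seqA and seqB must be parallel")
  if (all(is.na(object@seqA)) || all(is.na(object@seqB)))
    return("both progenitor consensus sets must be non-empty")
  TRUE
})

#' Electronic chromosome painting track
#'
#' Binned counts of subgenome-tagged SNPs along each chromosome. Bins tile
#' [0, chrom_length) without overlap (half-open, 0-based; stored 1-based in
#' the GRanges per Bioconductor convention).
#'
#' @slot bins GRanges of bins with one metadata count column per subgenome
#'   label.
#' @slot labels subgenome labels (metadata column names).
#' @slot binSize bin width in bp.
#' @exportClass PaintTrack
setClass("PaintTrack",
  representation(bins = "GRanges", labels = "character", binSize = "integer")
)

#' Calibrated ultrametric time tree
#'
#' @slot tree rooted `ape::phylo` tree, ultrametric, scaled so the root sits
#'   at `rootAge`.
#' @slot rootAge calibration age of the root (Myr).
#' @exportClass TimeTree
setClass("TimeTree", representation(tree = "ANY", rootAge = "numeric"))

#' SNP supermatrix with OTUs as rows
#'
#' @slot sequences DNAStringSet, one concatenated SNP sequence per OTU
#'   (heterozygous genotypes as IUPAC ambiguity codes, missing as N).
#' @slot sites data.frame mapping columns to (chrom, pos).
#' @exportClass SuperMatrix
setClass("SuperMatrix",
  representation(sequences = "DNAStringSet", sites = "data.frame")
)
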