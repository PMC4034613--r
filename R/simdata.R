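#' Construct a simulation configuration
#'
#' Builds a [SimulationConfig-class] describing one progenitor/allopolyploid
#' triad. Defaults model the study system the package targets: two strongly
#' selfing diploid progenitors whose transcribed sequences differ at about 2%
#' of sites (each differing site is a diploid-distinguishing polymorphism,
#' DDP), an allopolyploid that is the fixed union of one haplotype from each
#' progenitor with a small amount of post-merger mutation, a congeneric
#' mapping reference about 3% diverged from the triad ancestor, a 10% gene
#' fraction carrying a retained paleo-duplicate from an older whole-genome
#' duplication, and 100 nt single-end reads at an error rate of 0.001.
#'
#' @param nChromosomes,chromLength,nGenes,geneLength genome layout. `geneLength`
#'   may be a single value or a (min, max) range; lengths are rounded down to
#'   multiples of 3 so every gene is a complete CDS.
#' @param progenitorDivergence per-site probability that a transcribed site is
#'   a DDP (substitutions/site between the progenitor lineages).
#' @param withinSpeciesPolymorphism per-site heterozygosity within a diploid
#'   accession. Default 0: the modeled taxa are cleistogamous selfers and the
#'   diploid consensus is taken from the lineage that founded the polyploid.
#' @param referenceDivergence substitutions/site on the reference lineage.
#' @param paleoDupFraction,paleoDivergence retained paleo-duplicate fraction
#'   and divergence.
#' @param postMergerRate substitutions/site added to each allopolyploid
#'   subgenome after formation.
#' @param lossBlocks data.frame (chrom, start, end, subgenome) of intervals
#'   deleted from one subgenome ("A" or "B"); 0-based half-open.
#' @param readLength,nReads,errorRate read simulation defaults.
#' @param seed integer seed; the same seed yields bit-identical triads.
#' @return A [SimulationConfig-class] object.
#' @examples
#' cfg <- SimulationConfig(nGenes = 20L, nChromosomes = 2L,
#'                         chromLength = 25000L, seed = 1L)
#' cfg
#' @export
SimulationConfig <- function(nChromosomes = 5L, chromLength = 100000L,
                             nGenes = 200L, geneLength = 1500L,
                             progenitorDivergence = 0.02,
                             withinSpeciesPolymorphism = 0,
                             referenceDivergence = 0.03,
                             paleoDupFraction = 0.10,
                             paleoDivergence = 0.30,
                             postMergerRate = 1e-4,
                             lossBlocks = NULL,
                             readLength = 100L, nReads = 200000L,
                             errorRate = 0.001, seed = 1L) {
  if (is.null(lossBlocks)) {
    lossBlocks <- data.frame(chrom = character(), start = integer(),
                             end = integer(), subgenome = character())
  }
  new("SimulationConfig",
      nChromosomes = as.integer(nChromosomes),
      chromLength = as.integer(chromLength),
      nGenes = as.integer(nGenes),
      geneLength = as.integer(geneLength),
      progenitorDivergence = progenitorDivergence,
      withinSpeciesPolymorphism = withinSpeciesPolymorphism,
      referenceDivergence = referenceDivergence,
      paleoDupFraction = paleoDupFraction,
      paleoDivergence = paleoDivergence,
      postMergerRate = postMergerRate,
      lossBlocks = lossBlocks,
      readLength = as.integer(readLength),
      nReads = as.integer(nReads),
      errorRate = as.integer(0) + errorRate,
      seed = as.integer(seed))
}

#' Read a simulation configuration from a YAML file
#'
#' Field names match the arguments of [SimulationConfig()]; `lossBlocks` may
#' be given as a list of `(chrom, start, end, subgenome)` records.
#'
#' @param path path to a YAML file.
#' @return A [SimulationConfig-class] object.
#' @export
readSimulationConfig <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configurations requires the 'yaml' package")
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$lossBlocks))
    vals$lossBlocks <- do.call(rbind, lapply(vals$lossBlocks, as.data.frame))
  do.call(SimulationConfig, vals)
}

.BASES <- c("A", "C", "G", "T")

# substitute a uniformly chosen different base at each (chrom, pos0);
# returns list(seqs = modified character vector, new = new bases)
.mutateAt <- function(seqs, chrom, pos0) {
  new <- character(length(pos0))
  raws <- charToRaw("ACGT")
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    r <- charToRaw(seqs[[ch]])
    at <- pos0[i] + 1L
    oi <- match(as.integer(r[at]), as.integer(raws))
    ni <- ((oi - 1L + sample.int(3L, length(oi), replace = TRUE)) %% 4L) + 1L
    r[at] <- raws[ni]
    seqs[[ch]] <- rawToChar(r)
    new[i] <- .BASES[ni]
  }
  list(seqs = seqs, new = new)
}

# Bernoulli(p) subset of candidate positions
.drawSites <- function(n, p) {
  if (p <= 0 || n == 0L) return(integer())
  which(runif(n) < p)
}

# place gene lengths on chromosomes without overlap; returns data.frame
.placeGenes <- function(nChrom, chromLength, lengths) {
  chrom_of <- rep(seq_len(nChrom), length.out = length(lengths))
  out <- vector("list", nChrom)
  for (ch in seq_len(nChrom)) {
    lens <- lengths[chrom_of == ch]
    if (!length(lens)) next
    free <- chromLength - sum(lens)
    if (free < 0) {
      stop("requested genes exceed chromosome capacity on chrom ", ch)
    }
    offs <- sort(sample.int(free + 1L, length(lens), replace = TRUE) - 1L)
    starts <- offs + cumsum(c(0L, lens[-length(lens)]))
    out[[ch]] <- data.frame(chrom = paste0("chr", ch), start = starts,
                            end = starts + lens)
  }
  do.call(rbind, out)
}

#' Generate a synthetic progenitor/allopolyploid triad with full truth
#'
#' Simulates, from one common ancestor genome: a congeneric mapping reference
#' (the analogue of a sequenced reference genome), the founding haplotypes of
#' the two diploid progenitors, and the two subgenomes of the allopolyploid.
#' Progenitor divergence is drawn per transcribed site, so the DDP catalog is
#' exactly the set of sites at which the two founding haplotypes differ.
#' Paleo-duplicates are extra reference genes copied from a partner gene and
#' diverged at `paleoDivergence`; they are tagged in the gene-model table so
#' downstream paralogue screens can be exercised.
#'
#' @param config a [SimulationConfig-class].
#' @return A [TriadSimulation-class] object.
#' @examples
#' tri <- generateTriad(SimulationConfig(nChromosomes = 1L,
#'   chromLength = 20000L, nGenes = 8L, geneLength = 1200L, seed = 7L))
#' tri
#' head(ddpCatalog(tri))
#' @export
generateTriad <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@seed)
  nChrom <- config@nChromosomes
  clen <- config@chromLength

  # gene lengths (multiples of 3), primaries then paleo-duplicates
  nDup <- as.integer(round(config@paleoDupFraction * config@nGenes))
  nAll <- config@nGenes + nDup
  if (length(config@geneLength) == 2L) {
    lens <- sample(config@geneLength[1]:config@geneLength[2], nAll,
                   replace = TRUE)
  } else {
    lens <- rep(config@geneLength, nAll)
  }
  lens <- pmax(3L, (lens %/% 3L) * 3L)
  if (nDup) lens[config@nGenes + seq_len(nDup)] <- lens[seq_len(nDup)]

  loc <- .placeGenes(nChrom, clen, lens)
  ids <- c(sprintf("g%04d", seq_len(config@nGenes)),
           if (nDup) sprintf("g%04d.p", seq_len(nDup)))
  genes <- data.frame(
    gene_id = ids,
    chrom = loc$chrom, start = loc$start, end = loc$end,
    strand = sample(c("+", "-"), nAll, replace = TRUE),
    cds_frame = 0L,
    class = rep(c("primary", "paleo_dup"), c(config@nGenes, nDup)),
    paleo_pair = NA_character_,
    stringsAsFactors = FALSE
  )
  if (nDup) {
    pri <- seq_len(nDup)
    dup <- config@nGenes + seq_len(nDup)
    genes$paleo_pair[pri] <- genes$gene_id[dup]
    genes$paleo_pair[dup] <- genes$gene_id[pri]
  }

  # ancestor genome
  anc <- lapply(seq_len(nChrom), function(i)
    paste(sample(.BASES, clen, replace = TRUE), collapse = ""))
  names(anc) <- paste0("chr", seq_len(nChrom))

  # paleo-duplicates: overwrite the duplicate's region with a mutated copy
  # of its partner, so the pair is recognizably homologous
  if (nDup) {
    for (j in seq_len(nDup)) {
      src <- genes[j, ]
      dst <- genes[config@nGenes + j, ]
      seq <- substring(anc[[src$chrom]], src$start + 1L, src$end)
      L <- dst$end - dst$start
      seq <- substring(seq, 1L, L)  # partner lengths are equal by design
      at <- .drawSites(L, config@paleoDivergence)
      if (length(at)) {
        tmp <- list(s = seq)
        names(tmp) <- "s"
        tmp <- .mutateAt(tmp, rep("s", length(at)), at - 1L)
        seq <- tmp$seqs[["s"]]
      }
      a <- anc[[dst$chrom]]
      anc[[dst$chrom]] <- paste0(substring(a, 1L, dst$start), seq,
                                 substring(a, dst$end + 1L, nchar(a)))
    }
  }

  # transcribed positions per chromosome (0-based), with the owning gene
  tp <- do.call(rbind, lapply(seq_len(nAll), function(i) {
    g <- genes[i, ]
    data.frame(chrom = g$chrom, pos = seq.int(g$start, g$end - 1L),
               gene_id = g$gene_id,
               tpos = if (g$strand == "+") seq.int(0L, g$end - g$start - 1L)
                      else seq.int(g$end - g$start - 1L, 0L),
               stringsAsFactors = FALSE)
  }))

  # reference lineage: genome-wide substitutions
  ref <- anc
  if (config@referenceDivergence > 0) {
    for (ch in names(ref)) {
      at <- .drawSites(clen, config@referenceDivergence)
      if (length(at))
        ref <- .mutateAt(ref, rep(ch, length(at)), at - 1L)$seqs
    }
  }

  # progenitor lineages: DDP sites drawn per transcribed site; each DDP
  # mutates exactly one progenitor away from the ancestor
  hapA <- anc
  hapB <- anc
  ddp_idx <- .drawSites(nrow(tp), config@progenitorDivergence)
  ddp <- tp[ddp_idx, , drop = FALSE]
  if (nrow(ddp)) {
    toA <- runif(nrow(ddp)) < 0.5
    if (any(toA)) {
      m <- .mutateAt(hapA, ddp$chrom[toA], ddp$pos[toA])
      hapA <- m$seqs
    }
    if (any(!toA)) {
      m <- .mutateAt(hapB, ddp$chrom[!toA], ddp$pos[!toA])
      hapB <- m$seqs
    }
    ddp$allele_A <- .baseAt(hapA, ddp$chrom, ddp$pos)
    ddp$allele_B <- .baseAt(hapB, ddp$chrom, ddp$pos)
  } else {
    ddp$allele_A <- character()
    ddp$allele_B <- character()
  }
  rownames(ddp) <- NULL
  ddp <- ddp[, c("chrom", "pos", "allele_A", "allele_B", "gene_id", "tpos")]

  # second haplotype of each diploid accession (heterozygosity of selfers)
  mutTx <- function(hap, rate) {
    at <- .drawSites(nrow(tp), rate)
    if (length(at)) .mutateAt(hap, tp$chrom[at], tp$pos[at])$seqs else hap
  }
  hapA2 <- mutTx(hapA, config@withinSpeciesPolymorphism)
  hapB2 <- mutTx(hapB, config@withinSpeciesPolymorphism)

  # allopolyploid subgenomes: founding haplotypes plus post-merger mutation
  subA <- mutTx(hapA, config@postMergerRate)
  subB <- mutTx(hapB, config@postMergerRate)

  # loss blocks: genes overlapping a block are deleted from that subgenome
  lost <- list(A = character(), B = character())
  lb <- config@lossBlocks
  if (nrow(lb)) {
    for (i in seq_len(nrow(lb))) {
      hit <- genes$chrom == lb$chrom[i] & genes$start < lb$end[i] &
        genes$end > lb$start[i]
      s <- lb$subgenome[i]
      lost[[s]] <- union(lost[[s]], genes$gene_id[hit])
    }
  }

  dss <- function(x) Biostrings::DNAStringSet(unlist(x))
  new("TriadSimulation",
      reference = dss(ref), genes = genes,
      progenitorA = dss(hapA), progenitorB = dss(hapB),
      progenitorA2 = dss(hapA2), progenitorB2 = dss(hapB2),
      polyploidA = dss(subA), polyploidB = dss(subB),
      ddp = ddp, lostGenes = lost, config = config)
}

.baseAt <- function(seqs, chrom, pos0) {
  out <- character(length(pos0))
  for (ch in unique(chrom)) {
    i <- chrom == ch
    out[i] <- substring(seqs[[ch]], pos0[i] + 1L, pos0[i] + 1L)
  }
  out
}

#' Extract gene transcripts from one genome of a triad
#'
#' Transcripts are contiguous (single-exon): the gene interval, reverse
#' complemented for minus-strand genes. For polyploid subgenomes, genes
#' removed by loss blocks are dropped.
#'
#' @param triad a [TriadSimulation-class].
#' @param genome which genome to extract from.
#' @return A named DNAStringSet, one entry per gene.
#' @export
getTranscripts <- function(triad,
                           genome = c("reference", "progenitorA",
                                      "progenitorB", "progenitorA2",
                                      "progenitorB2", "polyploidA",
                                      "polyploidB")) {
  genome <- match.arg(genome)
  chroms <- slot(triad, genome)
  genes <- triad@genes
  if (genome %in% c("polyploidA", "polyploidB")) {
    side <- if (genome == "polyploidA") "A" else "B"
    genes <- genes[!genes$gene_id %in% triad@lostGenes[[side]], ,
                   drop = FALSE]
  }
  if (!nrow(genes)) return(Biostrings::DNAStringSet())
  tx <- Biostrings::DNAStringSet(chroms[genes$chrom],
                                 start = genes$start + 1L, end = genes$end)
  minus <- genes$strand == "-"
  if (any(minus)) tx[minus] <- Biostrings::reverseComplement(tx[minus])
  names(tx) <- genes$gene_id
  tx
}

#' Simulate single-end reads from one member of a triad
#'
#' Reads are exact substrings of transcripts (reverse-orientation sequencing
#' is not simulated; the aligner's strand handling is exercised separately),
#' drawn uniformly over genes and start offsets, with i.i.d. substitution
#' errors. For the allopolyploid, the two subgenomes are sampled with equal
#' probability; for a diploid accession, its two haplotypes are. The
#' returned truth table records the origin of every read.
#'
#' @param triad a [TriadSimulation-class].
#' @param sample which accession to sequence.
#' @param nReads,readLength,errorRate override the config values.
#' @param seed seed for this sample's reads; defaults to the triad seed plus
#'   a fixed per-sample offset so each sample is reproducible.
#' @param degradedBases,degradedQuality if `degradedBases > 0`, that many
#'   3'-terminal bases are assigned Phred quality `degradedQuality` (the
#'   bases themselves are unchanged); all other bases are Q40. Exercises
#'   quality trimming.
#' @param prefix read-name prefix.
#' @return list(reads = QualityScaledDNAStringSet, truth = data.frame with
#'   read_id, origin ("A"/"B" for the polyploid, "hap1"/"hap2" for a
#'   diploid), gene_id, start, strand).
#' @export
simulateReads <- function(triad,
                          sample = c("polyploid", "progenitorA",
                                     "progenitorB"),
                          nReads = NULL, readLength = NULL, errorRate = NULL,
                          seed = NULL, degradedBases = 0L,
                          degradedQuality = 2L, prefix = NULL) {
  sample <- match.arg(sample)
  cfg <- triad@config
  if (is.null(nReads)) nReads <- cfg@nReads
  if (is.null(readLength)) readLength <- cfg@readLength
  if (is.null(errorRate)) errorRate <- cfg@errorRate
  if (is.null(seed)) {
    seed <- cfg@seed + match(sample, c("progenitorA", "progenitorB",
                                       "polyploid"))
  }
  if (is.null(prefix)) prefix <- sample
  set.seed(seed)

  pools <- switch(sample,
    polyploid = list(A = getTranscripts(triad, "polyploidA"),
                     B = getTranscripts(triad, "polyploidB")),
    progenitorA = list(hap1 = getTranscripts(triad, "progenitorA"),
                       hap2 = getTranscripts(triad, "progenitorA2")),
    progenitorB = list(hap1 = getTranscripts(triad, "progenitorB"),
                       hap2 = getTranscripts(triad, "progenitorB2")))
  pools <- lapply(pools, as.character)
  widths <- lapply(pools, nchar)
  for (w in widths) {
    if (length(w) && min(w) < readLength)
      stop("readLength exceeds the shortest transcript")
  }
  if (nReads == 0L) {
    empty <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(),
      Biostrings::PhredQuality(character()))
    return(list(reads = empty,
                truth = data.frame(read_id = character(),
                                   origin = character(),
                                   gene_id = character(), start = integer(),
                                   strand = character())))
  }

  origin <- names(pools)[sample.int(2L, nReads, replace = TRUE)]
  gidx <- integer(nReads)
  gene <- character(nReads)
  off <- integer(nReads)
  seqs <- character(nReads)
  for (o in names(pools)) {
    i <- which(origin == o)
    if (!length(i)) next
    pool <- pools[[o]]
    gi <- sample.int(length(pool), length(i), replace = TRUE)
    maxoff <- widths[[o]][gi] - readLength
    oo <- floor(runif(length(i)) * (maxoff + 1L))
    seqs[i] <- substring(pool[gi], oo + 1L, oo + readLength)
    gene[i] <- names(pool)[gi]
    off[i] <- as.integer(oo)
  }

  # substitution errors
  if (errorRate > 0) {
    nerr <- rbinom(1L, nReads * readLength, errorRate)
    if (nerr > 0L) {
      at <- sample.int(nReads * readLength, nerr)
      rd <- (at - 1L) %/% readLength + 1L
      pp <- (at - 1L) %% readLength + 1L
      raws <- charToRaw("ACGT")
      for (r in unique(rd)) {
        p <- pp[rd == r]
        x <- charToRaw(seqs[r])
        oi <- match(as.integer(x[p]), as.integer(raws))
        ni <- ((oi - 1L + sample.int(3L, length(p), replace = TRUE)) %% 4L) + 1L
        x[p] <- raws[ni]
        seqs[r] <- rawToChar(x)
      }
    }
  }

  qual <- strrep(rawToChar(as.raw(33L + 40L)), readLength)
  if (degradedBases > 0L) {
    qual <- paste0(strrep(rawToChar(as.raw(33L + 40L)),
                          readLength - degradedBases),
                   strrep(rawToChar(as.raw(33L + degradedQuality)),
                          degradedBases))
  }
  ids <- sprintf("%s_r%06d", prefix, seq_len(nReads))
  reads <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs),
    Biostrings::PhredQuality(rep(qual, nReads)))
  names(reads) <- ids
  list(reads = reads,
       truth = data.frame(read_id = ids, origin = origin, gene_id = gene,
                          start = off, strand = "+",
                          stringsAsFactors = FALSE))
}

#' Write a triad to disk as FASTA + TSV
#'
#' Writes the reference and all haplotype/subgenome chromosome sets as FASTA,
#' the gene models and DDP catalog as TSV.
#'
#' @param triad a [TriadSimulation-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
exportTriad <- function(triad, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  slots <- c("reference", "progenitorA", "progenitorB", "polyploidA",
             "polyploidB")
  for (s in slots) {
    Biostrings::writeXStringSet(slot(triad, s),
                                file.path(dir, paste0(s, ".fa")))
  }
  write.table(triad@genes, file.path(dir, "genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(triad@ddp, file.path(dir, "ddp_catalog.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Simulate a single-gene multiple alignment for screening experiments
#'
#' Evolves sequences down a star-like genealogy: each ingroup tip diverges
#' from the root by `ingroupDivergence`, the outgroup by
#' `outgroupDivergence`, and (optionally) `paralogs` ingroup tips are
#' replaced by deep paralogues diverged by `paralogDivergence` -- the
#' signature of sampling the wrong member of an old duplicate pair.
#'
#' @param nIngroup number of ingroup sequences.
#' @param length alignment length (bp).
#' @param ingroupDivergence,outgroupDivergence,paralogDivergence
#'   substitutions/site from the root.
#' @param paralogs how many ingroup tips carry the deep paralogue.
#' @param seed optional seed.
#' @return A named DNAStringSet; the outgroup is named "OUT".
#' @export
simulateGeneAlignment <- function(nIngroup = 10L, length = 1200L,
                                  ingroupDivergence = 0.01,
                                  outgroupDivergence = 0.05,
                                  paralogs = 0L, paralogDivergence = 0.30,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  root <- paste(sample(.BASES, length, replace = TRUE), collapse = "")
  evolve <- function(s, rate) {
    at <- .drawSites(nchar(s), rate)
    if (!length(at)) return(s)
    tmp <- list(s = s)
    .mutateAt(tmp, rep("s", length(at)), at - 1L)$seqs[["s"]]
  }
  paralogRoot <- evolve(root, paralogDivergence)
  tips <- vapply(seq_len(nIngroup), function(i) {
    base <- if (i <= paralogs) paralogRoot else root
    evolve(base, ingroupDivergence)
  }, character(1))
  out <- evolve(root, outgroupDivergence)
  res <- Biostrings::DNAStringSet(c(tips, out))
  names(res) <- c(sprintf("ing%02d", seq_len(nIngroup)), "OUT")
  res
}
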