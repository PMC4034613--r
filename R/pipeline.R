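#' Run the full triad workflow on a synthetic simulation
#'
#' Convenience driver that chains every stage on one simulated triad:
#' simulate diploid and polyploid reads; align the diploid accessions to the
#' reference transcripts, call their SNPs and build the two species-group
#' consensus transcriptomes; call SNPs on the unseparated polyploid sample;
#' join the consensus sets into a progenitor reference, classify the
#' polyploid reads by preferential mapping, rebuild the two subgenome
#' consensus transcriptomes, and recall subgenome SNPs by re-mapping each
#' partition to the reference.
#'
#' @param config a [SimulationConfig-class]; `config@nReads` is the
#'   polyploid read count.
#' @param nDiploidReads reads simulated per diploid progenitor accession.
#' @param k seed length for all alignment passes.
#' @param consensusMinDepth masking depth for all consensus builds.
#' @param includeShared use SHARED reads in the subgenome assemblies.
#' @return list with: triad, reads (named list of read/truth pairs),
#'   diploidCalls (list of [VariantCallSet-class]), polyCalls (unseparated
#'   polyploid [VariantCallSet-class]), consensus (list A/B), progref,
#'   assignments, report, subgenomeConsensus, recall (named list of
#'   [VariantCallSet-class]), alignments (filtered alignment records per
#'   sample).
#' @export
runTriadPipeline <- function(config, nDiploidReads = 100000L, k = 20L,
                             consensusMinDepth = 3L, includeShared = TRUE) {
  triad <- generateTriad(config)
  tx <- getTranscripts(triad, "reference")
  idx <- seedIndex(tx, k = k)

  dipA <- simulateReads(triad, "progenitorA", nReads = nDiploidReads)
  dipB <- simulateReads(triad, "progenitorB", nReads = nDiploidReads)
  poly <- simulateReads(triad, "polyploid")

  fltA <- filterAlignments(alignReads(dipA$reads, idx))
  fltB <- filterAlignments(alignReads(dipB$reads, idx))
  fltP <- filterAlignments(alignReads(poly$reads, idx))

  callA <- pileupAndCall(fltA, dipA$reads, tx, sample = "dipA")
  callB <- pileupAndCall(fltB, dipB$reads, tx, sample = "dipB")
  callP <- pileupAndCall(fltP, poly$reads, tx, sample = "poly")

  consA <- buildGroupConsensus(fltA, dipA$reads, tx, group = "A",
                               minDepth = consensusMinDepth)
  consB <- buildGroupConsensus(fltB, dipB$reads, tx, group = "B",
                               minDepth = consensusMinDepth)

  progref <- buildProgenitorReference(consA, consB, labels = c("A", "B"))
  assignments <- classifyReads(alignToProgenitors(poly$reads, progref,
                                                  k = k), progref)
  assembled <- partitionAndAssemble(poly$reads, assignments, tx,
                                    labels = c("A", "B"),
                                    includeShared = includeShared,
                                    minDepth = consensusMinDepth)
  recall <- subgenomeSnpRecall(poly$reads, assignments, tx,
                               sampleBase = "poly", k = k)

  list(triad = triad,
       reads = list(progenitorA = dipA, progenitorB = dipB,
                    polyploid = poly),
       diploidCalls = list(A = callA, B = callB),
       polyCalls = callP,
       consensus = list(A = consA, B = consB),
       progref = progref,
       assignments = assignments,
       report = assembled$report,
       subgenomeConsensus = assembled[c("consensusA", "consensusB")],
       recall = recall,
       alignments = list(A = fltA, B = fltB, poly = fltP))
}

#' Count truth DDPs overlapped by each simulated read
#'
#' For each read of a truth table, the number of catalog DDP sites that fall
#' within the read's transcript interval. Reads overlapping zero DDPs carry
#' no subgenome information and must never receive a progenitor label.
#'
#' @param triad the [TriadSimulation-class] the reads came from.
#' @param truth a truth table from [simulateReads()].
#' @param readLength the simulated read length.
#' @return Integer vector parallel to `truth` rows.
#' @export
countTruthDdp <- function(triad, truth, readLength) {
  ddpByGene <- split(triad@ddp$tpos, triad@ddp$gene_id)
  n <- nrow(truth)
  out <- integer(n)
  byGene <- split(seq_len(n), truth$gene_id)
  for (g in names(byGene)) {
    tp <- ddpByGene[[g]]
    if (is.null(tp)) next
    i <- byGene[[g]]
    s <- truth$start[i]
    out[i] <- vapply(s, function(x) sum(tp >= x & tp < x + readLength),
                     integer(1))
  }
  out
}

#' Subgenome-tagged SNPs implied by the simulation truth
#'
#' For every DDP site, a tagged SNP is produced for each subgenome whose
#' allele differs from the reference base at that position (mirroring what a
#' perfect subgenome SNP recall against the reference would report at DDP
#' sites).
#'
#' @param triad a [TriadSimulation-class].
#' @param dropLost drop sites of a subgenome inside its loss blocks
#'   (default TRUE: a lost region yields no reads, hence no SNPs).
#' @return data.frame chrom, pos, label ("A"/"B") suitable for [binSnps()].
#' @export
truthTaggedSnps <- function(triad, dropLost = TRUE) {
  ddp <- triad@ddp
  if (!nrow(ddp)) {
    return(data.frame(chrom = character(), pos = integer(),
                      label = character()))
  }
  refb <- .baseAt(as.list(as.character(triad@reference)), ddp$chrom,
                  ddp$pos)
  rows <- list()
  for (side in c("A", "B")) {
    allele <- if (side == "A") ddp$allele_A else ddp$allele_B
    keep <- allele != refb
    if (dropLost) keep <- keep & !ddp$gene_id %in% triad@lostGenes[[side]]
    rows[[side]] <- data.frame(chrom = ddp$chrom[keep], pos = ddp$pos[keep],
                               label = side, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
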