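# The core analysis: sort allopolyploid reads into homoeologous subgenomes
# by preferential mapping against the joined progenitor reference, rebuild
# per-subgenome transcriptomes, and recall subgenome SNPs.

#' Join two progenitor consensus sets into a classification reference
#'
#' Targets are the union of the two consensus transcript sets, aligned on
#' gene id; a gene present in only one set is kept on that side only. Both
#' sides must be non-empty. Sequences of genes shared by both sides must
#' have equal length (they are rebuilt on the same reference gene models).
#'
#' @param consA,consB [ConsensusSet-class] objects (or named DNAStringSet /
#'   named character vectors) for the two putative progenitors.
#' @param labels the two progenitor labels, e.g. c("D3", "D4").
#' @return A [ProgenitorReference-class].
#' @export
buildProgenitorReference <- function(consA, consB, labels = c("A", "B")) {
  getseqs <- function(x) {
    if (is(x, "ConsensusSet")) x <- x@sequences
    s <- .asNamedChars(x)
    if (!length(s))
      stop("both progenitor consensus sets must be non-empty")
    if (is.null(names(s))) stop("consensus sequences must be named by gene")
    if (anyDuplicated(names(s))) stop("duplicate (label, gene) pairs")
    s
  }
  a <- getseqs(consA)
  b <- getseqs(consB)
  genes <- union(names(a), names(b))
  shared <- intersect(names(a), names(b))
  if (any(nchar(a[shared]) != nchar(b[shared])))
    stop("shared genes must have equal consensus lengths")
  new("ProgenitorReference", genes = genes,
      seqA = unname(a[genes]), seqB = unname(b[genes]),
      labels = as.character(labels))
}

#' Number of targets in a progenitor reference
#' @param progref a [ProgenitorReference-class].
#' @return Integer: targets on side A + targets on side B.
#' @export
progenitorTargets <- function(progref) {
  c(sum(!is.na(progref@seqA)), sum(!is.na(progref@seqB)))
}

#' Score reads against both sides of a progenitor reference
#'
#' Candidate placements (gene, offset, strand) are collected by exact
#' 20-mer seeding in either progenitor consensus; each candidate is scored
#' against both consensus sequences over the same columns, excluding columns
#' where the read or either present consensus carries an N. Ns therefore
#' carry no assignment information: a read can only be preferred by one
#' progenitor through actual base differences. The best candidate by
#' max(AS_A, AS_B) is reported (ties broken by gene, offset, strand).
#'
#' @param reads polyploid reads (QualityScaledDNAStringSet, DNAStringSet or
#'   named character).
#' @param progref a [ProgenitorReference-class].
#' @param k seed length (default 20).
#' @param mismatchPenalty mismatch penalty (default 6; AS = 0 is perfect).
#' @return data.frame: read_id, gene_id, start, strand, AS_A, AS_B
#'   (NA where the gene is absent from a side), mm_A, mm_B. Unmapped reads
#'   have NA in all alignment columns.
#' @export
alignToProgenitors <- function(reads, progref, k = 20L,
                               mismatchPenalty = 6L) {
  seqs <- .asNamedChars(reads)
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(seqs))
  res <- .cpp_classify(progref@seqA, progref@seqB, unname(seqs),
                       as.integer(k), as.integer(mismatchPenalty))
  data.frame(read_id = ids,
             gene_id = progref@genes[res$gene],
             start = res$start, strand = res$strand,
             AS_A = res$AS_A, AS_B = res$AS_B,
             mm_A = res$mm_A, mm_B = res$mm_B,
             stringsAsFactors = FALSE)
}

#' Classify reads into subgenomes by preferential mapping
#'
#' One label per read: no candidate placement gives UNMAPPED; a strictly
#' better best score on one progenitor gives that progenitor's label
#' (PROG_A/PROG_B, reported with the reference's own labels); equal best
#' scores with zero mismatches on both sides (a perfect match to both,
#' i.e. no distinguishing polymorphism) gives SHARED; equal best scores with
#' at least one mismatch gives AMBIGUOUS (the read cannot be attributed to a
#' progenitor). A gene present on one side only can only support that side's
#' label.
#'
#' @param aln output of [alignToProgenitors()] (one row per read; duplicate
#'   read ids are an error).
#' @param progref the [ProgenitorReference-class] used (for label names).
#' @return data.frame: read_id, label, AS_A, AS_B, mismatches, gene_id,
#'   start, strand.
#' @export
classifyReads <- function(aln, progref) {
  if (anyDuplicated(aln$read_id))
    stop("one row per read expected; duplicate read ids found")
  la <- paste0("PROG_", progref@labels[1])
  lb <- paste0("PROG_", progref@labels[2])
  sa <- aln$AS_A
  sb <- aln$AS_B
  label <- rep("UNMAPPED", nrow(aln))
  bothNA <- is.na(sa) & is.na(sb)
  onlyA <- !is.na(sa) & is.na(sb) & !is.na(aln$gene_id)
  onlyB <- is.na(sa) & !is.na(sb) & !is.na(aln$gene_id)
  both <- !is.na(sa) & !is.na(sb)
  label[onlyA] <- la
  label[onlyB] <- lb
  label[both & sa > sb] <- la
  label[both & sb > sa] <- lb
  eq <- both & sa == sb
  shared <- eq & aln$mm_A == 0L & aln$mm_B == 0L
  label[shared] <- "SHARED"
  label[eq & !shared] <- "AMBIGUOUS"
  label[bothNA] <- "UNMAPPED"
  mm <- ifelse(label == la, aln$mm_A,
               ifelse(label == lb, aln$mm_B,
                      pmin(aln$mm_A, aln$mm_B)))
  data.frame(read_id = aln$read_id, label = label,
             AS_A = sa, AS_B = sb, mismatches = mm,
             gene_id = aln$gene_id, start = aln$start, strand = aln$strand,
             stringsAsFactors = FALSE)
}

#' Partition reads by subgenome and rebuild subgenome transcriptomes
#'
#' For each progenitor label, a consensus transcriptome is rebuilt (majority
#' base per column, ties to the reference) from the reads carrying that
#' label plus, by default, the SHARED reads (which match both progenitors
#' perfectly and support either subgenome); AMBIGUOUS and UNMAPPED reads are
#' excluded. The report gives the fraction of reads per label.
#'
#' @param reads the polyploid reads.
#' @param assignments output of [classifyReads()].
#' @param reference named DNAStringSet of reference gene transcripts (the
#'   coordinate frame of the consensus; ties fall back to these bases).
#' @param labels the two progenitor labels in (A, B) order; derived from the
#'   assignment labels when NULL.
#' @param includeShared use SHARED reads in both subgenome assemblies
#'   (default TRUE).
#' @param minDepth consensus masking depth (default 3; see
#'   [buildGroupConsensus()]).
#' @return list(consensusA, consensusB = [ConsensusSet-class],
#'   report = data.frame(label, reads, fraction)).
#' @export
partitionAndAssemble <- function(reads, assignments, reference,
                                 labels = NULL, includeShared = TRUE,
                                 minDepth = 3L) {
  progLabels <- labels
  if (is.null(progLabels)) {
    progLabels <- sort(unique(sub("^PROG_", "", assignments$label[
      startsWith(assignments$label, "PROG_")])))
  }
  report <- as.data.frame(table(factor(assignments$label)),
                          stringsAsFactors = FALSE)
  names(report) <- c("label", "reads")
  report$fraction <- report$reads / max(1L, nrow(assignments))
  mkrecords <- function(rows) {
    data.frame(read_id = rows$read_id, target_id = rows$gene_id,
               start = rows$start, strand = rows$strand,
               stringsAsFactors = FALSE)
  }
  buildSide <- function(sideLabel, group) {
    keep <- assignments$label == paste0("PROG_", sideLabel) |
      (includeShared & assignments$label == "SHARED")
    rows <- assignments[keep & !is.na(assignments$gene_id), , drop = FALSE]
    buildGroupConsensus(mkrecords(rows), reads, reference, group = group,
                        minDepth = minDepth)
  }
  if (length(progLabels) < 2L) progLabels <- c("A", "B")
  list(consensusA = buildSide(progLabels[1], progLabels[1]),
       consensusB = buildSide(progLabels[2], progLabels[2]),
       report = report)
}

#' Re-map partitioned reads to the reference and recall subgenome SNPs
#'
#' Each subgenome read set is treated as an independent sample: aligned to
#' the reference transcripts with the standard scoring, filtered on
#' preferential mapping and mapq, and passed through the pileup caller.
#' SHARED reads carry no distinguishing information and are excluded by
#' default (set `includeShared = TRUE` to add them to both samples).
#'
#' @param reads the polyploid reads.
#' @param assignments output of [classifyReads()].
#' @param reference named DNAStringSet of reference gene transcripts.
#' @param sampleBase prefix for the derived sample ids; the two call sets
#'   are named `<sampleBase>-<label>` (e.g. "T2-D3").
#' @param includeShared also use SHARED reads in both samples.
#' @param minMapq mapq filter applied on the back-mapping (default 20).
#' @param minDepth,homFraction,minAlleleCount see [pileupAndCall()].
#' @param k seed length for the back-mapping.
#' @return named list of [VariantCallSet-class], one per subgenome label.
#' @export
subgenomeSnpRecall <- function(reads, assignments, reference,
                               sampleBase = "poly", includeShared = FALSE,
                               minMapq = 20L, minDepth = 5L,
                               homFraction = 0.8, minAlleleCount = 2L,
                               k = 20L) {
  labs <- sort(unique(sub("^PROG_", "", assignments$label[
    startsWith(assignments$label, "PROG_")])))
  idx <- seedIndex(reference, k = k)
  seqs <- .asNamedChars(reads)
  out <- list()
  for (lab in labs) {
    keep <- assignments$label == paste0("PROG_", lab) |
      (includeShared & assignments$label == "SHARED")
    ids <- assignments$read_id[keep]
    sub <- seqs[ids]
    rec <- alignReads(sub, idx)
    rec <- filterAlignments(rec, minMapq = minMapq)
    out[[paste0(sampleBase, "-", lab)]] <-
      pileupAndCall(rec, sub, reference,
                    sample = paste0(sampleBase, "-", lab),
                    minDepth = minDepth, homFraction = homFraction,
                    minAlleleCount = minAlleleCount)
  }
  out
}
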