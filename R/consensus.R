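#' Build a species-group consensus transcriptome
#'
#' Per reference gene and position, the majority base among covering reads;
#' positions with coverage below `minDepth` (default 1, i.e. only
#' zero-coverage positions) are masked to N; majority ties resolve to the
#' reference base so the consensus stays unambiguous for re-alignment.
#' Records typically pool all accessions of a species group.
#'
#' @param records filtered alignment records (all accessions of the group).
#' @param reads the aligned reads (named; pooled across accessions).
#' @param reference named DNAStringSet of reference gene transcripts.
#' @param group species-group label (e.g. "D3").
#' @param minDepth positions covered by fewer reads than this are masked to
#'   N. The subgenome-sorting pipeline uses 3 so that an isolated read error
#'   cannot fix a wrong base.
#' @return A [ConsensusSet-class].
#' @export
buildGroupConsensus <- function(records, reads, reference, group = "G1",
                                minDepth = 1L) {
  counts <- .pileupMatrices(records, reads, reference)
  refseq <- as.character(reference)
  out <- character(length(counts))
  stats <- vector("list", length(counts))
  for (t in seq_along(counts)) {
    m <- counts[[t]][1:4, , drop = FALSE]
    L <- ncol(m)
    depth <- colSums(m)
    refb <- match(strsplit(refseq[t], "")[[1]], .BASES)
    refMask <- matrix(0, 4, L)
    ok <- !is.na(refb)
    refMask[cbind(refb[ok], which(ok))] <- 0.5
    top <- max.col(t(m + refMask), "first")
    cons <- .BASES[top]
    cons[depth < minDepth] <- "N"
    out[t] <- paste(cons, collapse = "")
    nN <- sum(cons == "N")
    stats[[t]] <- data.frame(gene_id = names(reference)[t], length = L,
                             n_count = nN, n_fraction = nN / L,
                             covered_length = L - nN,
                             stringsAsFactors = FALSE)
  }
  seqs <- Biostrings::DNAStringSet(out)
  names(seqs) <- names(reference)
  new("ConsensusSet", sequences = seqs, group = group,
      stats = do.call(rbind, stats))
}

#' Per-gene consensus quality statistics and pass/fail
#'
#' A gene is full-length when its consensus has no Ns; it passes when its
#' length is at least `minLen` and its N fraction is at most `maxNFraction`
#' (both boundaries inclusive: "at least 1000 bp", "no more than 10% Ns";
#' set `strict = TRUE` for a strict < on the N fraction).
#'
#' @param consensus a [ConsensusSet-class].
#' @param minLen minimum alignment length (default 1000 bp).
#' @param maxNFraction maximum N fraction (default 0.10).
#' @param strict use a strict inequality for the N fraction.
#' @return data.frame: gene_id, length, n_fraction, full_length, pass.
#' @export
consensusStats <- function(consensus, minLen = 1000L, maxNFraction = 0.10,
                           strict = FALSE) {
  s <- consensus@stats
  nOk <- if (strict) s$n_fraction < maxNFraction
         else s$n_fraction <= maxNFraction
  data.frame(gene_id = s$gene_id, length = s$length,
             n_fraction = s$n_fraction,
             full_length = s$n_count == 0L,
             pass = s$length >= minLen & nOk,
             stringsAsFactors = FALSE)
}
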