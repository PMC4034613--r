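# Pileup-based SNP calling, multi-sample merging, format export, functional
# annotation and per-sample summaries.

# per-target 5 x L base-count matrices (rows A,C,G,T,N) from alignments;
# reads are oriented to the target strand before counting
.pileupMatrices <- function(records, reads, reference) {
  seqs <- .asNamedChars(reads)
  missing <- !records$read_id %in% names(seqs)
  if (any(missing)) {
    stop("alignment read id(s) not found among the reads: ",
         paste(head(unique(records$read_id[missing]), 5), collapse = ", "))
  }
  tidx <- match(records$target_id, names(reference))
  if (anyNA(tidx)) {
    bad <- unique(records$target_id[is.na(tidx)])
    stop("alignment target(s) not present in reference: ",
         paste(head(bad, 5), collapse = ", "))
  }
  oriented <- unname(seqs[records$read_id])
  minus <- records$strand == "-"
  if (any(minus)) {
    oriented[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(oriented[minus])))
  }
  .cpp_pileup(Biostrings::width(reference), tidx, records$start, oriented)
}

#' Call SNPs from filtered alignments by pileup
#'
#' Per column, alleles supported by at least `minAlleleCount` reads are
#' considered; a site is emitted iff at least one non-reference allele
#' passes and the total read coverage is at least `minDepth`. The genotype
#' is homozygous in the top allele when its fraction of called bases is at
#' least `homFraction`, otherwise heterozygous in the top two alleles
#' (ties prefer the reference base, then alphabetical order).
#'
#' @param records alignment data.frame, already passed through
#'   [filterAlignments()].
#' @param reads the aligned reads (named).
#' @param reference named DNAStringSet of the targets aligned against.
#' @param sample sample identifier.
#' @param minDepth minimum coverage to call a site (default 5).
#' @param homFraction top-allele fraction at or above which the genotype is
#'   homozygous (default 0.8).
#' @param minAlleleCount minimum reads supporting an allele (default 2).
#' @return A [VariantCallSet-class] (calls plus per-position coverage, which
#'   [mergeCalls()] uses to distinguish homozygous-reference from missing).
#' @export
pileupAndCall <- function(records, reads, reference, sample = "S1",
                          minDepth = 5L, homFraction = 0.8,
                          minAlleleCount = 2L) {
  counts <- .pileupMatrices(records, reads, reference)
  refseq <- as.character(reference)
  out <- vector("list", length(counts))
  coverage <- vector("list", length(counts))
  names(coverage) <- names(reference)
  for (t in seq_along(counts)) {
    m <- counts[[t]]
    depth <- colSums(m)
    coverage[[t]] <- depth
    acgt <- m[1:4, , drop = FALSE]
    depth4 <- colSums(acgt)
    refb <- match(strsplit(refseq[t], "")[[1]], .BASES)  # NA for N in ref
    L <- ncol(m)
    refMask <- matrix(0, 4, L)
    ok <- !is.na(refb)
    refMask[cbind(refb[ok], which(ok))] <- 0.5
    bumped <- acgt + refMask
    top <- max.col(t(bumped), "first")
    topCount <- acgt[cbind(top, seq_len(L))]
    b2 <- bumped
    b2[cbind(top, seq_len(L))] <- -1
    second <- max.col(t(b2), "first")
    secondCount <- acgt[cbind(second, seq_len(L))]
    cand <- acgt >= minAlleleCount
    nonrefCand <- colSums(cand) - ifelse(ok, cand[cbind(refb, seq_len(L))]
                                         + 0L, 0L)
    emit <- which(depth >= minDepth & nonrefCand >= 1L & depth4 > 0L)
    if (!length(emit)) next
    hom <- topCount[emit] / depth4[emit] >= homFraction
    a1 <- .BASES[top[emit]]
    a2 <- ifelse(hom, a1, .BASES[second[emit]])
    g <- ifelse(a1 <= a2, paste(a1, a2, sep = "/"), paste(a2, a1, sep = "/"))
    alt <- vapply(emit, function(j) {
      al <- .BASES[cand[, j]]
      paste(setdiff(al, .BASES[refb[j]]), collapse = ",")
    }, character(1))
    out[[t]] <- data.frame(
      target = names(reference)[t], pos = emit - 1L,
      ref = .BASES[refb[emit]], alt = alt, genotype = g,
      depth = as.integer(depth[emit]), stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, out)
  if (is.null(calls)) {
    calls <- data.frame(target = character(), pos = integer(),
                        ref = character(), alt = character(),
                        genotype = character(), depth = integer(),
                        stringsAsFactors = FALSE)
  }
  new("VariantCallSet", calls = calls, coverage = coverage, sample = sample,
      targets = setNames(Biostrings::width(reference), names(reference)))
}

.isHet <- function(genotype) {
  a <- strsplit(genotype, "/", fixed = TRUE)
  vapply(a, function(x) x[1] != x[2], logical(1))
}

#' Merge per-sample variant calls into a genotype matrix
#'
#' Sites are the union across samples. A sample without a call at a site is
#' genotyped homozygous-reference if its coverage there is at least
#' `minDepth`, and missing (NA) otherwise. Merging is order-independent up
#' to sample (column) order.
#'
#' @param callsets list of [VariantCallSet-class] objects (same reference).
#' @param minDepth coverage needed to assert homozygous-reference.
#' @return A [GenotypeMatrix-class] with chrom = target (transcript) names;
#'   see [liftGenotypeMatrix()] to move to genome coordinates.
#' @export
mergeCalls <- function(callsets, minDepth = 5L) {
  samples <- vapply(callsets, function(x) x@sample, character(1))
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  allc <- do.call(rbind, lapply(callsets, function(x) x@calls))
  key <- paste(allc$target, allc$pos)
  sites <- allc[!duplicated(key), c("target", "pos", "ref"), drop = FALSE]
  # union of alternative alleles per site
  altsplit <- strsplit(allc$alt, ",", fixed = TRUE)
  sitekeys <- rep(key, lengths(altsplit))
  altvec <- tapply(unlist(altsplit, use.names = FALSE), sitekeys,
                   function(x) paste(sort(unique(x[nzchar(x)])),
                                     collapse = ","))
  ord <- order(sites$target, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  skey <- paste(sites$target, sites$pos)
  geno <- matrix(NA_character_, nrow(sites), length(callsets))
  for (j in seq_along(callsets)) {
    cs <- callsets[[j]]
    k <- paste(cs@calls$target, cs@calls$pos)
    hit <- match(skey, k)
    geno[, j] <- cs@calls$genotype[hit]
    fill <- which(is.na(hit))
    if (length(fill)) {
      cov <- vapply(fill, function(i) {
        v <- cs@coverage[[sites$target[i]]]
        if (is.null(v)) 0L else v[sites$pos[i] + 1L]
      }, numeric(1))
      hr <- fill[cov >= minDepth]
      geno[hr, j] <- paste(sites$ref[hr], sites$ref[hr], sep = "/")
    }
  }
  rownames(geno) <- NULL
  colnames(geno) <- samples
  sites <- data.frame(chrom = sites$target, pos = sites$pos,
                      ref = sites$ref,
                      alt = unname(altvec[skey]),
                      stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  new("GenotypeMatrix", geno = geno, sites = sites, samples = samples)
}

.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.compGenotype <- function(g) {
  a <- strsplit(g, "/", fixed = TRUE)
  vapply(a, function(x) {
    if (anyNA(x)) return(NA_character_)
    x <- unname(.COMP[x])
    paste(sort(x), collapse = "/")
  }, character(1))
}

#' Lift a transcript-coordinate genotype matrix to genome coordinates
#'
#' Maps `chrom = gene_id, pos = transcript offset` to chromosome positions
#' using the gene-model table; alleles of minus-strand genes are
#' complemented so all sites are reported on the genome forward strand.
#'
#' @param gm a [GenotypeMatrix-class] keyed by gene id.
#' @param genes gene-model table (gene_id, chrom, start, end, strand).
#' @return A [GenotypeMatrix-class] keyed by chromosome.
#' @export
liftGenotypeMatrix <- function(gm, genes) {
  g <- genes[match(gm@sites$chrom, genes$gene_id), , drop = FALSE]
  if (anyNA(g$gene_id)) stop("sites reference unknown genes")
  plus <- g$strand == "+"
  pos <- ifelse(plus, g$start + gm@sites$pos, g$end - 1L - gm@sites$pos)
  sites <- gm@sites
  sites$chrom <- g$chrom
  sites$pos <- as.integer(pos)
  geno <- gm@geno
  if (any(!plus)) {
    i <- which(!plus)
    sites$ref[i] <- unname(.COMP[sites$ref[i]])
    sites$alt[i] <- vapply(strsplit(sites$alt[i], ",", fixed = TRUE),
                           function(x) paste(unname(.COMP[x]),
                                             collapse = ","),
                           character(1))
    geno[i, ] <- apply(geno[i, , drop = FALSE], 2, .compGenotype)
  }
  ord <- order(sites$chrom, sites$pos)
  new("GenotypeMatrix", geno = geno[ord, , drop = FALSE],
      sites = sites[ord, , drop = FALSE], samples = gm@samples)
}

#' Lift transcript-level variant calls to genome coordinates
#'
#' Convenience for painting: returns chrom, pos and (complemented where
#' needed) alleles for each call of a call set.
#'
#' @param calls calls data.frame (target = gene_id, pos = transcript offset).
#' @param genes gene-model table.
#' @return data.frame chrom, pos, ref, alt, genotype.
#' @export
liftVariants <- function(calls, genes) {
  g <- genes[match(calls$target, genes$gene_id), , drop = FALSE]
  if (anyNA(g$gene_id)) stop("calls reference unknown genes")
  plus <- g$strand == "+"
  out <- data.frame(
    chrom = g$chrom,
    pos = as.integer(ifelse(plus, g$start + calls$pos,
                            g$end - 1L - calls$pos)),
    ref = ifelse(plus, calls$ref, unname(.COMP[calls$ref])),
    alt = ifelse(plus, calls$alt,
                 vapply(strsplit(calls$alt, ",", fixed = TRUE),
                        function(x) paste(unname(.COMP[x]), collapse = ","),
                        character(1))),
    genotype = ifelse(plus, calls$genotype, .compGenotype(calls$genotype)),
    stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Annotate SNPs as synonymous, nonsynonymous or noncoding
#'
#' The codon containing each site is translated under the standard genetic
#' code for the reference and alternative allele; an identical amino acid
#' means synonymous. Sites outside every gene model are noncoding. Gene
#' models are single-exon CDS with a frame offset; a CDS whose length is not
#' divisible by 3 is an error.
#'
#' @param sites data.frame with chrom, pos (0-based genome), ref, alt
#'   (first allele used when several are listed).
#' @param genes gene-model table (gene_id, chrom, start, end, strand,
#'   cds_frame).
#' @param genome named DNAStringSet of chromosomes.
#' @return character vector in {"synonymous", "nonsynonymous", "noncoding"}.
#' @export
annotateEffect <- function(sites, genes, genome) {
  if (any((genes$end - genes$start - genes$cds_frame) %% 3L != 0L))
    stop("CDS length not divisible by 3")
  gr_genes <- GenomicRanges::GRanges(genes$chrom,
    IRanges::IRanges(genes$start + 1L, genes$end))
  gr_sites <- GenomicRanges::GRanges(sites$chrom,
    IRanges::IRanges(sites$pos + 1L, sites$pos + 1L))
  hit <- GenomicRanges::findOverlaps(gr_sites, gr_genes, select = "first")
  out <- rep("noncoding", nrow(sites))
  idx <- which(!is.na(hit))
  if (!length(idx)) return(out)
  code <- Biostrings::GENETIC_CODE
  tx_cache <- list()
  alt1 <- vapply(strsplit(sites$alt, ",", fixed = TRUE), `[[`, character(1),
                 1L)
  for (i in idx) {
    g <- genes[hit[i], ]
    gid <- g$gene_id
    if (is.null(tx_cache[[gid]])) {
      s <- Biostrings::DNAStringSet(genome[g$chrom], start = g$start + 1L,
                                    end = g$end)
      if (g$strand == "-") s <- Biostrings::reverseComplement(s)
      tx_cache[[gid]] <- as.character(s[[1]])
    }
    tx <- tx_cache[[gid]]
    tpos <- if (g$strand == "+") sites$pos[i] - g$start
            else g$end - 1L - sites$pos[i]
    refb <- sites$ref[i]
    altb <- alt1[i]
    if (g$strand == "-") {
      refb <- unname(.COMP[refb])
      altb <- unname(.COMP[altb])
    }
    cpos <- tpos - g$cds_frame
    if (cpos < 0L) next  # upstream of the frame start: noncoding
    c0 <- g$cds_frame + (cpos %/% 3L) * 3L
    codon <- substring(tx, c0 + 1L, c0 + 3L)
    off <- cpos %% 3L + 1L
    altCodon <- codon
    substring(altCodon, off, off) <- altb
    refCodon <- codon
    substring(refCodon, off, off) <- refb
    out[i] <- if (code[[refCodon]] == code[[altCodon]]) "synonymous"
              else "nonsynonymous"
  }
  out
}

#' Summarize a sample: SNP counts, heterozygosity, coverage, RPKM
#'
#' RPKM = reads_on_gene x 1e9 / (total_mapped_reads x gene_length_bp); a
#' gene is "represented" when its RPKM is greater than 0. The percentage of
#' heterozygous positions is computed over the sample's processed SNP calls.
#' Coverage is the fraction of reference positions covered by at least one
#' filtered read.
#'
#' @param callset a [VariantCallSet-class].
#' @param records the filtered alignment records of the same sample.
#' @return list: sample, processed_snps, pct_heterozygous, pct_coverage,
#'   represented_genes, rpkm (named numeric).
#' @export
summarizeSample <- function(callset, records) {
  lens <- callset@targets
  nMapped <- nrow(records)
  counts <- table(factor(records$target_id, levels = names(lens)))
  rpkm <- if (nMapped == 0L) setNames(rep(NA_real_, length(lens)),
                                      names(lens))
          else as.numeric(counts) * 1e9 / (nMapped * as.numeric(lens))
  names(rpkm) <- names(lens)
  covered <- sum(vapply(callset@coverage, function(v) sum(v > 0L),
                        numeric(1)))
  calls <- callset@calls
  nhet <- if (nrow(calls)) sum(.isHet(calls$genotype)) else 0L
  list(sample = callset@sample,
       processed_snps = nrow(calls),
       pct_heterozygous = if (nrow(calls)) 100 * nhet / nrow(calls)
                          else NA_real_,
       pct_coverage = 100 * covered / sum(as.numeric(lens)),
       represented_genes = if (nMapped == 0L) 0L else sum(counts > 0L),
       rpkm = rpkm)
}

#' Filter or partition a genotype matrix
#'
#' Modes: `missing` drops sites whose missing fraction exceeds `threshold`
#' (default 0 = complete cases only); `biallelic` keeps sites with exactly
#' two distinct observed alleles; `random_subset` samples `n` sites without
#' replacement (seeded, site order preserved); `by_chromosome` partitions
#' into one matrix per chromosome.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param mode filter mode.
#' @param threshold missing-fraction threshold for mode "missing".
#' @param n subset size for mode "random_subset"; if larger than the number
#'   of sites, all sites are returned with a warning.
#' @param seed seed for mode "random_subset".
#' @return A [GenotypeMatrix-class], or a named list of them for
#'   `by_chromosome`.
#' @export
filterMatrix <- function(gm, mode = c("missing", "biallelic",
                                      "random_subset", "by_chromosome"),
                         threshold = 0, n = NULL, seed = NULL) {
  mode <- match.arg(mode)
  sub <- function(keep) {
    new("GenotypeMatrix", geno = gm@geno[keep, , drop = FALSE],
        sites = gm@sites[keep, , drop = FALSE], samples = gm@samples)
  }
  if (mode == "missing") {
    frac <- rowMeans(is.na(gm@geno))
    return(sub(which(frac <= threshold)))
  }
  if (mode == "biallelic") {
    nAll <- vapply(seq_len(nrow(gm@geno)), function(i) {
      a <- unlist(strsplit(gm@geno[i, !is.na(gm@geno[i, ])], "/",
                           fixed = TRUE))
      length(unique(a))
    }, integer(1))
    return(sub(which(nAll == 2L)))
  }
  if (mode == "random_subset") {
    if (is.null(n)) stop("mode 'random_subset' needs n")
    if (!is.null(seed)) set.seed(seed)
    m <- nrow(gm@sites)
    if (n > m) {
      warning("requested more sites than available; keeping all ", m)
      n <- m
    }
    return(sub(sort(sample.int(m, n))))
  }
  chroms <- unique(gm@sites$chrom)
  out <- lapply(chroms, function(ch) sub(which(gm@sites$chrom == ch)))
  names(out) <- chroms
  out
}
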