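# Phylogenomic preparation and post-processing: OTU construction with
# subgenome splitting, SNP supermatrix export, gene selection, outgroup
# screening, tree calibration, minimum-divergence extraction and the Evanno
# delta-K statistic.

#' Build an OTU table from an accession table
#'
#' In `supermatrix` mode every diploid (and outgroup) accession is one OTU
#' and every allopolyploid accession contributes two OTUs, one per
#' homoeologous subgenome, named `<progenitor><species>_<accession>` (e.g.
#' the D1 homoeologue of a T1 accession becomes "D1T1_1288"). In
#' `species_tree` mode OTUs are species-level groups, each allopolyploid
#' species contributing one group per subgenome (e.g. "T2-D3").
#'
#' @param accessions data.frame with columns accession, species, ploidy
#'   ("diploid", "allopolyploid" or "outgroup") and, for allopolyploids,
#'   progenitor1 and progenitor2 (subgenome labels).
#' @param outgroup optional accession id(s) to re-classify as outgroup.
#' @param mode "supermatrix" or "species_tree".
#' @return data.frame: otu, accession, species, ploidy, subgenome (NA for
#'   diploids and the outgroup).
#' @examples
#' tbl <- readGlycineAccessions()
#' nrow(makeOtus(tbl, mode = "supermatrix"))          # 36 OTUs
#' ot <- makeOtus(tbl, mode = "species_tree")
#' length(unique(ot$otu[ot$ploidy != "outgroup"]))    # 11 ingroup groups
#' @export
makeOtus <- function(accessions, outgroup = NULL,
                     mode = c("supermatrix", "species_tree")) {
  mode <- match.arg(mode)
  need <- c("accession", "species", "ploidy")
  if (!all(need %in% names(accessions)))
    stop("accession table needs columns: ", paste(need, collapse = ", "))
  acc <- accessions
  if (!is.null(outgroup)) acc$ploidy[acc$accession %in% outgroup] <- "outgroup"
  rows <- list()
  for (i in seq_len(nrow(acc))) {
    a <- acc[i, ]
    if (a$ploidy == "allopolyploid") {
      progs <- c(a$progenitor1, a$progenitor2)
      if (anyNA(progs) || any(!nzchar(progs)))
        stop("allopolyploid accession ", a$accession,
             " lacks two progenitor labels")
      otu <- if (mode == "supermatrix")
        sprintf("%s%s_%s", progs, a$species, a$accession)
      else sprintf("%s-%s", a$species, progs)
      rows[[i]] <- data.frame(otu = otu, accession = a$accession,
                              species = a$species, ploidy = a$ploidy,
                              subgenome = progs, stringsAsFactors = FALSE)
    } else {
      otu <- if (mode == "supermatrix")
        sprintf("%s_%s", a$species, a$accession)
      else a$species
      rows[[i]] <- data.frame(otu = otu, accession = a$accession,
                              species = a$species, ploidy = a$ploidy,
                              subgenome = NA_character_,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (mode == "species_tree") {
    out <- out[!duplicated(out$otu), , drop = FALSE]
    out$accession <- NA_character_
    rownames(out) <- NULL
  }
  out
}

#' Accession table of the Glycine perennial polyploid study panel
#'
#' The 24-accession panel of three allopolyploid species (T1, T2, T5) and
#' their putative diploid progenitors (D1, D3, D4/syndetika, canescens,
#' clandestina), plus the G. max outgroup, with progenitor (subgenome)
#' labels per the crossing/marker hypotheses for the complex. Ships with the
#' package as plain TSV.
#'
#' @return data.frame with accession, species, ploidy, progenitor1,
#'   progenitor2.
#' @export
readGlycineAccessions <- function() {
  path <- system.file("extdata", "glycine_accessions.tsv",
                      package = "HomoeoSort")
  read.delim(path, stringsAsFactors = FALSE, na.strings = "")
}

.IUPAC_PAIR <- local({
  # unordered base pair -> IUPAC code
  pairs <- c(AA = "A", CC = "C", GG = "G", TT = "T",
             AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")
  pairs
})

#' Build a SNP supermatrix with OTUs as rows
#'
#' One column per retained SNP site, ordered by (chromosome, position).
#' Heterozygous genotypes become IUPAC ambiguity characters (default) or the
#' reference allele (`encode = "major"`); missing genotypes become N.
#'
#' @param gm a [GenotypeMatrix-class] whose samples are the OTU-level
#'   genotype sources (e.g. subgenome-split samples from
#'   [subgenomeSnpRecall()] merged by [mergeCalls()]).
#' @param otuTable optional OTU table from [makeOtus()]; every OTU must
#'   match a sample of `gm`, otherwise an error names the missing ones.
#' @param encode heterozygote encoding.
#' @return A [SuperMatrix-class].
#' @export
buildSupermatrix <- function(gm, otuTable = NULL,
                             encode = c("iupac", "major")) {
  encode <- match.arg(encode)
  otus <- gm@samples
  if (!is.null(otuTable)) {
    otus <- otuTable$otu
    miss <- setdiff(otus, gm@samples)
    if (length(miss))
      stop("OTU(s) with no genotype source: ", paste(miss, collapse = ", "))
  }
  g <- gm@geno[, match(otus, gm@samples), drop = FALSE]
  chars <- g
  uniq <- unique(as.vector(g))
  for (u in uniq) {
    if (is.na(u)) next
    al <- sort(strsplit(u, "/", fixed = TRUE)[[1]])
    ch <- if (encode == "iupac") .IUPAC_PAIR[paste(al, collapse = "")]
          else al[1]
    chars[which(g == u)] <- ch
  }
  chars[is.na(chars)] <- "N"
  seqs <- Biostrings::DNAStringSet(apply(chars, 2, paste, collapse = ""))
  names(seqs) <- otus
  new("SuperMatrix", sequences = seqs,
      sites = gm@sites[, c("chrom", "pos")])
}

#' Write / read a supermatrix as FASTA
#'
#' @param sm a [SuperMatrix-class].
#' @param path file path.
#' @return `writeSupermatrixFasta`: `path` invisibly;
#'   `readSupermatrixFasta`: a DNAStringSet (site coordinates are not stored
#'   in FASTA).
#' @export
writeSupermatrixFasta <- function(sm, path) {
  Biostrings::writeXStringSet(sm@sequences, path)
  invisible(path)
}

#' @rdname writeSupermatrixFasta
#' @export
readSupermatrixFasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write a supermatrix in relaxed PHYLIP format
#'
#' @param sm a [SuperMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSupermatrixPhylip <- function(sm, path) {
  n <- length(sm@sequences)
  L <- unique(Biostrings::width(sm@sequences))
  lines <- c(sprintf("%d %d", n, L),
             sprintf("%s  %s", names(sm@sequences),
                     as.character(sm@sequences)))
  writeLines(lines, path)
  invisible(path)
}

#' Select genes for gene-based phylogenetic analysis
#'
#' A gene is retained iff it passes the consensus quality criteria (length
#' at least `minLen`, N fraction at most `maxNFraction`) in every accession
#' consensus supplied, and it belongs to the list of retained duplicate
#' pairs from the recent whole-genome duplication.
#'
#' @param consensusSets named list of [ConsensusSet-class] (one per
#'   accession/subtranscriptome).
#' @param pairList character vector of gene ids that are members of retained
#'   WGD pairs (or a two-column data.frame of pairs).
#' @param minLen,maxNFraction see [consensusStats()].
#' @return character vector of retained gene ids.
#' @export
selectGenes <- function(consensusSets, pairList, minLen = 1000L,
                        maxNFraction = 0.10) {
  if (is.data.frame(pairList)) pairList <- unlist(pairList, use.names = FALSE)
  pairList <- unique(pairList[!is.na(pairList)])
  if (!length(pairList))
    warning("empty pair list: no gene can satisfy the pair criterion")
  passTables <- lapply(consensusSets, consensusStats, minLen = minLen,
                       maxNFraction = maxNFraction)
  genes <- Reduce(intersect, lapply(passTables, function(s)
    s$gene_id[s$pass]))
  intersect(genes, pairList)
}

.asCharMatrix <- function(alignment) {
  if (is.matrix(alignment)) return(alignment)
  s <- as.character(alignment)
  if (length(unique(nchar(s))) != 1L)
    stop("alignment sequences must have equal length")
  m <- do.call(rbind, strsplit(s, ""))
  rownames(m) <- names(s)
  m
}

#' Screen a gene alignment for paralogue contamination
#'
#' Builds a clock-rooted UPGMA tree from pairwise p-distances (sites with N
#' in either sequence are excluded pairwise) and passes the alignment iff
#' the outgroup is still a singleton at the final, deepest join -- i.e. the
#' outgroup is sister to all ingroup sequences. Sampling a deep paralogue
#' for some ingroup taxa splits the ingroup into two anciently diverged
#' clades deeper than the outgroup divergence, which fails the screen. An
#' alignment of identical sequences passes trivially (all joins at height
#' zero).
#'
#' @param alignment DNAStringSet (equal widths) or character matrix with
#'   named rows.
#' @param outgroup name of the outgroup sequence.
#' @param tol height tolerance when comparing the outgroup join to the
#'   deepest join.
#' @return TRUE (pass) or FALSE (fail).
#' @export
outgroupScreen <- function(alignment, outgroup, tol = 1e-12) {
  m <- .asCharMatrix(alignment)
  if (nrow(m) < 4L) stop("at least 4 sequences (including the outgroup) required")
  if (!outgroup %in% rownames(m)) stop("outgroup not found in alignment")
  db <- ape::as.DNAbin(tolower(m))
  d <- ape::dist.dna(db, model = "raw", pairwise.deletion = TRUE)
  if (anyNA(d)) stop("undefined pairwise distance (no shared called sites)")
  h <- hclust(as.dist(d), method = "average")
  io <- which(h$labels == outgroup)
  row <- which(h$merge[, 1] == -io | h$merge[, 2] == -io)[1]
  h$height[row] >= max(h$height) - tol
}

#' Calibrate an ultrametric tree by scaling its root to a fixed age
#'
#' All branch lengths are multiplied by `rootAge / current root height`, so
#' ratios of node heights are preserved and the topology is unchanged. The
#' input must be rooted and ultrametric within a relative tolerance.
#'
#' @param tree an `ape::phylo` object, a newick string, or a newick file
#'   path.
#' @param rootAge calibration age of the root (default 5 Myr, the divergence
#'   between the annual outgroup and the perennial ingroup in the target
#'   system).
#' @param tol relative ultrametricity tolerance (default 1e-6).
#' @return A [TimeTree-class].
#' @export
scaleTree <- function(tree, rootAge = 5.0, tol = 1e-6) {
  if (is.character(tree)) {
    tree <- if (grepl("(", tree, fixed = TRUE)) ape::read.tree(text = tree)
            else ape::read.tree(tree)
  }
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  depth <- ape::node.depth.edgelength(tree)
  ntip <- length(tree$tip.label)
  td <- depth[seq_len(ntip)]
  H <- max(td)
  if (H <= 0) stop("zero root height: cannot calibrate")
  if ((max(td) - min(td)) > tol * H)
    stop("tree is not ultrametric within tolerance")
  tree$edge.length <- tree$edge.length * (rootAge / H)
  new("TimeTree", tree = tree, rootAge = rootAge)
}

#' Node heights of a calibrated tree
#'
#' @param x a [TimeTree-class] (or an ultrametric phylo).
#' @return numeric vector of heights (age before present) indexed by ape
#'   node number.
#' @export
nodeHeights <- function(x) {
  tree <- if (is(x, "TimeTree")) x@tree else x
  depth <- ape::node.depth.edgelength(tree)
  H <- max(depth[seq_len(length(tree$tip.label))])
  H - depth
}

#' Minimum divergence age between two tip sets
#'
#' Returns the minimum, over pairs (a in A, b in B), of the height of the
#' pair's most recent common ancestor -- e.g. the minimum divergence between
#' a polyploid subgenome's alleles and its diploid progenitor's alleles.
#' Computed by a single post-order traversal: an internal node is the MRCA
#' of some pair iff one of its child subtrees contains a tip of A and a
#' different child subtree contains a tip of B.
#'
#' @param x a [TimeTree-class] or ultrametric phylo.
#' @param tipsA,tipsB disjoint, non-empty tip name sets present in the tree.
#' @return Minimum MRCA height (same units as the tree, Myr after
#'   [scaleTree()]).
#' @export
minDivergence <- function(x, tipsA, tipsB) {
  tree <- if (is(x, "TimeTree")) x@tree else x
  tips <- tree$tip.label
  if (!length(tipsA) || !length(tipsB)) stop("tip sets must be non-empty")
  if (length(intersect(tipsA, tipsB))) stop("tip sets must be disjoint")
  if (!all(c(tipsA, tipsB) %in% tips)) stop("tip set members missing from tree")
  heights <- nodeHeights(tree)
  ntip <- length(tips)
  nnode <- ntip + tree$Nnode
  hasA <- hasB <- logical(nnode)
  hasA[match(tipsA, tips)] <- TRUE
  hasB[match(tipsB, tips)] <- TRUE
  edge <- tree$edge
  po <- ape::reorder.phylo(tree, "postorder")$edge
  best <- Inf
  kids <- split(po[, 2], po[, 1])
  # postorder over parents: children already aggregated when parent visited
  parents <- unique(po[, 1])
  for (p in parents) {
    ch <- kids[[as.character(p)]]
    a <- hasA[ch]
    b <- hasB[ch]
    # p is the MRCA of some (A, B) pair iff an A tip and a B tip sit in
    # different child subtrees of p
    crossing <- FALSE
    for (i in seq_along(ch)) {
      if (a[i] && any(b[-i])) { crossing <- TRUE; break }
    }
    if (crossing) best <- min(best, heights[p])
    hasA[p] <- any(a)
    hasB[p] <- any(b)
  }
  if (!is.finite(best)) stop("no (A, B) pair found in the tree")
  best
}

#' Evanno delta-K from clustering log-probability replicates
#'
#' delta-K(K) = mean over replicates of |L(K+1) - 2 L(K) + L(K-1)| divided
#' by the standard deviation over replicates of L(K). Defined for interior K
#' only; a zero standard deviation yields NA for that K (undefined).
#' Replicates are paired by their order within each K, so the table must be
#' balanced.
#'
#' @param logTable data.frame with columns K and logP, one row per
#'   (K, replicate).
#' @return data.frame: K (interior values), deltaK.
#' @export
evannoDeltaK <- function(logTable) {
  if (!all(c("K", "logP") %in% names(logTable)))
    stop("logTable needs columns K and logP")
  Ks <- sort(unique(logTable$K))
  if (length(Ks) < 3L || !all(diff(Ks) == 1L))
    stop("at least 3 consecutive K values are required")
  reps <- table(logTable$K)
  if (length(unique(reps)) != 1L)
    stop("replicate counts must be equal across K")
  if (reps[1] < 2L) stop("at least 2 replicates per K are required")
  L <- vapply(Ks, function(k)
    logTable$logP[logTable$K == k], numeric(reps[1]))  # reps x K
  inner <- seq(2L, length(Ks) - 1L)
  dk <- vapply(inner, function(i) {
    second <- abs(L[, i + 1] - 2 * L[, i] + L[, i - 1])
    s <- sd(L[, i])
    if (s == 0) NA_real_ else mean(second) / s
  }, numeric(1))
  data.frame(K = Ks[inner], deltaK = dk)
}
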