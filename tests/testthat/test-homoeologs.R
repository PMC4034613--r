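test_that("progenitor reference joining: counts, one-sided genes, errors", {
  set.seed(21)
  genes <- setNames(vapply(1:10, function(i) randomSeq(300L),
                           character(1)), sprintf("g%02d", 1:10))
  a <- genes
  b <- genes
  pref <- buildProgenitorReference(a, b, labels = c("D3", "D4"))
  expect_identical(progenitorTargets(pref), c(10L, 10L))
  expect_identical(sum(progenitorTargets(pref)), 20L)
  # gene present only in A appears once, on the A side
  pref2 <- buildProgenitorReference(a, b[-3], labels = c("D3", "D4"))
  expect_identical(progenitorTargets(pref2), c(10L, 9L))
  aln <- alignToProgenitors(setNames(substring(a[[3]], 51, 150), "r"),
                            pref2)
  asg <- classifyReads(aln, pref2)
  expect_identical(asg$label, "PROG_D3")
  expect_error(buildProgenitorReference(a, character()), "non-empty")
  expect_error(buildProgenitorReference(c(a, a[1]), b), "duplicate")
})

test_that("classification follows the preferential-mapping rules", {
  set.seed(22)
  base <- randomSeq(400L)
  consA <- c(g = base)
  consB <- c(g = mutateSeq(base, 200L))  # one DDP at 1-based 200
  pref <- buildProgenitorReference(consA, consB, labels = c("A", "B"))
  reads <- c(
    over_ddp_A = substring(consA[["g"]], 151, 250),   # AS 0 / -6 -> PROG_A
    over_ddp_B = substring(consB[["g"]], 151, 250),   # -6 / 0 -> PROG_B
    no_ddp = substring(base, 1, 100),                 # 0 / 0 -> SHARED
    neither = mutateSeq(substring(base, 1, 100), 50L) # -6 / -6 -> AMBIGUOUS
  )
  asg <- classifyReads(alignToProgenitors(reads, pref), pref)
  expect_identical(asg$label[match(names(reads), asg$read_id)],
                   c("PROG_A", "PROG_B", "SHARED", "AMBIGUOUS"))
  shared <- asg[asg$read_id == "no_ddp", ]
  expect_identical(shared$AS_A, 0L)
  expect_identical(shared$AS_B, 0L)
  expect_identical(shared$mismatches, 0L)
  amb <- asg[asg$read_id == "neither", ]
  expect_identical(amb$AS_A, -6L)
  expect_identical(amb$AS_B, -6L)
  # unmapped read
  un <- classifyReads(alignToProgenitors(c(x = strrep("A", 100)), pref),
                      pref)
  expect_identical(un$label, "UNMAPPED")
  # one row per read enforced
  twice <- rbind(alignToProgenitors(reads[1], pref),
                 alignToProgenitors(reads[1], pref))
  expect_error(classifyReads(twice, pref), "duplicate")
})

test_that("N columns carry no assignment information", {
  set.seed(23)
  base <- randomSeq(300L)
  withN <- base
  substring(withN, 40, 59) <- strrep("N", 20)
  # consensus A has an N stretch that B resolves; a read matching both
  # elsewhere must not be pulled to either side
  pref <- buildProgenitorReference(c(g = withN), c(g = base),
                                   labels = c("A", "B"))
  asg <- classifyReads(alignToProgenitors(
    c(r = substring(base, 21, 120)), pref), pref)
  expect_identical(asg$label, "SHARED")
  # a mismatch inside the masked stretch is excluded on both sides
  rd <- mutateSeq(substring(base, 21, 120), 25L)  # inside N window of A
  asg2 <- classifyReads(alignToProgenitors(c(r = rd), pref), pref)
  expect_identical(asg2$label, "SHARED")
})

test_that("classification is sound and complete on clean reads", {
  tri <- generateTriad(smallConfig(paleoDupFraction = 0, seed = 77L))
  # ideal progenitor references: the founding haplotype transcripts
  pref <- buildProgenitorReference(
    getTranscripts(tri, "progenitorA"), getTranscripts(tri, "progenitorB"),
    labels = c("A", "B"))
  rr <- simulateReads(tri, "polyploid", nReads = 4000L, errorRate = 0)
  asg <- classifyReads(alignToProgenitors(rr$reads, pref), pref)
  m <- merge(asg, rr$truth, by = "read_id")
  m$ddp <- countTruthDdp(tri, m[, c("gene_id.y", "start.y")] |>
                           setNames(c("gene_id", "start")),
                         tri@config@readLength)
  prog <- startsWith(m$label, "PROG_")
  # partition: every read got exactly one label
  expect_identical(nrow(asg), 4000L)
  expect_identical(sum(table(asg$label)), 4000L)
  # soundness: error-free reads overlapping >= 1 DDP get the true subgenome
  withDdp <- m$ddp > 0
  expect_true(all(m$label[withDdp] == paste0("PROG_", m$origin[withDdp])))
  # completeness bound: reads overlapping 0 DDPs never get a PROG label
  expect_identical(sum(prog & m$ddp == 0), 0L)
  # with post-merger mutation 0 and no errors, non-DDP reads match both
  expect_true(all(m$label[!withDdp] %in% c("SHARED", "AMBIGUOUS")))
})

test_that("the expected PROG fraction is monotone in progenitor divergence", {
  fractions <- vapply(c(0.005, 0.01, 0.02, 0.04), function(d) {
    tri <- generateTriad(smallConfig(progenitorDivergence = d,
                                     paleoDupFraction = 0, seed = 31L))
    pref <- buildProgenitorReference(
      getTranscripts(tri, "progenitorA"),
      getTranscripts(tri, "progenitorB"), labels = c("A", "B"))
    rr <- simulateReads(tri, "polyploid", nReads = 2500L, errorRate = 0)
    asg <- classifyReads(alignToProgenitors(rr$reads, pref), pref)
    mean(startsWith(asg$label, "PROG_"))
  }, numeric(1))
  expect_true(all(diff(fractions) > 0))
})

test_that("subgenome assembly matches the founding haplotypes at covered positions", {
  pl <- smallPipeline()  # postMergerRate = 0
  txA <- as.character(getTranscripts(pl$triad, "progenitorA"))
  consA <- as.character(consensusSequences(
    pl$subgenomeConsensus$consensusA))
  agree <- vapply(names(consA), function(g) {
    c1 <- strsplit(consA[[g]], "")[[1]]
    c2 <- strsplit(txA[[g]], "")[[1]]
    ok <- c1 == "N" | c1 == c2
    all(ok)
  }, logical(1))
  expect_true(all(agree))
  # genes covered only by SHARED reads give identical subgenome sequences
  # (property check at the level of the report: partition sums to 1)
  expect_equal(sum(pl$report$fraction), 1)
  expect_setequal(pl$report$label,
                  c("AMBIGUOUS", "PROG_A", "PROG_B", "SHARED"))
})

test_that("subgenome SNP recall recovers DDP alleles and collapses heterozygosity", {
  pl <- smallPipeline()
  tri <- pl$triad
  genes <- geneModels(tri)
  ddp <- ddpCatalog(tri)
  txRef <- as.character(getTranscripts(tri, "reference"))
  for (side in c("A", "B")) {
    cs <- pl$recall[[paste0("poly-", side)]]
    allele <- if (side == "A") ddp$allele_A else ddp$allele_B
    strand <- genes$strand[match(ddp$gene_id, genes$gene_id)]
    alleleTx <- ifelse(strand == "+", allele,
                       unname(HomoeoSort:::.COMP[allele]))
    refTx <- substring(txRef[ddp$gene_id], ddp$tpos + 1L, ddp$tpos + 1L)
    cov <- vapply(seq_len(nrow(ddp)), function(i) {
      v <- cs@coverage[[ddp$gene_id[i]]]
      if (is.null(v)) 0 else v[ddp$tpos[i] + 1L]
    }, numeric(1))
    check <- cov >= 5 & alleleTx != refTx
    key <- paste(cs@calls$target, cs@calls$pos)
    hit <- match(paste(ddp$gene_id, ddp$tpos)[check], key)
    expect_true(all(!is.na(hit)))
    expect_true(all(cs@calls$genotype[hit] ==
                      paste(alleleTx[check], alleleTx[check], sep = "/")))
  }
  # union of subgenome read sets is a subset of the polyploid reads
  asg <- pl$assignments
  progIds <- asg$read_id[startsWith(asg$label, "PROG_")]
  expect_true(all(progIds %in% names(pl$reads$polyploid$reads)))
  # heterozygosity collapses after separation
  hetPoly <- hetFraction(pl$polyCalls@calls$genotype)
  hetSub <- vapply(pl$recall, function(cs)
    hetFraction(cs@calls$genotype), numeric(1))
  hetDip <- vapply(pl$diploidCalls, function(cs)
    hetFraction(cs@calls$genotype), numeric(1))
  expect_true(all(hetSub < hetPoly))
  expect_true(all(hetDip < hetPoly))
})
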