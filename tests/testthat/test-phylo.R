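test_that("OTU construction matches the study panel counts", {
  tbl <- readGlycineAccessions()
  sm <- makeOtus(tbl, mode = "supermatrix")
  expect_identical(nrow(sm), 36L)  # 13 diploids + 2x11 polyploids + outgroup
  expect_identical(anyDuplicated(sm$otu), 0L)
  expect_true(all(c("D1T1_1288", "D3T1_1288") %in% sm$otu))
  st <- makeOtus(tbl, mode = "species_tree")
  ingroup <- unique(st$otu[st$ploidy != "outgroup"])
  expect_identical(length(ingroup), 11L)
  expect_setequal(ingroup,
                  c("canescens", "clandestina", "D1", "D3", "D4",
                    "T1-D1", "T1-D3", "T2-D3", "T2-D4", "T5-A", "T5-D1"))
})

test_that("OTU counts follow #diploids + 2 #polyploids + #outgroups for any table", {
  set.seed(51)
  for (i in 1:5) {
    nd <- sample(0:6, 1)
    np <- sample(1:5, 1)
    no <- sample(0:2, 1)
    tbl <- data.frame(
      accession = sprintf("a%02d", seq_len(nd + np + no)),
      species = c(sample(letters[1:3], nd, TRUE),
                  sample(LETTERS[1:3], np, TRUE),
                  rep("out", no)),
      ploidy = rep(c("diploid", "allopolyploid", "outgroup"),
                   c(nd, np, no)),
      progenitor1 = c(rep(NA, nd), sample(letters[1:3], np, TRUE),
                      rep(NA, no)),
      progenitor2 = c(rep(NA, nd), sample(letters[4:6], np, TRUE),
                      rep(NA, no)),
      stringsAsFactors = FALSE)
    expect_identical(nrow(makeOtus(tbl, mode = "supermatrix")),
                     nd + 2L * np + no)
  }
  # diploids only, no outgroup: OTUs == accessions
  dip <- data.frame(accession = c("x", "y"), species = c("s1", "s2"),
                    ploidy = "diploid", progenitor1 = NA,
                    progenitor2 = NA)
  expect_identical(nrow(makeOtus(dip, mode = "supermatrix")), 2L)
  bad <- data.frame(accession = "p", species = "T", ploidy = "allopolyploid",
                    progenitor1 = "D1", progenitor2 = NA)
  expect_error(makeOtus(bad), "progenitor")
})

test_that("supermatrix encoding: dimensions, IUPAC, missing, round trip", {
  geno <- matrix(c("A/A", "A/G", NA,
                   "G/G", "C/T", "T/T"), nrow = 3)
  gm <- new("GenotypeMatrix", geno = geno,
            sites = data.frame(chrom = c("chr1", "chr1", "chr2"),
                               pos = c(0L, 5L, 3L),
                               ref = c("A", "C", "T"),
                               alt = c("G", "T", ""),
                               stringsAsFactors = FALSE),
            samples = c("otu1", "otu2"))
  sm <- buildSupermatrix(gm)
  expect_identical(length(sm@sequences), 2L)
  expect_identical(unique(Biostrings::width(sm@sequences)), 3L)
  expect_identical(as.character(sm@sequences[["otu1"]]), "ARN")
  expect_identical(as.character(sm@sequences[["otu2"]]), "GYT")
  # major-allele encoding collapses the heterozygote
  smM <- buildSupermatrix(gm, encode = "major")
  expect_identical(as.character(smM@sequences[["otu1"]]), "AAN")
  # FASTA round trip
  path <- tempfile(fileext = ".fa")
  writeSupermatrixFasta(sm, path)
  back <- readSupermatrixFasta(path)
  expect_identical(as.character(back), as.character(sm@sequences))
  # OTU without a genotype source
  ot <- data.frame(otu = c("otu1", "ghost"))
  expect_error(buildSupermatrix(gm, ot), "ghost")
  # PHYLIP header
  pp <- tempfile(fileext = ".phy")
  writeSupermatrixPhylip(sm, pp)
  expect_identical(readLines(pp)[1], "2 3")
})

test_that("gene selection needs quality in every accession and a retained pair", {
  mkstats <- function(fracs, lens = 1200L) {
    genes <- names(fracs)
    seqs <- Biostrings::DNAStringSet(setNames(rep(strrep("A", lens),
                                                  length(genes)), genes))
    new("ConsensusSet",
        sequences = seqs, group = "x",
        stats = data.frame(gene_id = genes, length = lens,
                           n_count = as.integer(fracs * lens),
                           n_fraction = fracs, covered_length = lens))
  }
  acc1 <- mkstats(c(g1 = 0, g2 = 0, g3 = 0.5, g4 = 0))
  acc2 <- mkstats(c(g1 = 0, g2 = 0.5, g3 = 0, g4 = 0.02))
  pairs <- data.frame(a = c("g1", "g2"), b = c("g1.p", "g2.p"))
  got <- selectGenes(list(acc1, acc2), pairs)
  expect_identical(got, "g1")  # g2 fails in acc2; g3 in acc1; g4 unpaired
  expect_warning(selectGenes(list(acc1), character()), "pair")
})

test_that("the outgroup screen passes orthologues and fails deep paralogues", {
  # deterministic single cases
  clean <- simulateGeneAlignment(nIngroup = 8, seed = 61L)
  expect_true(outgroupScreen(clean, "OUT"))
  para <- simulateGeneAlignment(nIngroup = 8, paralogs = 2, seed = 62L)
  expect_false(outgroupScreen(para, "OUT"))
  # identical sequences: trivially exterior outgroup
  same <- Biostrings::DNAStringSet(setNames(rep(strrep("ACGT", 50), 5),
                                            c(paste0("i", 1:4), "OUT")))
  expect_true(outgroupScreen(same, "OUT"))
  expect_error(outgroupScreen(same[1:3], "OUT"), "4 sequences")
  expect_error(outgroupScreen(same, "nope"), "outgroup")
  # one-sided rate guarantees over 100 seeded replicates each
  passClean <- vapply(1:100, function(s)
    outgroupScreen(simulateGeneAlignment(nIngroup = 8, seed = s), "OUT"),
    logical(1))
  failPara <- vapply(1:100, function(s)
    !outgroupScreen(simulateGeneAlignment(nIngroup = 8, paralogs = 2,
                                          seed = 200 + s), "OUT"),
    logical(1))
  expect_gte(mean(passClean), 0.95)
  expect_gte(mean(failPara), 0.95)
})

test_that("tree calibration scales heights linearly and validates input", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:0.5,d:0.5):1.5);")
  tt <- scaleTree(tr, rootAge = 5)
  h <- nodeHeights(tt)
  ntip <- 4L
  expect_equal(max(h), 5)
  expect_equal(unname(h[seq_len(ntip)]), rep(0, 4))
  # already at the target age: unchanged
  tt2 <- scaleTree(tt@tree, rootAge = 5)
  expect_equal(tt2@tree$edge.length, tt@tree$edge.length)
  # internal heights scale linearly: 1 -> 2.5 and 0.5 -> 1.25 (ratio kept)
  inner <- sort(unname(h[(ntip + 1L):length(h)]))
  expect_equal(inner, c(1.25, 2.5, 5))
  expect_error(scaleTree(ape::read.tree(text = "((a:1,b:2):1,c:3);")),
               "ultrametric")
  expect_error(scaleTree(ape::read.tree(text = "((a:0,b:0):0,c:0);")),
               "height")
})

test_that("minimum divergence equals the brute-force MRCA scan", {
  # sisters: the parent's height
  tr <- scaleTree(ape::read.tree(text = "((a:1,b:1):3,(c:3,d:3):1);"),
                  rootAge = 4)
  expect_equal(minDivergence(tr, "a", "b"), 1)
  expect_equal(minDivergence(tr, c("a", "b"), c("c", "d")), 4)
  expect_error(minDivergence(tr, c("a", "b"), c("b", "c")), "disjoint")
  expect_error(minDivergence(tr, character(), "a"), "non-empty")
  expect_error(minDivergence(tr, "a", "zz"), "missing")
  set.seed(71)
  for (i in 1:20) {
    tree <- ape::rcoal(12)
    tt <- scaleTree(tree, rootAge = 5)
    tips <- sample(tree$tip.label)
    A <- tips[1:4]
    B <- tips[5:9]
    h <- nodeHeights(tt)
    oracle <- min(vapply(A, function(a) min(vapply(B, function(b)
      h[ape::getMRCA(tt@tree, c(a, b))], numeric(1))), numeric(1)))
    expect_equal(minDivergence(tt, A, B), oracle)
  }
})

test_that("Evanno delta-K follows the second-difference formula", {
  # exactly linear L(K): zero second difference at interior K
  lin <- data.frame(K = rep(2:5, each = 3),
                    logP = rep(c(-100, -90, -80, -70), each = 3) +
                      rep(c(0, 1, -1), 4))
  dk <- evannoDeltaK(lin)
  expect_identical(dk$K, c(3L, 4L))
  expect_equal(dk$deltaK, c(0, 0))
  # shift invariance
  lin2 <- lin
  lin2$logP <- lin2$logP + 1234
  expect_equal(evannoDeltaK(lin2)$deltaK, dk$deltaK)
  # toy 4x3 table against a direct evaluation
  set.seed(81)
  toy <- data.frame(K = rep(2:5, each = 3),
                    logP = rnorm(12, mean = rep(c(-500, -400, -380, -375),
                                                each = 3), sd = 5))
  got <- evannoDeltaK(toy)
  L <- matrix(toy$logP, nrow = 3)  # reps x K (K = 2..5)
  for (j in 2:3) {
    exp_dk <- mean(abs(L[, j + 1] - 2 * L[, j] + L[, j - 1])) / sd(L[, j])
    expect_equal(got$deltaK[j - 1], exp_dk)
  }
  # zero replicate variance is undefined
  const <- data.frame(K = rep(2:4, each = 2), logP = rep(c(-10, -5, -4),
                                                         each = 2))
  expect_true(is.na(evannoDeltaK(const)$deltaK))
  expect_error(evannoDeltaK(data.frame(K = c(2, 2, 4, 4, 5, 5),
                                       logP = 1:6)), "consecutive")
  expect_error(evannoDeltaK(data.frame(K = c(2, 3, 3, 4, 4),
                                       logP = 1:5)), "equal")
})
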