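# helper: align perfect-position reads by constructing records directly
recordsAt <- function(ids, target, starts) {
  data.frame(read_id = ids, target_id = target, start = starts,
             strand = "+", stringsAsFactors = FALSE)
}

test_that("the depth-5 boundary and unanimous homozygous calls", {
  ref <- Biostrings::DNAStringSet(c(g = strrep("A", 40)))
  rd <- function(n) setNames(rep(paste0(strrep("A", 10), "G",
                                        strrep("A", 9)), n),
                             sprintf("r%02d", seq_len(n)))
  # depth 4 with a clear alt: no call
  r4 <- rd(4)
  v4 <- pileupAndCall(recordsAt(names(r4), "g", rep(0L, 4)), r4, ref)
  expect_identical(nrow(v4@calls), 0L)
  # depth 5, 5/5 alt reads: homozygous alt
  r5 <- rd(5)
  v5 <- pileupAndCall(recordsAt(names(r5), "g", rep(0L, 5)), r5, ref)
  expect_identical(nrow(v5@calls), 1L)
  expect_identical(v5@calls$pos, 10L)
  expect_identical(v5@calls$genotype, "G/G")
  expect_identical(v5@calls$ref, "A")
  expect_identical(v5@calls$alt, "G")
})

test_that("random toy pileups match a direct re-evaluation of the rules", {
  set.seed(11)
  for (rep in 1:5) {
    ref <- c(g = randomSeq(60L))
    refv <- strsplit(ref[["g"]], "")[[1]]
    n <- 40L
    starts <- sample(0:40, n, replace = TRUE)
    reads <- vapply(starts, function(s) {
      rd <- substring(ref[["g"]], s + 1, s + 20)
      if (runif(1) < 0.7) rd <- mutateSeq(rd, sample(20L, sample(2, 1)))
      rd
    }, character(1))
    names(reads) <- sprintf("r%02d", seq_len(n))
    refset <- Biostrings::DNAStringSet(ref)
    got <- pileupAndCall(recordsAt(names(reads), "g", starts), reads,
                         refset)
    # independent rule application from scratch
    counts <- matrix(0L, 4, 60, dimnames = list(c("A", "C", "G", "T"),
                                                NULL))
    for (i in seq_len(n)) {
      v <- strsplit(reads[[i]], "")[[1]]
      for (j in seq_along(v)) {
        counts[v[j], starts[i] + j] <- counts[v[j], starts[i] + j] + 1L
      }
    }
    for (p in 1:60) {
      col <- counts[, p]
      depth <- sum(col)
      cand <- names(col)[col >= 2L]
      nonref <- setdiff(cand, refv[p])
      expected <- depth >= 5L && length(nonref) >= 1L
      called <- (p - 1L) %in% got@calls$pos
      expect_identical(called, expected)
      if (expected) {
        row <- got@calls[got@calls$pos == p - 1L, ]
        # top allele (ref-first tie break), hom iff fraction >= 0.8
        ord <- order(-col, names(col) != refv[p], names(col))
        top <- names(col)[ord[1]]
        if (col[top] / depth >= 0.8) {
          expect_identical(row$genotype, paste(top, top, sep = "/"))
        } else {
          second <- names(col)[ord[2]]
          expect_identical(row$genotype,
                           paste(sort(c(top, second)), collapse = "/"))
        }
        expect_identical(row$depth, depth)
      }
    }
  }
})

test_that("unknown alignment targets are rejected by name", {
  ref <- Biostrings::DNAStringSet(c(g = strrep("A", 30)))
  reads <- c(r1 = strrep("A", 10))
  expect_error(pileupAndCall(recordsAt("r1", "nope", 0L), reads, ref),
               "nope")
})

test_that("merging takes the site union and distinguishes hom-ref from missing", {
  ref <- Biostrings::DNAStringSet(c(g1 = strrep("A", 30),
                                    g2 = strrep("C", 30)))
  mk <- function(sample, target, pos, genotype, covTargets) {
    cov <- lapply(names(ref), function(t)
      if (t %in% covTargets) rep(10L, 30) else rep(0L, 30))
    names(cov) <- names(ref)
    new("VariantCallSet",
        calls = data.frame(target = target, pos = pos,
                           ref = substring(as.character(ref[[target[1]]]),
                                           1, 1),
                           alt = "G", genotype = genotype, depth = 10L,
                           stringsAsFactors = FALSE),
        coverage = cov, sample = sample,
        targets = setNames(Biostrings::width(ref), names(ref)))
  }
  s1 <- mk("s1", "g1", 5L, "G/G", covTargets = "g1")   # no g2 coverage
  s2 <- mk("s2", "g2", 7L, "C/G", covTargets = c("g1", "g2"))
  gm <- mergeCalls(list(s1, s2))
  expect_identical(sampleNames(gm), c("s1", "s2"))
  expect_identical(nrow(siteInfo(gm)), 2L)
  g <- unname(genotypes(gm))
  expect_identical(g[1, 1], "G/G")        # s1 call at g1:5
  expect_identical(g[2, 1], NA_character_) # s1 missing at g2:7 (no depth)
  expect_identical(g[1, 2], "A/A")        # s2 hom-ref at g1:5 (covered)
  expect_identical(g[2, 2], "C/G")
  # order independence up to column order
  gm2 <- mergeCalls(list(s2, s1))
  expect_identical(siteInfo(gm2), siteInfo(gm))
  expect_identical(genotypes(gm2)[, "s1"], genotypes(gm)[, "s1"])
  expect_error(mergeCalls(list(s1, s1)), "duplicate")
})

test_that("HapMap, VCF and Structure exports round-trip / follow the format", {
  geno <- matrix(c("A/A", "C/T", NA, "A/G", "C/C", "T/T"), nrow = 3)
  gm <- new("GenotypeMatrix", geno = geno,
            sites = data.frame(chrom = c("chr1", "chr1", "chr2"),
                               pos = c(4L, 9L, 2L),
                               ref = c("A", "C", "T"),
                               alt = c("G", "T", ""),
                               stringsAsFactors = FALSE),
            samples = c("s1", "s2"))
  hp <- tempfile(fileext = ".hmp.txt")
  writeHapMap(gm, hp)
  back <- readHapMap(hp)
  expect_identical(genotypes(back), genotypes(gm))
  expect_identical(siteInfo(back)$pos, siteInfo(gm)$pos)
  vcf <- tempfile(fileext = ".vcf")
  writeVcfFile(gm, vcf)
  backv <- readVcfGenotypes(vcf)
  expect_identical(genotypes(backv), genotypes(gm))
  expect_identical(siteInfo(backv)$ref, siteInfo(gm)$ref)
  st <- tempfile(fileext = ".str")
  writeStructure(gm, st)
  lines <- strsplit(readLines(st), "\t")
  expect_length(lines, 4L)  # two rows per sample
  expect_identical(lines[[1]][1], "s1")
  # A=1 C=2 G=3 T=4, missing -9; s1 alleles at the three sites
  expect_identical(lines[[1]][-1], c("1", "2", "-9"))
  expect_identical(lines[[2]][-1], c("1", "4", "-9"))
})

test_that("effect annotation agrees with full codon-table enumeration", {
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste,
                  collapse = "")
  cds <- paste(codons, collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr = cds))
  genes <- data.frame(gene_id = "g", chrom = "chr", start = 0L,
                      end = nchar(cds), strand = "+", cds_frame = 0L)
  sites <- list()
  expected <- character()
  for (ci in seq_along(codons)) {
    for (off in 0:2) {
      refb <- substring(codons[ci], off + 1, off + 1)
      for (alt in setdiff(c("A", "C", "G", "T"), refb)) {
        sites[[length(sites) + 1]] <- data.frame(
          chrom = "chr", pos = (ci - 1L) * 3L + off, ref = refb, alt = alt)
        altCodon <- codons[ci]
        substring(altCodon, off + 1, off + 1) <- alt
        aaRef <- as.character(Biostrings::translate(
          Biostrings::DNAString(codons[ci]), no.init.codon = TRUE))
        aaAlt <- as.character(Biostrings::translate(
          Biostrings::DNAString(altCodon), no.init.codon = TRUE))
        expected[length(expected) + 1] <-
          if (aaRef == aaAlt) "synonymous" else "nonsynonymous"
      }
    }
  }
  sites <- do.call(rbind, sites)
  got <- annotateEffect(sites, genes, genome)
  expect_identical(got, expected)
})

test_that("noncoding sites, minus-strand genes and frame errors are handled", {
  genome <- Biostrings::DNAStringSet(c(chr = paste0("TTTT",
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString("GGAAAA"))), "TTTT")))
  genes <- data.frame(gene_id = "g", chrom = "chr", start = 4L, end = 10L,
                      strand = "-", cds_frame = 0L)
  # transcript is GGAAAA; genome position of transcript pos 2 (G->G codon
  # wobble) is start + (end-start-1-2) = 4 + 3 = 7; transcript GGA -> GGG
  # means genome base C -> C->? compute: transcript alt G at tpos 2 is
  # genome ref complement
  tpos <- 2L
  gpos <- 10L - 1L - tpos
  refb <- substring(as.character(genome[["chr"]]), gpos + 1, gpos + 1)
  site <- data.frame(chrom = "chr", pos = gpos, ref = refb, alt = "C")
  # transcript change GGA -> GGG (Gly -> Gly): synonymous
  expect_identical(annotateEffect(site, genes, genome), "synonymous")
  # GGA -> AGA (Gly -> Arg): nonsynonymous at transcript pos 0
  gpos0 <- 10L - 1L - 0L
  refb0 <- substring(as.character(genome[["chr"]]), gpos0 + 1, gpos0 + 1)
  site0 <- data.frame(chrom = "chr", pos = gpos0, ref = refb0, alt = "T")
  expect_identical(annotateEffect(site0, genes, genome), "nonsynonymous")
  # outside any gene: noncoding
  out <- data.frame(chrom = "chr", pos = 1L, ref = "T", alt = "A")
  expect_identical(annotateEffect(out, genes, genome), "noncoding")
  badGenes <- data.frame(gene_id = "g", chrom = "chr", start = 4L,
                         end = 9L, strand = "+", cds_frame = 0L)
  expect_error(annotateEffect(site, badGenes, genome), "divisible")
})

test_that("sample summaries follow the RPKM and percentage definitions", {
  ref <- Biostrings::DNAStringSet(c(g1 = strrep("A", 1000),
                                    g2 = strrep("C", 500)))
  cov <- list(g1 = c(rep(2L, 600), rep(0L, 400)), g2 = rep(0L, 500))
  calls <- data.frame(target = "g1", pos = 0:9, ref = "A", alt = "G",
                      genotype = c(rep("A/G", 3), rep("G/G", 7)),
                      depth = 10L, stringsAsFactors = FALSE)
  cs <- new("VariantCallSet", calls = calls, coverage = cov, sample = "s",
            targets = setNames(Biostrings::width(ref), names(ref)))
  records <- data.frame(read_id = sprintf("r%03d", 1:1000),
                        target_id = c(rep("g1", 10), rep("g2", 990)))
  s <- summarizeSample(cs, records)
  expect_equal(s$rpkm[["g1"]], 10 * 1e9 / (1000 * 1000))
  expect_equal(s$pct_heterozygous, 30)
  expect_equal(s$pct_coverage, 100 * 600 / 1500)
  expect_identical(s$represented_genes, 2L)
  # a gene with zero reads is not represented
  records2 <- records[records$target_id == "g1", ]
  s2 <- summarizeSample(cs, records2)
  expect_identical(s2$represented_genes, 1L)
  expect_identical(s2$rpkm[["g2"]], 0)
})

test_that("matrix filters: missing, biallelic, random subset, by chromosome", {
  geno <- matrix(c("A/A", "A/G", NA,  "C/C",
                   "A/A", "G/G", "C/C", "C/C",
                   "A/T", "A/G", "C/C", "C/G"), nrow = 4)
  gm <- new("GenotypeMatrix", geno = geno,
            sites = data.frame(chrom = c("chr1", "chr1", "chr2", "chr2"),
                               pos = c(1L, 5L, 2L, 8L),
                               ref = c("A", "G", "C", "C"),
                               alt = c("T", "A", "", "G"),
                               stringsAsFactors = FALSE),
            samples = c("s1", "s2", "s3"))
  # complete cases: site 3 (one NA) dropped
  cc <- filterMatrix(gm, "missing")
  expect_identical(nrow(siteInfo(cc)), 3L)
  # no missing cells: unchanged
  expect_identical(siteInfo(filterMatrix(cc, "missing")), siteInfo(cc))
  # biallelic: site1 {A,T}=2 kept, site2 {A,G}=2 kept, site3 {C}=1 dropped,
  # site4 {C,G}=2 kept
  bi <- filterMatrix(gm, "biallelic")
  expect_identical(siteInfo(bi)$pos, c(1L, 5L, 8L))
  # a site with 3 observed alleles is removed
  geno3 <- geno
  geno3[4, 1] <- "A/T"
  gm3 <- new("GenotypeMatrix", geno = geno3, sites = gm@sites,
             samples = gm@samples)
  expect_false(8L %in% siteInfo(filterMatrix(gm3, "biallelic"))$pos)
  # random subset: exact size, seeded, order preserved
  r1 <- filterMatrix(gm, "random_subset", n = 2L, seed = 99L)
  r2 <- filterMatrix(gm, "random_subset", n = 2L, seed = 99L)
  expect_identical(siteInfo(r1), siteInfo(r2))
  expect_identical(nrow(siteInfo(r1)), 2L)
  expect_false(is.unsorted(siteInfo(r1)$pos[siteInfo(r1)$chrom == "chr1"]))
  expect_warning(filterMatrix(gm, "random_subset", n = 10L), "available")
  # by chromosome partitions; biallelic and by_chromosome commute
  parts <- filterMatrix(gm, "by_chromosome")
  expect_identical(names(parts), c("chr1", "chr2"))
  a <- lapply(filterMatrix(gm, "by_chromosome"), filterMatrix, "biallelic")
  b <- filterMatrix(filterMatrix(gm, "biallelic"), "by_chromosome")
  expect_identical(lapply(a, siteInfo), lapply(b, siteInfo))
})
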