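# Shared fixtures (built once per run) and independent oracles.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE)) {
    assign(name, fn(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env, inherits = FALSE)
}

smallConfig <- function(...) {
  args <- list(nChromosomes = 2L, chromLength = 30000L, nGenes = 16L,
               geneLength = 1200L, nReads = 6000L, seed = 42L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(SimulationConfig, args)
}

# one modest pipeline shared by the consensus/homoeolog unit tests;
# postMergerRate 0 so subgenome consensus can be compared to the founding
# haplotypes exactly
smallPipeline <- function() {
  fixture("smallPipeline", function() {
    runTriadPipeline(smallConfig(postMergerRate = 0), nDiploidReads = 8000L)
  })
}

# QualityScaledDNAStringSet from bases + quality strings
makeReads <- function(bases, quals = NULL, ids = NULL) {
  if (is.null(quals)) quals <- strrep("I", nchar(bases))
  r <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(bases), Biostrings::PhredQuality(quals))
  names(r) <- if (is.null(ids)) sprintf("r%03d", seq_along(bases)) else ids
  r
}

randomSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutateSeq <- function(s, positions) {
  # substitute a different base at 1-based positions
  v <- strsplit(s, "")[[1]]
  for (p in positions) {
    v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  }
  paste(v, collapse = "")
}

# Exhaustive offset-scan alignment oracle: scores the read at every offset
# of every target on both strands and reports best and second-best under
# the same deterministic tie order (target, position, strand).
oracleAlign <- function(read, targets, mm = 6L, np = 1L) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(read)))
  nN <- utf8ToInt("N")
  cand <- list()
  for (t in seq_along(targets)) {
    tv <- utf8ToInt(targets[[t]])
    for (strand in c("+", "-")) {
      sv <- utf8ToInt(if (strand == "+") read else rc)
      L <- length(sv)
      TL <- length(tv)
      if (TL < L) next
      for (p in 0:(TL - L)) {
        w <- tv[(p + 1):(p + L)]
        amb <- w == nN | sv == nN
        mmn <- sum(sv != w & !amb)
        sc <- -(mm * mmn + np * sum(amb))
        cand[[length(cand) + 1]] <- data.frame(
          t = t, p = p, strand = strand, score = sc, mismatches = mmn)
      }
    }
  }
  cand <- do.call(rbind, cand)
  ord <- order(-cand$score, cand$t, cand$p, match(cand$strand, c("+", "-")))
  cand <- cand[ord, , drop = FALSE]
  list(best = cand[1, ], XS = if (nrow(cand) > 1) max(cand$score[-1])
                              else NA_integer_)
}

hetFraction <- function(genotypes) {
  a <- strsplit(genotypes, "/", fixed = TRUE)
  mean(vapply(a, function(x) x[1] != x[2], logical(1)))
}
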