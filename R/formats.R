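# Text-format export/import of genotype matrices: VCF 4.2, HapMap and
# Structure. Internal coordinates are 0-based; VCF and HapMap positions are
# written 1-based per their standards.

.alleleRows <- function(gm) {
  # list(ref=..., alleles=list of c(ref, alts))
  alts <- strsplit(gm@sites$alt, ",", fixed = TRUE)
  alleles <- mapply(function(r, a) c(r, a[nzchar(a)]), gm@sites$ref, alts,
                    SIMPLIFY = FALSE)
  alleles
}

#' Write a genotype matrix as VCF 4.2
#'
#' SNP sites only, GT fields, missing genotypes as "./.".
#'
#' @param gm a [GenotypeMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeVcfFile <- function(gm, path) {
  alleles <- .alleleRows(gm)
  gt <- matrix(".", nrow(gm@geno), ncol(gm@geno))
  for (i in seq_len(nrow(gm@geno))) {
    al <- alleles[[i]]
    g <- strsplit(gm@geno[i, ], "/", fixed = TRUE)
    gt[i, ] <- vapply(g, function(x) {
      if (anyNA(x)) return("./.")
      ix <- match(x, al)
      if (anyNA(ix)) {
        stop("genotype allele outside {ref, alt} at site ",
             gm@sites$chrom[i], ":", gm@sites$pos[i] + 1L)
      }
      paste(ix - 1L, collapse = "/")
    }, character(1))
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=HomoeoSort",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gm@samples), collapse = "\t"))
  alt <- ifelse(nzchar(gm@sites$alt), gm@sites$alt, ".")
  body <- paste(gm@sites$chrom, gm@sites$pos + 1L, ".", gm@sites$ref, alt,
                ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Reads SNP records with GT fields into a [GenotypeMatrix-class]. Uses
#' vcfR when installed, otherwise a minimal internal reader for plain-text
#' VCF.
#'
#' @param path VCF path.
#' @return A [GenotypeMatrix-class].
#' @export
readVcfGenotypes <- function(path) {
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    gtm <- vcfR::extract.gt(v, element = "GT")
    samples <- colnames(gtm)
    chrom <- fix[, "CHROM"]
    pos <- as.integer(fix[, "POS"]) - 1L
    ref <- fix[, "REF"]
    alt <- ifelse(is.na(fix[, "ALT"]) | fix[, "ALT"] == ".", "",
                  fix[, "ALT"])
  } else {
    lines <- readLines(path)
    hdr <- lines[startsWith(lines, "#CHROM")]
    if (!length(hdr)) stop("no #CHROM header in ", path)
    cols <- strsplit(hdr, "\t", fixed = TRUE)[[1]]
    samples <- cols[-(1:9)]
    body <- lines[!startsWith(lines, "#")]
    f <- strsplit(body, "\t", fixed = TRUE)
    getf <- function(i) vapply(f, `[[`, character(1), i)
    chrom <- getf(1)
    pos <- as.integer(getf(2)) - 1L
    ref <- getf(4)
    alt <- ifelse(getf(5) == ".", "", getf(5))
    gtm <- t(vapply(f, function(x) sub(":.*", "", x[-(1:9)]),
                    character(length(samples))))
    if (length(samples) == 1L) gtm <- matrix(gtm, ncol = 1L)
  }
  geno <- matrix(NA_character_, length(chrom), length(samples))
  for (i in seq_along(chrom)) {
    al <- c(ref[i], strsplit(alt[i], ",", fixed = TRUE)[[1]])
    g <- strsplit(gtm[i, ], "[/|]")
    geno[i, ] <- vapply(g, function(x) {
      ix <- suppressWarnings(as.integer(x))
      if (anyNA(ix)) return(NA_character_)
      paste(sort(al[ix + 1L]), collapse = "/")
    }, character(1))
  }
  colnames(geno) <- samples
  ord <- order(chrom, pos)
  new("GenotypeMatrix",
      geno = geno[ord, , drop = FALSE],
      sites = data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                         stringsAsFactors = FALSE)[ord, , drop = FALSE],
      samples = samples)
}

#' Write / read HapMap genotype tables
#'
#' Tab-delimited HapMap: rs#, alleles (e.g. "A/G"), chrom, pos (1-based),
#' strand, then placeholder columns, then one two-letter genotype column per
#' sample ("NN" = missing). `readHapMap` inverts `writeHapMap` losslessly
#' for SNP data.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param path file path.
#' @return `writeHapMap`: `path` invisibly; `readHapMap`: a
#'   [GenotypeMatrix-class].
#' @export
writeHapMap <- function(gm, path) {
  alleles <- vapply(.alleleRows(gm), paste, character(1), collapse = "/")
  g <- gsub("/", "", gm@geno, fixed = TRUE)
  g[is.na(g)] <- "NN"
  df <- data.frame(
    `rs.` = sprintf("%s_%d", gm@sites$chrom, gm@sites$pos + 1L),
    alleles = alleles, chrom = gm@sites$chrom, pos = gm@sites$pos + 1L,
    strand = "+", assembly. = NA, center = NA, protLSID = NA,
    assayLSID = NA, panelLSID = NA, QCcode = NA,
    stringsAsFactors = FALSE, check.names = FALSE)
  df <- cbind(df, as.data.frame(g, stringsAsFactors = FALSE))
  names(df) <- c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
                 "center", "protLSID", "assayLSID", "panelLSID", "QCcode",
                 gm@samples)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeHapMap
#' @export
readHapMap <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  samples <- names(df)[-(1:11)]
  alleles <- strsplit(df$alleles, "/", fixed = TRUE)
  geno <- matrix(NA_character_, nrow(df), length(samples))
  for (j in seq_along(samples)) {
    g <- as.character(df[[samples[j]]])
    ok <- g != "NN" & !is.na(g)
    a1 <- substring(g[ok], 1, 1)
    a2 <- substring(g[ok], 2, 2)
    geno[ok, j] <- ifelse(a1 <= a2, paste(a1, a2, sep = "/"),
                          paste(a2, a1, sep = "/"))
  }
  colnames(geno) <- samples
  sites <- data.frame(
    chrom = as.character(df$chrom), pos = as.integer(df$pos) - 1L,
    ref = vapply(alleles, `[[`, character(1), 1L),
    alt = vapply(alleles, function(x) paste(x[-1], collapse = ","),
                 character(1)),
    stringsAsFactors = FALSE)
  ord <- order(sites$chrom, sites$pos)
  new("GenotypeMatrix", geno = geno[ord, , drop = FALSE],
      sites = sites[ord, , drop = FALSE], samples = samples)
}

#' Write a genotype matrix in Structure format
#'
#' Two rows per individual; alleles coded A=1, C=2, G=3, T=4; missing -9.
#' The first column is the sample id.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeStructure <- function(gm, path) {
  code <- setNames(1:4, .BASES)
  con <- file(path, "w")
  on.exit(close(con))
  for (j in seq_along(gm@samples)) {
    g <- strsplit(gm@geno[, j], "/", fixed = TRUE)
    a1 <- vapply(g, function(x) if (anyNA(x) || !length(x)) -9L
                 else unname(code[x[1]]), integer(1))
    a2 <- vapply(g, function(x) if (anyNA(x) || !length(x)) -9L
                 else unname(code[x[2]]), integer(1))
    a1[is.na(a1)] <- -9L
    a2[is.na(a2)] <- -9L
    writeLines(paste(c(gm@samples[j], a1), collapse = "\t"), con)
    writeLines(paste(c(gm@samples[j], a2), collapse = "\t"), con)
  }
  invisible(path)
}
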