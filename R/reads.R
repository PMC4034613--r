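#' Read and write FASTQ (Sanger/Phred+33)
#'
#' Thin wrappers around Biostrings that keep sequence and per-base quality
#' together in a QualityScaledDNAStringSet.
#'
#' @param path FASTQ file path.
#' @param reads a QualityScaledDNAStringSet.
#' @return `readFastq` returns a QualityScaledDNAStringSet; `writeFastq`
#'   returns `path` invisibly.
#' @export
readFastq <- function(path) {
  # Biostrings warns that the FASTQ metadata columns are dropped when the
  # qualities are attached; nothing of value is lost
  suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
}

#' @rdname readFastq
#' @export
writeFastq <- function(reads, path) {
  Biostrings::writeQualityScaledXStringSet(reads, path)
}

#' Demultiplex reads by exact leading barcode match
#'
#' A read is assigned to a sample if and only if its first `barcodeLength`
#' bases exactly match that sample's barcode; the matched barcode is removed
#' from both bases and qualities. Everything else lands in the unassigned
#' set.
#'
#' @param reads QualityScaledDNAStringSet.
#' @param barcodeMap named character vector, barcode -> sample name.
#' @param barcodeLength barcode length; defaults to the barcodes' common
#'   length.
#' @return list(samples = named list of QualityScaledDNAStringSet (one per
#'   sample, all samples present even if empty), unassigned =
#'   QualityScaledDNAStringSet).
#' @examples
#' # a 3 nt barcode is removed on assignment
#' r <- Biostrings::QualityScaledDNAStringSet(
#'   Biostrings::DNAStringSet(c(x = "ACTGGGT")),
#'   Biostrings::PhredQuality("IIIIIII"))
#' demultiplexReads(r, c(ACT = "s1"))$samples$s1
#' @export
demultiplexReads <- function(reads, barcodeMap, barcodeLength = NULL) {
  bc <- names(barcodeMap)
  if (anyDuplicated(bc)) stop("duplicate barcodes in barcode map")
  if (length(bc) && length(unique(nchar(bc))) > 1L)
    stop("all barcodes must have the same length")
  if (is.null(barcodeLength)) {
    barcodeLength <- if (length(bc)) nchar(bc[1]) else 0L
  }
  if (length(bc) && any(nchar(bc) != barcodeLength))
    stop("barcodes do not match barcodeLength")
  n <- length(reads)
  if (!length(bc) || barcodeLength == 0L || n == 0L) {
    empty <- lapply(unique(unname(barcodeMap)), function(s) reads[0])
    names(empty) <- unique(unname(barcodeMap))
    return(list(samples = empty, unassigned = reads))
  }
  lead <- as.character(Biostrings::subseq(as(reads, "DNAStringSet"),
                                          1L, barcodeLength))
  hit <- match(lead, bc)
  samples <- lapply(unique(unname(barcodeMap)), function(s) {
    i <- which(!is.na(hit) & unname(barcodeMap)[hit] == s)
    IRanges::narrow(reads[i], start = barcodeLength + 1L)
  })
  names(samples) <- unique(unname(barcodeMap))
  list(samples = samples, unassigned = reads[is.na(hit)])
}

#' Quality-process reads: end trimming and length filtering
#'
#' Bases are trimmed from the read extremes while the terminal base quality
#' is below `minQuality`; reads shorter than `minLength` after trimming are
#' discarded. Interior bases are never altered, and the operation is
#' idempotent. `minLength` is inclusive: a trimmed length of exactly
#' `minLength` is kept.
#'
#' @param reads QualityScaledDNAStringSet (Phred+33).
#' @param minQuality minimum terminal base quality (default 30).
#' @param minLength minimum post-trim read length (default 50, inclusive).
#' @param ends trim "both" extremes (default) or only the 3' end.
#' @return list(reads = kept trimmed reads, discarded = number of reads
#'   removed by the length filter).
#' @export
processReads <- function(reads, minQuality = 30L, minLength = 50L,
                         ends = c("both", "3prime")) {
  ends <- match.arg(ends)
  n <- length(reads)
  if (n == 0L) return(list(reads = reads, discarded = 0L))
  quals <- as.character(Biostrings::quality(reads))
  b <- .cpp_trim_bounds(quals, 33L + as.integer(minQuality), ends == "both")
  len <- pmax(b[, 2] - b[, 1] + 1L, 0L)
  keep <- len >= minLength
  kept <- IRanges::narrow(reads[keep], start = b[keep, 1], end = b[keep, 2])
  list(reads = kept, discarded = sum(!keep))
}
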