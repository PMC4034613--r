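#' Construct an alignment scoring scheme
#'
#' End-to-end ungapped scoring in which a perfect alignment scores 0 and the
#' alignment score is the negated sum of penalties, so "AS = 0" literally
#' means "no mismatches". Columns involving a non-ACGT base cost
#' `ambiguousPenalty` and are not counted as mismatches.
#'
#' @param mismatchPenalty penalty per mismatch (default 6).
#' @param ambiguousPenalty penalty per ambiguous column (default 1).
#' @return A [ScoringScheme-class].
#' @export
scoringScheme <- function(mismatchPenalty = 6L, ambiguousPenalty = 1L) {
  new("ScoringScheme", match = 0,
      mismatchPenalty = as.integer(mismatchPenalty),
      ambiguousPenalty = as.integer(ambiguousPenalty))
}

#' Build an exact k-mer seed index over reference transcripts
#'
#' Every k-mer of every target (windows containing non-ACGT characters are
#' skipped) is retrievable with its positions. The index is session-local.
#'
#' @param targets named DNAStringSet or named character vector.
#' @param k seed length (default 20); must not exceed the shortest target.
#' @return A [SeedIndex-class].
#' @export
seedIndex <- function(targets, k = 20L) {
  seqs <- if (is.character(targets)) targets else as.character(targets)
  if (!length(seqs)) stop("empty reference")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("targets must be named")
  k <- as.integer(k)
  if (k > min(nchar(seqs)))
    stop("seed length k exceeds the shortest target")
  new("SeedIndex", ptr = .cpp_build_index(unname(seqs), k), k = k,
      targets = names(seqs), widths = nchar(seqs))
}

#' Number of seed positions held by an index
#' @param index a [SeedIndex-class].
#' @return Numeric count of indexed k-mer positions.
#' @export
seedCount <- function(index) .cpp_index_positions(index@ptr)

# character conversion that keeps names (as.character drops them on
# character input)
.asNamedChars <- function(x) {
  if (is.character(x)) x else as.character(x)
}

# mapq = 42 with no alternative placement; 0 on a tie; else min(42, 5*gap).
# Chosen so that one distinguishing mismatch (gap 6 -> mapq 30) survives a
# mapq >= 20 filter while ties fail it.
.mapqFromScores <- function(AS, XS) {
  ifelse(is.na(XS), 42L,
         ifelse(XS >= AS, 0L, pmin(42L, 5L * (AS - XS))))
}

#' Align reads to an indexed reference (seeded, ungapped, end-to-end)
#'
#' Candidate placements are found by exact seed match (non-overlapping
#' k-mers across the read, plus one flush with the 3' end) on both strands,
#' then scored over the full read length without gaps. The best placement is
#' reported with its score AS; XS is the score of the best placement at a
#' different (target, position, strand), absent (NA) if the read has a
#' single candidate placement. Ties are broken deterministically by target,
#' then position, then strand. Reads with no seed hit are omitted
#' (unmapped). An alignment with `mismatches` mismatches and no ambiguous
#' columns has AS = -mismatchPenalty * mismatches.
#'
#' @param reads QualityScaledDNAStringSet, DNAStringSet, or named character.
#' @param index a [SeedIndex-class] from [seedIndex()].
#' @param scoring a [ScoringScheme-class].
#' @return data.frame: read_id, target_id, start (0-based), strand, AS, XS
#'   (NA when absent), mismatches, mapq.
#' @export
alignReads <- function(reads, index, scoring = scoringScheme()) {
  seqs <- .asNamedChars(reads)
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(seqs))
  res <- .cpp_align(index@ptr, unname(seqs),
                    scoring@mismatchPenalty, scoring@ambiguousPenalty)
  mapped <- !is.na(res$target)
  out <- data.frame(
    read_id = ids[mapped],
    target_id = index@targets[res$target[mapped]],
    start = res$start[mapped],
    strand = res$strand[mapped],
    AS = res$AS[mapped],
    XS = res$XS[mapped],
    mismatches = res$mismatches[mapped],
    stringsAsFactors = FALSE
  )
  out$mapq <- .mapqFromScores(out$AS, out$XS)
  out
}

#' Filter alignments on preferential mapping and mapping quality
#'
#' Removes records whose best placement is tied with an alternative
#' (AS == XS: no preferential mapping) and records with mapq below
#' `minMapq`. Lowering `minMapq` never removes a previously kept record.
#'
#' @param records alignment data.frame from [alignReads()] or [readSam()].
#' @param minMapq minimum mapping quality (default 20).
#' @return The filtered data.frame.
#' @export
filterAlignments <- function(records, minMapq = 20L) {
  if (!"mapq" %in% names(records))
    stop("records must carry a mapq column")
  tie <- !is.na(records$XS) & records$XS >= records$AS
  records[!tie & records$mapq >= minMapq, , drop = FALSE]
}

#' Write alignments as SAM
#'
#' Minimal single-end SAM output: @HD/@SQ header, FLAG 0/16 by strand,
#' 1-based POS, full-length match CIGAR, and AS:i/XS:i/NM:i tags. Reads are
#' written in the orientation of the original read (SEQ is reverse
#' complemented for minus-strand alignments, per the SAM standard).
#'
#' @param records alignment data.frame from [alignReads()].
#' @param reads the reads that were aligned (named, for SEQ output).
#' @param index the [SeedIndex-class] used (for @SQ lines).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSam <- function(records, reads, index, path) {
  seqs <- .asNamedChars(reads)
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", index@targets, index@widths))
  seq <- seqs[records$read_id]
  minus <- records$strand == "-"
  if (any(minus)) {
    seq[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seq[minus])))
  }
  body <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*\tAS:i:%d\tNM:i:%d%s",
    records$read_id, ifelse(minus, 16L, 0L), records$target_id,
    records$start + 1L, records$mapq, nchar(seq), seq, records$AS,
    records$mismatches,
    ifelse(is.na(records$XS), "", sprintf("\tXS:i:%d", records$XS)))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read alignments from SAM
#'
#' Accepts external SAM with AS:i (and optional XS:i, NM:i) tags; records
#' without an AS tag are rejected with an error, since downstream
#' classification depends on best-score semantics. Unmapped records
#' (FLAG 0x4) are skipped.
#'
#' @param path SAM file path.
#' @return data.frame in the layout of [alignReads()] output.
#' @export
readSam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) {
    return(data.frame(read_id = character(), target_id = character(),
                      start = integer(), strand = character(),
                      AS = integer(), XS = integer(), mismatches = integer(),
                      mapq = integer(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  getf <- function(i) vapply(fields, `[[`, character(1), i)
  flag <- as.integer(getf(2))
  keep <- bitwAnd(flag, 4L) == 0L
  tag <- function(name) {
    vapply(fields, function(f) {
      hit <- f[startsWith(f, paste0(name, ":i:"))]
      if (length(hit)) as.integer(sub(".*:i:", "", hit[1])) else NA_integer_
    }, integer(1))
  }
  AS <- tag("AS")
  if (any(is.na(AS[keep])))
    stop("SAM records without an AS:i tag cannot be used")
  out <- data.frame(
    read_id = getf(1), target_id = getf(3),
    start = as.integer(getf(4)) - 1L,
    strand = ifelse(bitwAnd(flag, 16L) != 0L, "-", "+"),
    AS = AS, XS = tag("XS"), mismatches = tag("NM"),
    mapq = as.integer(getf(5)),
    stringsAsFactors = FALSE
  )
  out[keep, , drop = FALSE]
}
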