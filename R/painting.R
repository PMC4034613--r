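# Electronic chromosome painting: genome-wide binned densities of
# subgenome-tagged SNPs and a scan for regions represented by a single
# homoeologue.

#' Bin subgenome-tagged SNP positions along chromosomes
#'
#' Bins tile each chromosome's [0, length) without overlap (half-open: a SNP
#' at position `binSize` falls in the second bin). Each SNP increments
#' exactly one bin of its subgenome's track, so per-label bin sums equal the
#' per-label input SNP counts.
#'
#' @param snps data.frame with chrom, pos (0-based) and label (subgenome
#'   tag, e.g. "D3"/"D4").
#' @param chromSizes named vector of chromosome lengths.
#' @param binSize bin width in bp (default 100 kb; pick a smaller value for
#'   small synthetic genomes).
#' @return A [PaintTrack-class].
#' @export
binSnps <- function(snps, chromSizes, binSize = 100000L) {
  binSize <- as.integer(binSize)
  if (is.null(names(chromSizes))) stop("chromSizes must be named")
  bad <- !snps$chrom %in% names(chromSizes)
  if (any(bad)) {
    stop("SNPs on unknown chromosome(s): ",
         paste(unique(snps$chrom[bad]), collapse = ", "))
  }
  over <- snps$pos >= chromSizes[snps$chrom] | snps$pos < 0L
  if (any(over)) {
    off <- snps[over, , drop = FALSE]
    stop("SNP position(s) outside chromosome bounds: ",
         paste(sprintf("%s:%d", off$chrom, off$pos)[seq_len(min(5,
               nrow(off)))], collapse = ", "))
  }
  labels <- sort(unique(as.character(snps$label)))
  bins <- lapply(names(chromSizes), function(ch) {
    len <- chromSizes[[ch]]
    nb <- ceiling(len / binSize)
    start0 <- (seq_len(nb) - 1L) * binSize
    GenomicRanges::GRanges(ch, IRanges::IRanges(start0 + 1L,
                                                pmin(start0 + binSize, len)))
  })
  gr <- suppressWarnings(do.call(c, bins))
  counts <- matrix(0L, length(gr), length(labels),
                   dimnames = list(NULL, labels))
  chromOffset <- cumsum(c(0L, vapply(bins, length, integer(1))))
  names(chromOffset) <- c(names(chromSizes), "_end")
  for (lab in labels) {
    s <- snps[snps$label == lab, , drop = FALSE]
    idx <- chromOffset[s$chrom] + s$pos %/% binSize + 1L
    tab <- table(idx)
    counts[as.integer(names(tab)), lab] <-
      counts[as.integer(names(tab)), lab] + as.integer(tab)
  }
  mc <- S4Vectors::DataFrame(counts)
  names(mc) <- labels
  S4Vectors::mcols(gr) <- mc
  new("PaintTrack", bins = gr, labels = labels, binSize = binSize)
}

#' Scan a paint track for single-homoeologue regions
#'
#' A sliding window of `windowBins` consecutive bins is flagged iff its
#' total SNP count is at least `minInformative` and at least one subgenome's
#' count within it is exactly zero. Overlapping flagged windows are merged
#' into candidate intervals. A balanced allopolyploid should produce no
#' intervals; a deletion of one subgenome produces intervals overlapping the
#' lost block.
#'
#' @param track a [PaintTrack-class].
#' @param windowBins window width in bins (default 5).
#' @param minInformative minimum total SNPs in a window for it to be
#'   informative (default 10).
#' @return GRanges of merged flagged intervals with a `missing_label`
#'   metadata column (comma-joined when both labels are absent in different
#'   windows of the interval).
#' @export
scanSingleHomoeologRegions <- function(track, windowBins = 5L,
                                       minInformative = 10L) {
  gr <- track@bins
  labels <- track@labels
  flagged <- GenomicRanges::GRanges()
  for (ch in unique(as.character(GenomicRanges::seqnames(gr)))) {
    sel <- as.character(GenomicRanges::seqnames(gr)) == ch
    sub <- gr[sel]
    m <- as.matrix(S4Vectors::mcols(sub))
    nb <- nrow(m)
    if (nb < windowBins) next
    roll <- function(v) {
      cs <- cumsum(c(0, v))
      cs[(windowBins + 1):(nb + 1)] - cs[1:(nb - windowBins + 1)]
    }
    sums <- vapply(seq_along(labels), function(j) roll(m[, j]),
                   numeric(nb - windowBins + 1))
    if (is.null(dim(sums))) sums <- matrix(sums, nrow = 1)
    tot <- rowSums(sums)
    zero <- sums == 0
    hit <- which(tot >= minInformative & rowSums(zero) > 0)
    if (!length(hit)) next
    ws <- GenomicRanges::GRanges(ch, IRanges::IRanges(
      GenomicRanges::start(sub)[hit],
      GenomicRanges::end(sub)[hit + windowBins - 1L]))
    ws$missing_label <- vapply(hit, function(h)
      paste(labels[zero[h, ]], collapse = ","), character(1))
    flagged <- suppressWarnings(c(flagged, ws))
  }
  if (!length(flagged)) {
    out <- GenomicRanges::GRanges()
    out$missing_label <- character()
    return(out)
  }
  merged <- GenomicRanges::reduce(flagged)
  ov <- GenomicRanges::findOverlaps(merged, flagged)
  lab <- tapply(flagged$missing_label[S4Vectors::subjectHits(ov)],
                S4Vectors::queryHits(ov), function(x)
                  paste(sort(unique(unlist(strsplit(x, ",")))),
                        collapse = ","))
  merged$missing_label <- unname(lab[as.character(seq_along(merged))])
  merged
}

#' Export a paint track as bedGraph (one file per subgenome)
#'
#' @param track a [PaintTrack-class].
#' @param prefix output path prefix; files are `<prefix>.<label>.bedGraph`.
#' @param perKb write counts per kb instead of raw counts.
#' @return The written paths, invisibly.
#' @export
exportBedGraph <- function(track, prefix, perKb = FALSE) {
  gr <- track@bins
  paths <- character(0)
  for (lab in track@labels) {
    v <- S4Vectors::mcols(gr)[[lab]]
    if (perKb) v <- v / (GenomicRanges::width(gr) / 1000)
    path <- paste0(prefix, ".", lab, ".bedGraph")
    lines <- c(sprintf("track type=bedGraph name=\"%s\"", lab),
               sprintf("%s\t%d\t%d\t%g",
                       as.character(GenomicRanges::seqnames(gr)),
                       GenomicRanges::start(gr) - 1L,
                       GenomicRanges::end(gr), v))
    writeLines(lines, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Write flagged intervals as BED
#'
#' @param regions GRanges from [scanSingleHomoeologRegions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(regions, path) {
  if (!length(regions)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  name <- if (!is.null(regions$missing_label))
    paste0("missing_", regions$missing_label) else "."
  writeLines(sprintf("%s\t%d\t%d\t%s",
                     as.character(GenomicRanges::seqnames(regions)),
                     GenomicRanges::start(regions) - 1L,
                     GenomicRanges::end(regions), name), path)
  invisible(path)
}

#' Plot electronic chromosome painting
#'
#' One panel per chromosome; per-bin SNP counts of the two subgenomes are
#' drawn as opposing colored bars around the chromosome axis.
#'
#' @param track a [PaintTrack-class].
#' @param colors one color per label.
#' @param file optional PNG path; plots to the active device when NULL.
#' @return NULL, invisibly.
#' @export
plotPaintTracks <- function(track, colors = c("blue", "red"), file = NULL) {
  gr <- track@bins
  chroms <- unique(as.character(GenomicRanges::seqnames(gr)))
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 140 * length(chroms))
    on.exit(grDevices::dev.off())
  }
  graphics::par(mfrow = c(length(chroms), 1), mar = c(2, 4, 1, 1))
  m <- as.matrix(S4Vectors::mcols(gr))
  top <- max(m, 1)
  for (ch in chroms) {
    sel <- as.character(GenomicRanges::seqnames(gr)) == ch
    x0 <- GenomicRanges::start(gr)[sel] - 1L
    x1 <- GenomicRanges::end(gr)[sel]
    graphics::plot(NULL, xlim = c(0, max(x1)), ylim = c(-top, top),
                   xlab = "", ylab = ch, yaxt = "n", bty = "n")
    graphics::abline(h = 0, col = "grey60")
    graphics::rect(x0, 0, x1, m[sel, 1], col = colors[1], border = NA)
    if (ncol(m) > 1)
      graphics::rect(x0, -m[sel, 2], x1, 0, col = colors[2], border = NA)
  }
  invisible(NULL)
}
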