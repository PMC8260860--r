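# GRanges spanning whole chromosomes of a genome model (optionally autosomes).
.genomeSpace <- function(genome, autosomesOnly = TRUE) {
  si <- genome@seqinfo
  nm <- GenomeInfoDb::seqnames(si)
  if (autosomesOnly) nm <- intersect(nm, genome@autosomes)
  GRanges(nm, IRanges(1L, GenomeInfoDb::seqlengths(si)[nm]),
          seqinfo = si)
}

.asGRanges <- function(x) {
  if (is(x, "GRanges")) granges(x) else stop("expected a GRanges-derived object")
}

#' Number of distinct bases covered by a peak set
#'
#' The quantity `A` of the enrichment fold: bases covered by at least one
#' interval, each base counted once regardless of how many intervals
#' overlap it.
#'
#' @param peaks A [PeakSet-class] or `GRanges`.
#' @param genome A [GenomeModel-class].
#' @param autosomesOnly Restrict to the genome's autosomes (default `TRUE`,
#'   as enrichment is tested on autosomes only).
#' @return Numeric bp count.
#' @examples
#' gm <- GenomeModel("1", 1000)
#' p <- PeakSet(GRanges("1", IRanges(c(1, 51), c(100, 150))), genome = gm)
#' coverageBp(p, gm)  # 150: overlapping bases counted once
#' @export
coverageBp <- function(peaks, genome, autosomesOnly = TRUE) {
  gr <- reduce(.asGRanges(peaks))
  gr <- GenomicRanges::intersect(gr, .genomeSpace(genome, autosomesOnly),
                                 ignore.strand = TRUE)
  sum(as.numeric(width(gr)))
}

#' Consensus peaks across replicate samples
#'
#' Every genomic position is classified as under a peak or not in each
#' sample; positions under a peak in at least `minSupport` samples (default
#' 2) form the consensus, emitted as maximal intervals. Support is counted
#' per sample: overlapping intervals within one sample contribute support 1.
#'
#' @param peaksets List of [PeakSet-class] objects on the same genome.
#' @param genome A [GenomeModel-class].
#' @param minSupport Minimum number of supporting samples per base.
#' @param label Label for the output set.
#' @return A [PeakSet-class] of non-overlapping sorted intervals with a
#'   `maxSupport` metadata column (maximum per-base support within each
#'   interval). `shapeClass` is inherited from the inputs (which must agree).
#' @export
consensusPeaks <- function(peaksets, genome, minSupport = 2L,
                           label = "consensus") {
  if (minSupport < 1) stop("minSupport must be >= 1")
  stopifnot(length(peaksets) >= 1)
  shapes <- unique(vapply(peaksets, shapeClass, ""))
  if (length(shapes) != 1)
    stop("all peak sets must share one shape class")
  if (minSupport > length(peaksets)) {
    warning("minSupport exceeds the number of samples: consensus is empty")
    return(PeakSet(GRanges(seqinfo = genome@seqinfo), shapeClass = shapes,
                   label = label, genome = genome))
  }
  sl <- GenomeInfoDb::seqlengths(genome@seqinfo)
  covs <- lapply(peaksets, function(p) {
    gr <- reduce(.asGRanges(p))
    GenomeInfoDb::seqlevels(gr) <- names(sl)
    coverage(gr, width = sl)
  })
  total <- Reduce(`+`, covs)
  views <- slice(total, lower = minSupport, rangesOnly = FALSE)
  gr <- GRanges(
    rep(names(views), lengths(views)),
    unlist(IRanges::ranges(views), use.names = FALSE),
    maxSupport = unlist(lapply(views, viewMaxs), use.names = FALSE),
    seqinfo = genome@seqinfo
  )
  PeakSet(gr, shapeClass = shapes, label = label, genome = genome)
}

#' Single-base anchor of each peak
#'
#' Narrow peaks are anchored at their summit (peak-caller column 10);
#' broad peaks, and narrow peaks lacking a summit, at their midpoint
#' (halfway between start and end, floor convention).
#'
#' @param peaks A [PeakSet-class].
#' @return Integer vector of 1-based anchor positions, one per peak.
#' @export
peakAnchors <- function(peaks) {
  n <- length(peaks)
  if (n == 0) return(integer(0))
  mid <- (start(peaks) + end(peaks) - 1L) %/% 2L + 1L
  if (shapeClass(peaks) == "narrow" &&
      "summit" %in% colnames(mcols(peaks))) {
    summit <- mcols(peaks)$summit
    miss <- is.na(summit)
    if (any(miss))
      warning(sprintf("%d narrow peak(s) lack a summit; midpoint used", sum(miss)))
    anchor <- ifelse(miss, mid, start(peaks) + summit)
  } else {
    if (shapeClass(peaks) == "narrow")
      warning("narrow peaks lack a summit column; midpoints used")
    anchor <- mid
  }
  as.integer(anchor)
}

#' Anchors as a width-1 GRanges
#' @param peaks A [PeakSet-class].
#' @return `GRanges` of width-1 anchor positions carrying a `peakIdx`
#'   metadata column pointing back into `peaks`.
#' @export
anchorRanges <- function(peaks) {
  a <- peakAnchors(peaks)
  GRanges(seqnames(peaks), IRanges(a, width = 1L),
          peakIdx = seq_along(peaks),
          seqinfo = GenomeInfoDb::seqinfo(peaks))
}

#' Distance from positions to the nearest transcription start site
#'
#' Unsigned base-pair distance `|position - TSS|` to the nearest TSS on the
#' same chromosome. Positions on chromosomes without any TSS get `NA` and
#' are reported with a warning (they are excluded from distance-stratified
#' analyses).
#'
#' @param positions `GRanges` of width-1 positions (e.g. [anchorRanges()]
#'   output or a [SnpRanges-class]).
#' @param tss `GRanges` of width-1 TSS positions (see [geneTss()]).
#' @return Numeric vector of distances, `NA` where undefined.
#' @export
distanceToNearestTss <- function(positions, tss) {
  stopifnot(all(width(positions) == 1L), all(width(tss) == 1L))
  out <- rep(NA_real_, length(positions))
  tssByChrom <- split(start(tss), as.character(seqnames(tss)))
  posChrom <- as.character(seqnames(positions))
  for (chr in unique(posChrom)) {
    idx <- which(posChrom == chr)
    tp <- tssByChrom[[chr]]
    if (is.null(tp) || length(tp) == 0) next
    tp <- sort(tp)
    p <- start(positions)[idx]
    # nearest sorted neighbour via findInterval
    k <- findInterval(p, tp)
    lo <- pmax(k, 1L); hi <- pmin(k + 1L, length(tp))
    out[idx] <- pmin(abs(p - tp[lo]), abs(p - tp[hi]))
  }
  if (anyNA(out))
    warning(sprintf(
      "%d position(s) lie on chromosomes without a TSS; distance set to NA",
      sum(is.na(out))))
  out
}
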