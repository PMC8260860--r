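# Independent brute-force oracles used to check the interval, counting and
# hypergeometric machinery. These deliberately avoid the code paths they
# verify: everything here is per-base bitmaps, all-pairs scans and exact
# pmf summation.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

# per-base coverage bitmap of a GRanges over one genome model
oracleCoverageBp <- function(gr, genome, autosomesOnly = TRUE) {
  nm <- GenomeInfoDb::seqnames(genome@seqinfo)
  if (autosomesOnly) nm <- intersect(nm, autosomes(genome))
  len <- GenomeInfoDb::seqlengths(genome@seqinfo)
  total <- 0
  for (chr in nm) {
    bit <- logical(len[[chr]])
    sel <- as.character(seqnames(gr)) == chr
    for (i in which(sel)) {
      s <- max(start(gr)[i], 1L); e <- min(end(gr)[i], len[[chr]])
      if (e >= s) bit[s:e] <- TRUE
    }
    total <- total + sum(bit)
  }
  total
}

# per-base vote bitmap consensus: maximal runs of bases covered by >= k sets
oracleConsensus <- function(grList, genome, minSupport) {
  len <- GenomeInfoDb::seqlengths(genome@seqinfo)
  out <- list()
  for (chr in GenomeInfoDb::seqnames(genome@seqinfo)) {
    votes <- integer(len[[chr]])
    for (gr in grList) {
      bit <- logical(len[[chr]])
      sel <- as.character(seqnames(gr)) == chr
      for (i in which(sel)) bit[start(gr)[i]:end(gr)[i]] <- TRUE
      votes <- votes + bit
    }
    hit <- votes >= minSupport
    if (!any(hit)) next
    r <- rle(hit)
    ends <- cumsum(r$lengths); starts <- c(1L, head(ends, -1) + 1L)
    keep <- r$values
    out[[chr]] <- GRanges(chr, IRanges(starts[keep], ends[keep]))
  }
  if (length(out) == 0) return(GRanges())
  # per-chromosome pieces carry disjoint seqlevels; combining them warns
  sort(suppressWarnings(do.call(c, unname(out))))
}

# exhaustive min |pos - tss| scan
oracleNearestTss <- function(posChrom, pos, tssChrom, tss) {
  vapply(seq_along(pos), function(i) {
    d <- abs(pos[i] - tss[tssChrom == posChrom[i]])
    if (length(d) == 0) NA_real_ else min(d)
  }, 0)
}

# all-pairs fragment-in-peak counting
oracleFragmentCounts <- function(peaks, frags) {
  vapply(seq_along(peaks), function(i) {
    sum(as.character(seqnames(frags)) == as.character(seqnames(peaks))[i] &
          start(frags) <= end(peaks)[i] & end(frags) >= start(peaks)[i])
  }, 0L)
}

# exact hypergeometric pmf via lchoose; tails by summation
oracleHyperTails <- function(A, B, C, D) {
  support <- max(0, A + B - D):min(A, B)
  logpmf <- lchoose(B, support) + lchoose(D - B, A - support) - lchoose(D, A)
  pmf <- exp(logpmf)
  list(pEnrich = sum(pmf[support >= C]), pDeplete = sum(pmf[support <= C]))
}

# coordinate key, ignoring seqinfo, for cross-representation comparisons
grKey <- function(gr) paste(seqnames(gr), start(gr), end(gr))

# random interval set on a small genome
randomIntervals <- function(n, genome, maxWidth = 500) {
  nm <- GenomeInfoDb::seqnames(genome@seqinfo)
  len <- GenomeInfoDb::seqlengths(genome@seqinfo)
  chr <- sample(nm, n, replace = TRUE)
  w <- sample.int(maxWidth, n, replace = TRUE)
  s <- vapply(seq_len(n), function(i)
    sample.int(max(len[[chr[i]]] - w[i], 1L), 1L), 0L)
  sort(GRanges(chr, IRanges(s, width = w), seqinfo = genome@seqinfo))
}
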