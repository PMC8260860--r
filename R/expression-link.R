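#' Pair peaks with genes within a window of the TSS
#'
#' Every (peak, gene) pair whose anchor-to-TSS distance is at most `window`
#' bp (default 100 kb). A peak may pair with many genes and a gene with
#' many peaks. Distances use the peak anchor: summit for narrow peaks,
#' midpoint for broad.
#'
#' @param consensus A [PeakSet-class].
#' @param genes `GRanges` of gene models with `gene_id`.
#' @param window Maximum anchor-to-TSS distance in bp.
#' @return A `data.frame` with `peak_id`, `gene_id`, `tss_distance`.
#' @export
pairPeaksGenes <- function(consensus, genes, window = 100000) {
  anchors <- anchorRanges(consensus)
  tss <- geneTss(genes)
  near <- suppressWarnings(GRanges(
    seqnames(tss),
    IRanges(pmax(start(tss) - window, 1L), start(tss) + window),
    seqinfo = GenomeInfoDb::seqinfo(tss)))
  near <- trim(near)
  hits <- findOverlaps(anchors, near, ignore.strand = TRUE)
  pi <- mcols(anchors)$peakIdx[queryHits(hits)]
  gi <- subjectHits(hits)
  d <- abs(start(anchors)[queryHits(hits)] - start(tss)[gi])
  keep <- d <= window
  ids <- if (!is.null(names(consensus))) names(consensus) else
    sprintf("peak_%d", seq_along(consensus))
  data.frame(peak_id = ids[pi[keep]],
             gene_id = mcols(tss)$gene_id[gi[keep]],
             tss_distance = d[keep],
             stringsAsFactors = FALSE)
}

#' Correlate peak height with gene expression across samples
#'
#' Pearson correlation of normalized peak signal against gene counts over
#' matched samples, for each (peak, gene) pair. The two-sided p-value uses
#' the t-transform `t = r * sqrt(n-2) / sqrt(1-r^2)` with `n - 2` degrees
#' of freedom. Pairs in which either vector has zero variance get `NA` and
#' are excluded from summaries.
#'
#' @param pairs Data frame from [pairPeaksGenes()].
#' @param peakCpm Peak x sample matrix of normalized signal (rownames =
#'   peak ids).
#' @param geneCounts Gene x sample matrix (rownames = gene ids), as
#'   provided (no re-normalization).
#' @param matchedSamples Character vector of sample names present in both
#'   matrices; default: their common columns.
#' @param alpha Significance threshold.
#' @return `pairs` with added columns `r`, `p_value`, `n_samples`,
#'   `significant`.
#' @export
correlatePeakGene <- function(pairs, peakCpm, geneCounts,
                              matchedSamples = intersect(colnames(peakCpm),
                                                         colnames(geneCounts)),
                              alpha = 0.05) {
  n <- length(matchedSamples)
  if (n < 3) stop("need at least 3 matched samples for a defined p-value")
  x <- peakCpm[pairs$peak_id, matchedSamples, drop = FALSE]
  y <- geneCounts[pairs$gene_id, matchedSamples, drop = FALSE]
  xc <- x - rowMeans(x)
  yc <- y - rowMeans(y)
  sx <- sqrt(rowSums(xc^2))
  sy <- sqrt(rowSums(yc^2))
  r <- rowSums(xc * yc) / (sx * sy)
  r[sx == 0 | sy == 0] <- NA_real_
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  out <- pairs
  out$r <- r
  out$p_value <- p
  out$n_samples <- n
  out$significant <- !is.na(p) & p < alpha
  out
}

#' Peaks correlated with the expression of at least one gene
#'
#' @param results Data frame from [correlatePeakGene()].
#' @param consensus The [PeakSet-class] the pairs were built from.
#' @param direction Keep pairs of `"any"` (default), `"positive"` or
#'   `"negative"` correlation sign.
#' @param alpha Significance threshold on the pair p-value.
#' @return A [PeakSet-class] of the unique peaks participating in at least
#'   one significant pair of the requested direction.
#' @export
correlatedPeakSet <- function(results, consensus,
                              direction = c("any", "positive", "negative"),
                              alpha = 0.05) {
  direction <- match.arg(direction)
  keep <- !is.na(results$p_value) & results$p_value < alpha
  if (direction == "positive") keep <- keep & results$r > 0
  if (direction == "negative") keep <- keep & results$r < 0
  ids <- unique(results$peak_id[keep])
  allIds <- if (!is.null(names(consensus))) names(consensus) else
    sprintf("peak_%d", seq_along(consensus))
  sub <- consensus[allIds %in% ids]
  sub@label <- paste0(consensus@label, "_correlated_", direction)
  sub
}

#' Summarize correlation directions
#'
#' Counts of significant positive and negative correlations; the majority
#' direction mirrors the expectation that repressive marks correlate
#' negatively with expression while activating marks correlate positively.
#'
#' @param results Data frame from [correlatePeakGene()].
#' @return A one-row `data.frame` with `n_pairs`, `n_significant`,
#'   `n_positive`, `n_negative`, `frac_significant`, `majority_direction`.
#' @export
correlationSummary <- function(results) {
  ok <- !is.na(results$p_value)
  sig <- ok & results$significant
  npos <- sum(sig & results$r > 0)
  nneg <- sum(sig & results$r < 0)
  data.frame(
    n_pairs = sum(ok),
    n_significant = sum(sig),
    n_positive = npos,
    n_negative = nneg,
    frac_significant = sum(sig) / max(sum(ok), 1),
    majority_direction = if (npos == nneg) "tied" else
      if (npos > nneg) "positive" else "negative",
    stringsAsFactors = FALSE
  )
}
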