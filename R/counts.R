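#' Count fragments overlapping consensus peaks
#'
#' A fragment is counted for every peak it overlaps by at least one base;
#' a fragment spanning several peaks increments all of them.
#'
#' @param fragments Named list of `GRanges` (one element per sample) or a
#'   single `GRanges`.
#' @param consensus A [PeakSet-class] of consensus peaks.
#' @return Integer matrix, peaks x samples. Row names are taken from
#'   `names(consensus)` or generated as `peak_<i>`.
#' @export
countFragmentsInPeaks <- function(fragments, consensus) {
  if (is(fragments, "GRanges")) fragments <- list(sample1 = fragments)
  peaks <- granges(consensus)
  mat <- vapply(fragments, function(fr)
    countOverlaps(peaks, fr, minoverlap = 1L, ignore.strand = TRUE),
    integer(length(peaks)))
  if (length(peaks) == 1L) mat <- matrix(mat, nrow = 1,
                                         dimnames = list(NULL, names(fragments)))
  rownames(mat) <- if (!is.null(names(consensus))) names(consensus) else
    sprintf("peak_%d", seq_along(peaks))
  mat
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values scale factors (doubly trimmed weighted mean of
#' log-ratios against a reference sample, trims 30% on M and 5% on A),
#' re-centred to geometric mean 1. Library sizes default to the supplied
#' full library sizes; when absent, column sums are used with a warning.
#'
#' @param counts Feature x sample matrix of non-negative counts.
#' @param libSizes Optional per-sample full library sizes (total fragments
#'   sequenced), in column order.
#' @param logratioTrim,sumTrim Trim fractions for M and A values.
#' @return Named numeric vector of positive factors, geometric mean 1.
#' @export
tmmFactors <- function(counts, libSizes = NULL,
                       logratioTrim = 0.30, sumTrim = 0.05) {
  stopifnot(is.matrix(counts), ncol(counts) >= 2)
  if (any(colSums(counts) == 0))
    stop("every sample must have at least one nonzero feature")
  if (is.null(libSizes)) {
    warning("full library sizes not supplied; using column sums")
    libSizes <- colSums(counts)
  }
  stopifnot(length(libSizes) == ncol(counts), all(libSizes > 0))
  f <- edgeR::calcNormFactors(counts, lib.size = libSizes, method = "TMM",
                              logratioTrim = logratioTrim, sumTrim = sumTrim)
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

#' Normalized counts per million
#'
#' `(count + priorCount) / (libSize * factor) * 1e6`, optionally on the
#' log2 scale. The prior count (default 0.5) keeps log values finite at
#' zero counts.
#'
#' @param counts Feature x sample matrix.
#' @param factors Normalization factors (e.g. [tmmFactors()]); default 1.
#' @param libSizes Per-sample library sizes; default column sums.
#' @param priorCount Pseudocount added before scaling.
#' @param log Return log2 values.
#' @return Numeric matrix of the same shape as `counts`.
#' @export
normalizedCpm <- function(counts, factors = rep(1, ncol(counts)),
                          libSizes = colSums(counts),
                          priorCount = 0.5, log = FALSE) {
  stopifnot(all(factors > 0), all(libSizes > 0),
            length(factors) == ncol(counts),
            length(libSizes) == ncol(counts))
  eff <- libSizes * factors
  cpm <- sweep(counts + priorCount, 2, eff, "/") * 1e6
  if (log) log2(cpm) else cpm
}

#' Assemble a peak count experiment
#'
#' Bundles counts, consensus peaks and sample metadata into a
#' [SummarizedExperiment::SummarizedExperiment] whose `rowRanges` are the
#' consensus peaks and whose `colData` carries `animal`, `tissue` and
#' `libSize`.
#'
#' @param counts Peak x sample matrix.
#' @param consensus A [PeakSet-class] with one range per count row.
#' @param sampleSheet Data frame with `sample`, `animal`, `tissue` and
#'   optionally `libSize`.
#' @return A `RangedSummarizedExperiment` with assay `counts`.
#' @export
peakCountExperiment <- function(counts, consensus, sampleSheet) {
  stopifnot(nrow(counts) == length(consensus))
  meta <- sampleSheet[match(colnames(counts), sampleSheet$sample), , drop = FALSE]
  if (anyNA(meta$sample)) stop("count columns missing from sample sheet")
  if (is.null(meta$libSize)) meta$libSize <- colSums(counts)
  rr <- granges(consensus)
  names(rr) <- rownames(counts)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowRanges = rr,
    colData = DataFrame(meta, row.names = meta$sample))
}
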