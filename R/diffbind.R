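# Row-wise variance without forming a full copy per group.
.rowVars <- function(x) {
  m <- rowMeans(x)
  rowSums((x - m)^2) / (ncol(x) - 1L)
}

# Welch two-sample t-test per row of a log2-CPM matrix: focal vs rest.
.welchRows <- function(mat, focal) {
  x <- mat[, focal, drop = FALSE]
  y <- mat[, !focal, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  if (n1 < 2 || n2 < 2)
    return(list(fold = m1 - m2, p = rep(NA_real_, nrow(mat))))
  v1 <- .rowVars(x); v2 <- .rowVars(y)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  # constant rows: no variance, no evidence either way
  p[se2 == 0] <- 1
  list(fold = m1 - m2, p = p)
}

#' Tissue-versus-rest differential binding
#'
#' For each consensus peak, compares TMM-normalized log2-CPM in the focal
#' tissue against all other tissues. A peak is called significantly
#' differentially bound when the p-value is below `alpha` (default 0.05)
#' and binding is more than `minFold`-fold (default 2) different from the
#' average binding in all other tissues, in either direction.
#'
#' The default per-peak test is a Welch two-sample t-test on log2-CPM; any
#' function `(focalMatrix, restMatrix) -> p-value vector` can be plugged in
#' via `testFun` (e.g. a negative-binomial GLM wrapper).
#'
#' @param counts Peak x sample count matrix, or a `SummarizedExperiment`
#'   from [peakCountExperiment()].
#' @param sampleSheet Sample sheet (ignored when `counts` is a
#'   `SummarizedExperiment`).
#' @param tissue Focal tissue.
#' @param alpha Significance threshold on the raw p-value.
#' @param minFold Fold-change threshold on the natural scale.
#' @param restAverage `"samples"` (default): the rest mean averages over
#'   samples; `"tissues"`: over per-tissue means, so tissues with more
#'   replicates do not dominate.
#' @param factors,libSizes Optional TMM factors and library sizes; computed
#'   from the data when missing.
#' @param testFun Optional replacement p-value function.
#' @param adjust Also report Benjamini-Hochberg adjusted p-values.
#' @return A `data.frame` with `peak_id`, `tissue`, `log2_fold`, `p_value`,
#'   `significant`, `direction` (and `p_adj` when `adjust = TRUE`).
#'   `significant` is `NA` when the p-value is undefined (single-sample
#'   group under the default test).
#' @export
differentialBindingTest <- function(counts, sampleSheet = NULL, tissue,
                                    alpha = 0.05, minFold = 2,
                                    restAverage = c("samples", "tissues"),
                                    factors = NULL, libSizes = NULL,
                                    testFun = NULL, adjust = FALSE) {
  restAverage <- match.arg(restAverage)
  if (is(counts, "SummarizedExperiment")) {
    sampleSheet <- as.data.frame(SummarizedExperiment::colData(counts))
    if (is.null(libSizes)) libSizes <- sampleSheet$libSize
    counts <- SummarizedExperiment::assay(counts, "counts")
  }
  stopifnot(!is.null(sampleSheet))
  meta <- sampleSheet[match(colnames(counts), sampleSheet$sample), , drop = FALSE]
  tissues <- meta$tissue
  if (!tissue %in% tissues) stop(sprintf("tissue '%s' not present", tissue))
  if (length(unique(tissues)) < 2) stop("need at least two tissues")
  if (is.null(libSizes)) {
    libSizes <- if (!is.null(meta$libSize)) meta$libSize else colSums(counts)
  }
  if (is.null(factors)) factors <- tmmFactors(counts, libSizes = libSizes)
  lcpm <- normalizedCpm(counts, factors, libSizes, log = TRUE)

  focal <- tissues == tissue
  if (is.null(testFun)) {
    res <- .welchRows(lcpm, focal)
    p <- res$p
  } else {
    p <- testFun(lcpm[, focal, drop = FALSE], lcpm[, !focal, drop = FALSE])
  }
  if (restAverage == "samples") {
    restMean <- rowMeans(lcpm[, !focal, drop = FALSE])
  } else {
    byTissue <- vapply(unique(tissues[!focal]), function(tt)
      rowMeans(lcpm[, tissues == tt, drop = FALSE]), numeric(nrow(lcpm)))
    restMean <- rowMeans(matrix(byTissue, nrow = nrow(lcpm)))
  }
  fold <- rowMeans(lcpm[, focal, drop = FALSE]) - restMean
  sig <- p < alpha & abs(fold) > log2(minFold)
  out <- data.frame(
    peak_id = if (!is.null(rownames(counts))) rownames(counts) else
      sprintf("peak_%d", seq_len(nrow(counts))),
    tissue = tissue,
    log2_fold = fold,
    p_value = p,
    significant = sig,
    direction = ifelse(fold >= 0, "up", "down"),
    stringsAsFactors = FALSE
  )
  if (adjust) out$p_adj <- stats::p.adjust(p, method = "BH")
  rownames(out) <- NULL
  out
}
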