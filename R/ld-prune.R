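#' Squared correlation of two dosage vectors
#'
#' LD `r^2` as the squared Pearson correlation of genotype dosages over
#' pairwise-complete observations. A zero-variance vector makes `r^2`
#' undefined; it is reported as 0 with a warning (such a SNP never prunes
#' a partner).
#'
#' @param g1,g2 Dosage vectors in \{0, 1, 2\}, `NA` allowed.
#' @return `r^2` in `[0, 1]`.
#' @export
pairwiseR2 <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2) stop("need at least 2 complete pairs")
  x <- g1[ok]; y <- g2[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("zero-variance dosage vector: r^2 treated as 0")
    return(0)
  }
  cor(x, y)^2
}

# r^2 matrix for a block of SNP rows, pairwise-complete, zero-variance -> 0.
.r2Block <- function(dos) {
  r <- suppressWarnings(cor(t(dos), use = "pairwise.complete.obs"))
  r[is.na(r)] <- 0
  r^2
}

#' Windowed LD pruning of a SNP set
#'
#' Greedy thinning so that no two retained SNPs within `windowBp` of each
#' other (the 1-Mb window, by default) have `r^2 >= r2Max` (default 0.5).
#' SNPs are scanned per chromosome in genomic order (`mode = "positional"`)
#' or in ascending p-value order (`mode = "by_pvalue"`, so the most
#' significant SNP of each LD region is the one kept); a SNP is dropped
#' when its `r^2` against any already-retained SNP within the window
#' reaches `r2Max`. The scan is evaluated in chunks of `stepSnps` SNPs
#' (the moving step); chunking does not change the result, which is fully
#' determined by the retention contract above.
#'
#' @param snps A [SnpRanges-class] (needs a `pvalue` column for
#'   `mode = "by_pvalue"`).
#' @param dosages SNP x individual dosage matrix aligned with `snps` (rows
#'   in the same order).
#' @param windowBp Window size in bp.
#' @param stepSnps Moving step in SNPs (validated; chunk size of the scan).
#' @param r2Max Pruning threshold.
#' @param mode `"positional"` or `"by_pvalue"`.
#' @return The retained [SnpRanges-class], in original genomic order, with a
#'   `retainedIdx` attribute giving row indices into the input.
#' @export
windowPrune <- function(snps, dosages, windowBp = 1e6, stepSnps = 50,
                        r2Max = 0.5, mode = c("positional", "by_pvalue")) {
  mode <- match.arg(mode)
  if (stepSnps < 1) stop("stepSnps must be >= 1")
  stopifnot(nrow(dosages) == length(snps))
  if (mode == "by_pvalue" && !"pvalue" %in% colnames(mcols(snps)))
    stop("by_pvalue mode requires a pvalue column")

  chrom <- as.character(seqnames(snps))
  pos <- start(snps)
  keep <- logical(length(snps))
  for (chr in unique(chrom)) {
    idx <- which(chrom == chr)
    ord <- if (mode == "by_pvalue")
      idx[order(mcols(snps)$pvalue[idx], pos[idx])] else idx[order(pos[idx])]
    kept <- integer(0)
    for (i in ord) {
      inWin <- kept[abs(pos[kept] - pos[i]) <= windowBp]
      drop <- FALSE
      # scan retained window partners in chunks of stepSnps
      if (length(inWin)) {
        for (chunk in split(inWin, ceiling(seq_along(inWin) / stepSnps))) {
          r2 <- suppressWarnings(
            apply(dosages[chunk, , drop = FALSE], 1, function(g)
              tryCatch(pairwiseR2(g, dosages[i, ]),
                       warning = function(w) 0)))
          if (any(r2 >= r2Max)) { drop <- TRUE; break }
        }
      }
      if (!drop) kept <- c(kept, i)
    }
    keep[kept] <- TRUE
  }
  retained <- which(keep)
  out <- snps[retained]
  attr(out, "retainedIdx") <- retained
  out
}
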