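# One-sided hypergeometric tails for the enrichment quadruple.
# Population: D exchangeable genomic positions, of which B are SNPs;
# A positions are drawn (the bases under regions); C successes observed.
.hyperTails <- function(A, B, C, D) {
  list(
    pEnrich = phyper(C - 1, B, D - B, A, lower.tail = FALSE),
    pDeplete = phyper(C, B, D - B, A, lower.tail = TRUE)
  )
}

.enrichResult <- function(A, B, C, D, regionLabel = "", snpLabel = "") {
  defined <- A > 0 && B > 0
  if (!defined) {
    return(.EnrichmentResult(A = A, B = B, C = C, D = D,
                             regionLabel = regionLabel, snpLabel = snpLabel,
                             defined = FALSE))
  }
  tails <- .hyperTails(A, B, C, D)
  .EnrichmentResult(A = A, B = B, C = C, D = D,
                    fold = (C / A) / (B / D),
                    pEnrich = tails$pEnrich, pDeplete = tails$pDeplete,
                    regionLabel = regionLabel, snpLabel = snpLabel,
                    defined = TRUE)
}

#' Base-pair enrichment of a SNP set in a region set
#'
#' Computes the enrichment fold `(C/A)/(B/D)` where `A` is the number of
#' autosomal bases under the regions, `B` the number of (deduplicated,
#' autosomal) SNP positions, `C` the number of SNP positions under the
#' regions and `D` the autosomal genome size. Significance of enrichment
#' and depletion comes from the hypergeometric distribution treating bases
#' as exchangeable units: drawing `A` of `D` positions, of which `B` are
#' SNPs, `P(X >= C)` tests enrichment and `P(X <= C)` depletion.
#'
#' @param snps A [SnpRanges-class].
#' @param regions A [PeakSet-class] (or `GRanges`).
#' @param genome A [GenomeModel-class]; `D` is its autosomal size.
#' @param autosomesOnly Restrict SNPs and regions to autosomes (default
#'   `TRUE`).
#' @return An [EnrichmentResult-class]; undefined (all-`NA`) when `A == 0`
#'   or `B == 0`.
#' @examples
#' gm <- GenomeModel("1", 1000)
#' peaks <- PeakSet(GRanges("1", IRanges(1, 100)), genome = gm)
#' snps <- SnpRanges("1", c(10, 20, 30, 40, 50, 150, 300, 450, 600, 750), genome = gm)
#' snpEnrichment(snps, peaks, gm)  # fold (5/100)/(10/1000) = 5
#' @export
snpEnrichment <- function(snps, regions, genome, autosomesOnly = TRUE) {
  space <- .genomeSpace(genome, autosomesOnly)
  reg <- GenomicRanges::intersect(reduce(.asGRanges(regions)), space,
                                  ignore.strand = TRUE)
  sn <- .asGRanges(snps)
  sn <- sn[overlapsAny(sn, space, ignore.strand = TRUE)]
  A <- sum(as.numeric(width(reg)))
  B <- length(sn)
  C <- sum(overlapsAny(sn, reg, ignore.strand = TRUE))
  D <- if (autosomesOnly) autosomalBp(genome) else
    sum(as.numeric(GenomeInfoDb::seqlengths(genome@seqinfo)))
  .enrichResult(A, B, as.numeric(C), D,
                regionLabel = if (is(regions, "PeakSet")) regions@label else "",
                snpLabel = if (is(snps, "SnpRanges")) snps@label else "")
}

#' Default 100-kb distance bands up to 1 Mb
#'
#' Half-open bands `[0, 100kb), [100kb, 200kb), ..., [900kb, 1Mb)`.
#'
#' @param width Band width in bp.
#' @param n Number of bands.
#' @return Data frame with `lower` and `upper` (half-open).
#' @export
defaultDistanceBands <- function(width = 100000, n = 10) {
  data.frame(lower = (seq_len(n) - 1) * width, upper = seq_len(n) * width)
}

# Autosomal bases whose distance to the nearest TSS is <= x.
.bpWithinTss <- function(tss, x, space) {
  if (x < 0) return(0)
  win <- suppressWarnings(GRanges(
    seqnames(tss), IRanges(pmax(start(tss) - x, 1L), start(tss) + x),
    seqinfo = GenomeInfoDb::seqinfo(tss)))
  win <- trim(win)
  sum(as.numeric(width(GenomicRanges::intersect(reduce(win), space,
                                                ignore.strand = TRUE))))
}

#' Distance-to-TSS stratified enrichment
#'
#' Enrichment recomputed within distance bands: a band `[lower, upper)`
#' keeps the peaks whose anchor (summit or midpoint) lies at a distance to
#' the nearest TSS inside the band, and the SNPs whose own distance lies in
#' the band. `A` is the covered bp of the selected peaks, `B` the SNPs in
#' the band, `C` the band SNPs under the selected peaks, and `D` (by
#' default) the number of autosomal bases whose distance to the nearest TSS
#' falls in the band; set `bandD = FALSE` to use the whole autosomal
#' genome. Bands holding fewer than `minSnps` SNPs (default 10) are
#' reported as `NA` rather than as unstable estimates.
#'
#' @param snps A [SnpRanges-class].
#' @param regions A [PeakSet-class].
#' @param genes `GRanges` of gene models (TSS source).
#' @param genome A [GenomeModel-class].
#' @param bands Data frame with `lower`/`upper` columns; default
#'   [defaultDistanceBands()].
#' @param minSnps Minimum SNPs per band.
#' @param bandD Use band-restricted `D` (default) or global autosomal `D`.
#' @return Data frame with one row per band: `lower`, `upper`, `A`, `B`,
#'   `C`, `D`, `fold`, `pEnrich`, `pDeplete`.
#' @export
distanceStratifiedEnrichment <- function(snps, regions, genes, genome,
                                         bands = defaultDistanceBands(),
                                         minSnps = 10, bandD = TRUE) {
  stopifnot(all(bands$upper > bands$lower))
  if (is.unsorted(bands$lower) ||
      any(bands$lower[-1] < bands$upper[-nrow(bands)]))
    stop("bands must be ordered and non-overlapping")
  space <- .genomeSpace(genome, autosomesOnly = TRUE)
  tss <- geneTss(genes)

  anchors <- anchorRanges(regions)
  auto <- overlapsAny(anchors, space, ignore.strand = TRUE)
  peakDist <- suppressWarnings(distanceToNearestTss(anchors, tss))
  sn <- .asGRanges(snps)
  snAuto <- overlapsAny(sn, space, ignore.strand = TRUE)
  snpDist <- suppressWarnings(distanceToNearestTss(sn, tss))

  Dglobal <- autosomalBp(genome)
  out <- lapply(seq_len(nrow(bands)), function(i) {
    lo <- bands$lower[i]; hi <- bands$upper[i]
    pk <- which(auto & !is.na(peakDist) & peakDist >= lo & peakDist < hi)
    sb <- which(snAuto & !is.na(snpDist) & snpDist >= lo & snpDist < hi)
    B <- length(sb)
    selReg <- GenomicRanges::intersect(
      reduce(granges(regions)[mcols(anchors)$peakIdx[pk]]), space,
      ignore.strand = TRUE)
    A <- sum(as.numeric(width(selReg)))
    C <- if (B) sum(overlapsAny(sn[sb], selReg, ignore.strand = TRUE)) else 0
    D <- if (bandD)
      .bpWithinTss(tss, hi - 1, space) - .bpWithinTss(tss, lo - 1, space)
    else Dglobal
    if (B < minSnps || A == 0 || D <= 0) {
      data.frame(lower = lo, upper = hi, A = A, B = B, C = C, D = D,
                 fold = NA_real_, pEnrich = NA_real_, pDeplete = NA_real_)
    } else {
      r <- .enrichResult(A, B, as.numeric(C), D)
      data.frame(lower = lo, upper = hi, A = A, B = B, C = C, D = D,
                 fold = r@fold, pEnrich = r@pEnrich, pDeplete = r@pDeplete)
    }
  })
  do.call(rbind, out)
}

#' Chromatin-state overlap enrichment against annotation regions
#'
#' For each (state, annotation) cell the same fold arithmetic as the SNP
#' enrichment, on base counts: `A` = bases in the state, `B` = bases in the
#' annotation, `C` = bases in both, `D` = genome size; fold =
#' `(C/A)/(B/D)`. Also reports each state's genome fraction `A/D`.
#'
#' @param seg A [StateSegmentation-class].
#' @param annotations Named list of [PeakSet-class]/`GRanges` annotation
#'   region sets (e.g. active promoters, tissue-specific genes).
#' @param genome A [GenomeModel-class].
#' @param autosomesOnly Restrict to autosomes (default `FALSE`: the
#'   segmentation annotates the whole genome).
#' @return A list with `fold` (state x annotation matrix, `NA` rows for
#'   empty states) and `genomeFraction` (named vector `A/D` per state).
#' @export
stateOverlapEnrichment <- function(seg, annotations, genome,
                                   autosomesOnly = FALSE) {
  space <- .genomeSpace(genome, autosomesOnly)
  D <- sum(as.numeric(width(space)))
  states <- sort(unique(mcols(seg)$state))
  annGr <- lapply(annotations, function(a)
    GenomicRanges::intersect(reduce(.asGRanges(a)), space, ignore.strand = TRUE))
  Bs <- vapply(annGr, function(g) sum(as.numeric(width(g))), 0)
  fold <- matrix(NA_real_, length(states), length(annotations),
                 dimnames = list(states, names(annotations)))
  frac <- setNames(numeric(length(states)), states)
  for (s in states) {
    sg <- GenomicRanges::intersect(
      reduce(granges(seg)[mcols(seg)$state == s]), space, ignore.strand = TRUE)
    A <- sum(as.numeric(width(sg)))
    frac[s] <- A / D
    if (A == 0) next
    for (j in seq_along(annGr)) {
      if (Bs[j] == 0) next
      C <- sum(as.numeric(width(GenomicRanges::intersect(
        sg, annGr[[j]], ignore.strand = TRUE))))
      fold[s, j] <- (C / A) / (Bs[j] / D)
    }
  }
  list(fold = fold, genomeFraction = frac)
}

#' Long-format report over many enrichment results
#'
#' Binds [EnrichmentResult-class] objects into a long table, optionally
#' averaging fold over a grouping label (e.g. per mark across tissues, the
#' way study-wide figures average per-tissue enrichment).
#'
#' @param results List of [EnrichmentResult-class] objects.
#' @param averageBy `NULL` for the long table, or one of `"regionLabel"`,
#'   `"snpLabel"` to return mean folds per group (undefined results are
#'   dropped from averages).
#' @param adjust Add BH-adjusted enrichment p-values to the long table.
#' @return A `data.frame`.
#' @export
enrichmentReport <- function(results, averageBy = NULL, adjust = FALSE) {
  stopifnot(length(results) >= 1)
  tab <- do.call(rbind, lapply(results, as.data.frame))
  rownames(tab) <- NULL
  if (adjust) tab$pEnrichAdj <- stats::p.adjust(tab$pEnrich, method = "BH")
  if (is.null(averageBy)) return(tab)
  averageBy <- match.arg(averageBy, c("regionLabel", "snpLabel"))
  ok <- tab$defined
  agg <- aggregate(tab$fold[ok], by = list(group = tab[[averageBy]][ok]), FUN = mean)
  names(agg) <- c(averageBy, "mean_fold")
  agg
}
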