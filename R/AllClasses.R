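#' @import methods
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @import GenomeInfoDb
#' @importFrom stats cor pt phyper rnbinom rpois rnorm runif rbinom aggregate var p.adjust setNames
#' @importFrom utils read.table write.table head
NULL

#' Genome model with an autosomal subset
#'
#' Holds the chromosome names and lengths of a (possibly synthetic) genome
#' together with the subset of chromosomes treated as autosomes. Enrichment
#' statistics are computed over the autosomes only, mirroring analyses of the
#' bovine genome where the total genome size is the sum of chromosomes 1-29
#' and sex chromosomes are excluded.
#'
#' @slot seqinfo A [GenomeInfoDb::Seqinfo] with chromosome names and lengths.
#' @slot autosomes Character vector of chromosome names used for enrichment.
#'
#' @seealso [GenomeModel()], [autosomalBp()]
#' @export
setClass("GenomeModel",
  representation(seqinfo = "Seqinfo", autosomes = "character")
)

setValidity("GenomeModel", function(object) {
  si <- object@seqinfo
  msgs <- character()
  if (anyDuplicated(GenomeInfoDb::seqnames(si)))
    msgs <- c(msgs, "chromosome names must be unique")
  len <- GenomeInfoDb::seqlengths(si)
  if (any(is.na(len)) || any(len <= 0))
    msgs <- c(msgs, "all chromosome lengths must be known and > 0")
  if (!all(object@autosomes %in% GenomeInfoDb::seqnames(si)))
    msgs <- c(msgs, "autosomes must be a subset of chromosome names")
  if (length(object@autosomes) == 0)
    msgs <- c(msgs, "at least one autosome is required")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GenomeModel
#'
#' @param names Character vector of chromosome names.
#' @param lengths Integer vector of chromosome lengths in bp.
#' @param autosomes Chromosome names used for enrichment; defaults to all.
#' @return A [GenomeModel-class] object.
#' @examples
#' gm <- GenomeModel(c("1", "2", "X"), c(1e6, 8e5, 5e5), autosomes = c("1", "2"))
#' autosomalBp(gm)
#' @export
GenomeModel <- function(names, lengths, autosomes = names) {
  si <- Seqinfo(seqnames = as.character(names), seqlengths = as.integer(lengths))
  new("GenomeModel", seqinfo = si, autosomes = as.character(autosomes))
}

#' Set of peak intervals from one sample or a consensus
#'
#' A `PeakSet` is a [GenomicRanges::GRanges] (1-based, closed intervals; BED
#' inputs are converted on read) with two extra slots: the peak shape class
#' (`"narrow"` for point-source marks such as H3K4Me3, H3K27ac and CTCF;
#' `"broad"` for domain marks such as H3K4Me1 and H3K27Me3) and a free-text
#' label (mark/tissue/animal). Metadata columns `score` and `summit` are
#' optional; `summit`, when present, is the 0-based offset of the summit from
#' the peak start (narrowPeak column 10 semantics).
#'
#' Peaks are strand-less. Intervals may be stored overlapping; [coverageBp()]
#' counts each base once.
#'
#' @slot shapeClass `"narrow"` or `"broad"`.
#' @slot label Free-text label.
#' @export
setClass("PeakSet",
  contains = "GRanges",
  representation(shapeClass = "character", label = "character"),
  prototype(shapeClass = "narrow", label = "")
)

setValidity("PeakSet", function(object) {
  msgs <- character()
  if (length(object@shapeClass) != 1L ||
      !object@shapeClass %in% c("narrow", "broad"))
    msgs <- c(msgs, "shapeClass must be one of 'narrow', 'broad'")
  if (length(object@label) != 1L)
    msgs <- c(msgs, "label must be a single string")
  if (length(object) && !all(strand(object) == "*"))
    msgs <- c(msgs, "peaks are strand-less: strand must be '*'")
  if ("summit" %in% colnames(mcols(object))) {
    s <- mcols(object)$summit
    bad <- !is.na(s) & (s < 0L | s >= width(object))
    if (any(bad))
      msgs <- c(msgs, "summit offsets must lie in [0, width)")
  }
  len <- seqlengths(object)
  if (length(object) && !all(is.na(len))) {
    idx <- as.character(seqnames(object))
    lim <- len[idx]
    if (any(!is.na(lim) & end(object) > lim))
      msgs <- c(msgs, "intervals extend beyond chromosome ends")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a PeakSet
#'
#' @param gr A `GRanges` of peak intervals (optionally with `score` and
#'   `summit` metadata columns).
#' @param shapeClass `"narrow"` or `"broad"`.
#' @param label Free-text label for the sample (mark/tissue/animal).
#' @param genome Optional [GenomeModel-class]; when given, seqinfo is taken
#'   from it and intervals are validated against chromosome lengths.
#' @return A [PeakSet-class], sorted by (chromosome, start).
#' @export
PeakSet <- function(gr, shapeClass = c("narrow", "broad"), label = "",
                    genome = NULL) {
  shapeClass <- match.arg(shapeClass)
  strand(gr) <- "*"
  if (!is.null(genome)) {
    if (!all(seqlevels(gr) %in% GenomeInfoDb::seqnames(genome@seqinfo)))
      stop("peaks use chromosomes absent from the genome model")
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(genome@seqinfo)
    GenomeInfoDb::seqinfo(gr) <- genome@seqinfo
  }
  gr <- sort(gr, ignore.strand = TRUE)
  new("PeakSet", gr, shapeClass = shapeClass, label = label)
}

#' Set of single-base variant positions
#'
#' Width-1 [GenomicRanges::GRanges] holding putative causal SNP positions
#' (QTL, eQTL, splice QTL, conserved sites, ...). Positions are deduplicated
#' on construction. An optional `pvalue` metadata column carries per-SNP
#' association p-values for significance-aware LD pruning.
#'
#' @slot label Free-text label for the SNP set.
#' @export
setClass("SnpRanges",
  contains = "GRanges",
  representation(label = "character"),
  prototype(label = "")
)

setValidity("SnpRanges", function(object) {
  msgs <- character()
  if (length(object) && any(width(object) != 1L))
    msgs <- c(msgs, "all SNP positions must have width 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SnpRanges from chromosome/position vectors
#'
#' @param chrom Chromosome names.
#' @param pos 1-based positions.
#' @param pvalue Optional per-SNP p-values.
#' @param label Free-text label.
#' @param genome Optional [GenomeModel-class] for seqinfo validation.
#' @return A [SnpRanges-class], sorted and deduplicated by position (for
#'   duplicated positions the smallest p-value is kept).
#' @export
SnpRanges <- function(chrom, pos, pvalue = NULL, label = "", genome = NULL) {
  gr <- GRanges(as.character(chrom), IRanges(as.integer(pos), width = 1L))
  if (!is.null(pvalue)) mcols(gr)$pvalue <- as.numeric(pvalue)
  if (!is.null(genome)) {
    if (!all(seqlevels(gr) %in% GenomeInfoDb::seqnames(genome@seqinfo)))
      stop("SNPs use chromosomes absent from the genome model")
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(genome@seqinfo)
    GenomeInfoDb::seqinfo(gr) <- genome@seqinfo
  }
  if (!is.null(pvalue)) {
    o <- order(as.factor(seqnames(gr)), start(gr), mcols(gr)$pvalue)
  } else {
    o <- order(as.factor(seqnames(gr)), start(gr))
  }
  gr <- gr[o]
  dup <- duplicated(paste(seqnames(gr), start(gr)))
  gr <- gr[!dup]
  new("SnpRanges", gr, label = label)
}

#' Chromatin-state segmentation
#'
#' A genome segmentation (e.g. from a hidden-Markov chromatin-state model)
#' as a [GenomicRanges::GRanges] with a `state` metadata column. Segments
#' must not overlap within a chromosome: every covered base carries at most
#' one state.
#'
#' @slot nStates Number of distinct states in the model.
#' @export
setClass("StateSegmentation",
  contains = "GRanges",
  representation(nStates = "integer")
)

setValidity("StateSegmentation", function(object) {
  msgs <- character()
  if (!"state" %in% colnames(mcols(object)))
    msgs <- c(msgs, "a 'state' metadata column is required")
  if (length(object) > 1L) {
    gr <- sort(object, ignore.strand = TRUE)
    same <- as.character(seqnames(gr))[-1] == as.character(seqnames(gr))[-length(gr)]
    if (any(same & start(gr)[-1] <= end(gr)[-length(gr)]))
      msgs <- c(msgs, "segments must not overlap within a chromosome")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a StateSegmentation
#'
#' @param gr A `GRanges` with a `state` metadata column.
#' @param nStates Number of states; defaults to the number of distinct labels.
#' @return A [StateSegmentation-class], sorted.
#' @export
StateSegmentation <- function(gr, nStates = length(unique(mcols(gr)$state))) {
  strand(gr) <- "*"
  gr <- sort(gr, ignore.strand = TRUE)
  new("StateSegmentation", gr, nStates = as.integer(nStates))
}

#' Result of a base-pair enrichment test
#'
#' Container for the enrichment quadruple: `A` bases under regions, `B` SNP
#' positions, `C` SNP positions under regions, `D` genomic positions tested.
#' The fold enrichment is `(C/A)/(B/D)` and one-sided hypergeometric tail
#' probabilities are reported for enrichment (`P(X >= C)`) and depletion
#' (`P(X <= C)`).
#'
#' @slot A,B,C,D Numeric counts as defined above.
#' @slot fold Fold enrichment `(C/A)/(B/D)`.
#' @slot pEnrich,pDeplete One-sided hypergeometric tail probabilities.
#' @slot regionLabel,snpLabel Labels of the tested region and SNP sets.
#' @slot defined `FALSE` when `A == 0` or `B == 0` (fold and p-values `NA`).
#' @export
setClass("EnrichmentResult",
  representation(
    A = "numeric", B = "numeric", C = "numeric", D = "numeric",
    fold = "numeric", pEnrich = "numeric", pDeplete = "numeric",
    regionLabel = "character", snpLabel = "character", defined = "logical"
  ),
  prototype(A = 0, B = 0, C = 0, D = 0, fold = NA_real_,
            pEnrich = NA_real_, pDeplete = NA_real_,
            regionLabel = "", snpLabel = "", defined = FALSE)
)

# new("EnrichmentResult", C = ...) would partially match new()'s Class
# argument; construct through initialize() instead.
.EnrichmentResult <- function(...) initialize(new("EnrichmentResult"), ...)

setValidity("EnrichmentResult", function(object) {
  msgs <- character()
  if (object@defined) {
    if (object@C > min(object@A, object@B))
      msgs <- c(msgs, "C cannot exceed min(A, B)")
    if (object@fold < 0) msgs <- c(msgs, "fold must be >= 0")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "GenomeModel", function(object) {
  n <- length(GenomeInfoDb::seqnames(object@seqinfo))
  cat(sprintf("GenomeModel: %d chromosomes, %d autosomal (%s bp autosomal)\n",
              n, length(object@autosomes),
              format(autosomalBp(object), big.mark = ",")))
})

setMethod("show", "PeakSet", function(object) {
  cat(sprintf("PeakSet '%s' (%s): %d intervals, %s bp covered\n",
              object@label, object@shapeClass, length(object),
              format(sum(width(reduce(granges(object)))), big.mark = ",")))
  if (length(object)) callNextMethod()
})

setMethod("show", "SnpRanges", function(object) {
  cat(sprintf("SnpRanges '%s': %d positions%s\n", object@label, length(object),
              if ("pvalue" %in% colnames(mcols(object))) " (with p-values)" else ""))
})

setMethod("show", "StateSegmentation", function(object) {
  cat(sprintf("StateSegmentation: %d segments, %d states\n",
              length(object), object@nStates))
})

setMethod("show", "EnrichmentResult", function(object) {
  if (!object@defined) {
    cat("EnrichmentResult: undefined (A or B is zero)\n")
    return(invisible(NULL))
  }
  cat(sprintf(
    "EnrichmentResult [%s in %s]\n  A=%.0f region bp, B=%.0f SNPs, C=%.0f overlapping, D=%.0f bp\n  fold=%.4g  p(enrich)=%.3g  p(deplete)=%.3g\n",
    object@snpLabel, object@regionLabel,
    object@A, object@B, object@C, object@D,
    object@fold, object@pEnrich, object@pDeplete))
})
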