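#' Read gene models from GTF or a minimal gene table
#'
#' GTF (Ensembl dialect; `gene` features, or the 5'-most transcript per
#' gene when no gene features are present) via `rtracklayer`, or a minimal
#' 5-column TSV (`gene_id`, `chrom`, `start`, `end`, `strand`; 1-based
#' inclusive coordinates). The TSS is always derived from the model, never
#' read: the start for `+` genes, the end for `-` genes.
#'
#' @param path Path to the file.
#' @param format `"gtf"` or `"tsv"` (guessed from the extension by default).
#' @param genome Optional [GenomeModel-class] attached as seqinfo.
#' @param stripChr Remove a leading `"chr"` from chromosome names.
#' @return A `GRanges` with a `gene_id` metadata column, one range per gene.
#' @export
readGeneModels <- function(path, format = c("auto", "gtf", "tsv"),
                           genome = NULL, stripChr = TRUE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE))
      "gtf" else "tsv"
  if (format == "gtf") {
    gtf <- rtracklayer::import(path, format = "gtf")
    genes <- gtf[gtf$type == "gene"]
    if (length(genes) == 0) {
      tx <- gtf[gtf$type %in% c("transcript", "mRNA")]
      if (length(tx) == 0) stop("no gene or transcript features in GTF")
      # 5'-most transcript start per gene on the gene's strand
      sp <- split(tx, tx$gene_id)
      genes <- unlist(range(sp, ignore.strand = FALSE))
      mcols(genes)$gene_id <- names(genes)
      names(genes) <- NULL
    }
    gr <- granges(genes)
    mcols(gr)$gene_id <- as.character(mcols(genes)$gene_id)
  } else {
    tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "start", "end", "strand")
    if (!all(need %in% names(tab)))
      stop("gene table must have columns: ", paste(need, collapse = ", "))
    gr <- GRanges(as.character(tab$chrom), IRanges(tab$start, tab$end),
                  strand = tab$strand, gene_id = as.character(tab$gene_id))
  }
  if (stripChr)
    gr <- GenomeInfoDb::renameSeqlevels(
      gr, setNames(sub("^chr", "", seqlevels(gr)), seqlevels(gr)))
  if (!all(strand(gr) %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  if (!is.null(genome)) {
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(genome@seqinfo)
    GenomeInfoDb::seqinfo(gr) <- genome@seqinfo
  }
  sort(gr)
}

#' Write gene models as the minimal TSV
#' @param genes `GRanges` with `gene_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGeneModels <- function(genes, path) {
  tab <- data.frame(gene_id = mcols(genes)$gene_id,
                    chrom = as.character(seqnames(genes)),
                    start = start(genes), end = end(genes),
                    strand = as.character(strand(genes)))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Transcription start sites of gene models
#'
#' @param genes `GRanges` of genes with strand.
#' @return Width-1 `GRanges` at the TSS of each gene (start for `+`,
#'   end for `-`), carrying `gene_id`.
#' @export
geneTss <- function(genes) {
  pos <- ifelse(strand(genes) == "+", start(genes), end(genes))
  GRanges(seqnames(genes), IRanges(as.integer(pos), width = 1L),
          gene_id = mcols(genes)$gene_id,
          seqinfo = GenomeInfoDb::seqinfo(genes))
}

.checkExpression <- function(counts, sampleSheet) {
  stopifnot(is.matrix(counts))
  if (any(counts < 0)) stop("expression counts must be non-negative")
  if (!all(colnames(counts) %in% sampleSheet$sample))
    stop("all count columns must appear in the sample sheet")
  sampleSheet[match(colnames(counts), sampleSheet$sample), , drop = FALSE]
}

#' Classify gene activity in a tissue from RNA-seq counts
#'
#' A gene is *active* in a tissue when every animal's count in that tissue
#' exceeds `activeMin` (default 200), *inactive* when every animal's count
#' is below `inactiveMax` (default 10), and *ambiguous* otherwise. Both
#' comparisons are strict, following the "over 200" / "less than 10" rule.
#'
#' @param counts Gene x sample matrix of (normalized) counts.
#' @param sampleSheet Data frame with `sample`, `animal`, `tissue`.
#' @param tissue Focal tissue.
#' @param activeMin,inactiveMax Activity thresholds.
#' @return A `data.frame` with `gene_id`, `tissue`, `status` (factor with
#'   levels active/inactive/ambiguous).
#' @export
classifyGeneActivity <- function(counts, sampleSheet, tissue,
                                 activeMin = 200, inactiveMax = 10) {
  meta <- .checkExpression(counts, sampleSheet)
  sel <- meta$tissue == tissue
  if (!any(sel)) stop(sprintf("tissue '%s' absent from the sample sheet", tissue))
  sub <- counts[, sel, drop = FALSE]
  active <- rowSums(sub > activeMin) == ncol(sub)
  inactive <- rowSums(sub < inactiveMax) == ncol(sub)
  status <- rep("ambiguous", nrow(counts))
  status[active] <- "active"
  status[inactive & !active] <- "inactive"
  data.frame(gene_id = rownames(counts), tissue = tissue,
             status = factor(status, levels = c("active", "inactive", "ambiguous")),
             stringsAsFactors = FALSE)
}

#' Tissue-specific active genes
#'
#' Genes active in the focal tissue (all animals over `activeMin`) whose
#' counts are below `inactiveMax` in every sample of every other tissue.
#'
#' @inheritParams classifyGeneActivity
#' @return Character vector of gene ids.
#' @export
tissueSpecificActive <- function(counts, sampleSheet, tissue,
                                 activeMin = 200, inactiveMax = 10) {
  meta <- .checkExpression(counts, sampleSheet)
  if (length(unique(meta$tissue)) < 2)
    stop("tissue specificity requires at least two tissues")
  act <- classifyGeneActivity(counts, sampleSheet, tissue,
                              activeMin, inactiveMax)
  other <- counts[, meta$tissue != tissue, drop = FALSE]
  lowElsewhere <- rowSums(other < inactiveMax) == ncol(other)
  rownames(counts)[act$status == "active" & lowElsewhere]
}

# Strand-aware upstream window [tss-from, tss-to] in gene-local coordinates,
# clipped to the chromosome. from > to >= 1; widths shrink only at edges.
.upstreamWindow <- function(genes, from, to) {
  tss <- geneTss(genes)
  plus <- as.logical(strand(genes) == "+")
  s <- ifelse(plus, start(tss) - from, start(tss) + to)
  e <- ifelse(plus, start(tss) - to, start(tss) + from)
  lim <- GenomeInfoDb::seqlengths(genes)[as.character(seqnames(genes))]
  s <- pmax(s, 1)
  e <- ifelse(is.na(lim), e, pmin(e, lim))
  keep <- e >= s
  GRanges(seqnames(genes)[keep], IRanges(s[keep], e[keep]),
          gene_id = mcols(genes)$gene_id[keep],
          seqinfo = GenomeInfoDb::seqinfo(genes))
}

#' Promoter regions of genes
#'
#' The promoter is the `promoterBp` (default 2000) bases immediately
#' upstream of the TSS, strand-aware and clipped at chromosome edges. The
#' TSS base itself is not included.
#'
#' @param genes `GRanges` of genes with strand and seqinfo.
#' @param promoterBp Promoter width in bp.
#' @param label Label for the returned set.
#' @return A [PeakSet-class] labelled by gene via the `gene_id` column.
#' @export
buildPromoters <- function(genes, promoterBp = 2000, label = "promoters") {
  gr <- .upstreamWindow(genes, from = promoterBp, to = 1L)
  new("PeakSet", sort(gr, ignore.strand = TRUE),
      shapeClass = "broad", label = label)
}

#' Proximal regions of genes
#'
#' The `proximalBp` (default 8000) bases immediately upstream of the
#' promoter's upstream edge, strand-aware and clipped. Promoter and
#' proximal region of a gene never overlap by construction.
#'
#' @inheritParams buildPromoters
#' @param proximalBp Proximal-region width in bp.
#' @return A [PeakSet-class].
#' @export
buildProximal <- function(genes, promoterBp = 2000, proximalBp = 8000,
                          label = "proximal") {
  gr <- .upstreamWindow(genes, from = promoterBp + proximalBp,
                        to = promoterBp + 1L)
  new("PeakSet", sort(gr, ignore.strand = TRUE),
      shapeClass = "broad", label = label)
}
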