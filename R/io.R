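#' Read a genome model from a chromosome-sizes file
#'
#' Two-column TSV (name, length in bp), the UCSC "chrom.sizes" layout.
#'
#' @param path Path to the file.
#' @param autosomes Autosome names; default: every chromosome whose
#'   (possibly "chr"-stripped) name is numeric, matching the convention that
#'   enrichment runs over chromosomes named "1".."29".
#' @param stripChr Remove a leading `"chr"` from chromosome names (default
#'   `TRUE`; references mix dialects).
#' @return A [GenomeModel-class].
#' @export
readGenome <- function(path, autosomes = NULL, stripChr = TRUE) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("name", "length"),
                    colClasses = c("character", "numeric"))
  if (stripChr) tab$name <- sub("^chr", "", tab$name)
  if (is.null(autosomes))
    autosomes <- tab$name[grepl("^[0-9]+$", tab$name)]
  if (length(autosomes) == 0) autosomes <- tab$name
  GenomeModel(tab$name, tab$length, autosomes = autosomes)
}

# Column layouts of the BED family. narrowPeak column 10 is the 0-based
# summit offset from the interval start (-1 = not called).
.bedCols <- list(
  bed        = c("chrom", "start", "end", "name", "score", "strand"),
  narrowPeak = c("chrom", "start", "end", "name", "score", "strand",
                 "signalValue", "pValue", "qValue", "peak"),
  broadPeak  = c("chrom", "start", "end", "name", "score", "strand",
                 "signalValue", "pValue", "qValue")
)

#' Read peak calls from a BED-family file
#'
#' Supports BED3-BED6, ENCODE narrowPeak (10 columns, summit in column 10)
#' and broadPeak (9 columns). Coordinates are converted from 0-based
#' half-open to the 1-based closed convention of `GRanges` on read.
#' Malformed lines raise an error naming the line number. Intervals on
#' chromosomes absent from `genome` either raise an error or are skipped
#' with a message, depending on `unknownChrom`.
#'
#' @param path Path to the file.
#' @param format One of `"bed"`, `"narrowPeak"`, `"broadPeak"`.
#' @param genome A [GenomeModel-class] used to validate coordinates.
#' @param label Label stored on the returned set.
#' @param unknownChrom `"error"` (default) or `"skip"`.
#' @param stripChr Remove a leading `"chr"` from chromosome names.
#' @return A [PeakSet-class]; `shapeClass` is `"narrow"` for narrowPeak and
#'   `"broad"` otherwise. The `summit` column is populated only for
#'   narrowPeak input with a non-negative column 10.
#' @export
readPeaks <- function(path, format = c("bed", "narrowPeak", "broadPeak"),
                      genome, label = basename(path),
                      unknownChrom = c("error", "skip"), stripChr = TRUE) {
  format <- match.arg(format)
  unknownChrom <- match.arg(unknownChrom)
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(PeakSet(GRanges(seqinfo = genome@seqinfo),
                   shapeClass = if (format == "narrowPeak") "narrow" else "broad",
                   label = label, genome = genome))
  }
  fields <- strsplit(lines, "\t")
  nmin <- if (format == "bed") 3L else length(.bedCols[[format]])
  nf <- lengths(fields)
  if (any(nf < nmin))
    stop(sprintf("malformed %s line %d: expected >= %d fields, got %d",
                 format, which(nf < nmin)[1], nmin, nf[which(nf < nmin)[1]]))
  chrom <- vapply(fields, `[[`, "", 1L)
  if (stripChr) chrom <- sub("^chr", "", chrom)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad))
    stop(sprintf("malformed %s line %d: non-numeric coordinates", format, bad[1]))
  bad <- which(end0 <= start0 | start0 < 0)
  if (length(bad))
    stop(sprintf("malformed %s line %d: need 0 <= start < end", format, bad[1]))

  known <- GenomeInfoDb::seqnames(genome@seqinfo)
  unk <- !(chrom %in% known)
  if (any(unk)) {
    if (unknownChrom == "error")
      stop(sprintf("line %d: unknown chromosome '%s'",
                   which(unk)[1], chrom[which(unk)[1]]))
    message(sprintf("readPeaks: skipped %d interval(s) on unknown chromosomes (%s)",
                    sum(unk), paste(unique(chrom[unk]), collapse = ", ")))
    fields <- fields[!unk]; chrom <- chrom[!unk]
    start0 <- start0[!unk]; end0 <- end0[!unk]
  }
  lim <- GenomeInfoDb::seqlengths(genome@seqinfo)[chrom]
  bad <- which(end0 > lim)
  if (length(bad))
    stop(sprintf("line %d: interval end %d beyond chromosome '%s' length %d",
                 bad[1], end0[bad[1]], chrom[bad[1]], lim[bad[1]]))

  gr <- GRanges(chrom, IRanges(start0 + 1L, end0))
  nmax <- length(.bedCols[[format]])
  getcol <- function(i, as = as.numeric) {
    if (all(lengths(fields) >= i))
      suppressWarnings(as(vapply(fields, `[[`, "", i))) else NULL
  }
  sc <- getcol(5L)
  if (!is.null(sc)) mcols(gr)$score <- sc
  if (format == "narrowPeak") {
    summit <- getcol(10L, as = as.integer)
    if (any(summit >= end0 - start0, na.rm = TRUE)) {
      bad <- which(summit >= end0 - start0)[1]
      stop(sprintf("line %d: summit offset outside the interval", bad))
    }
    summit[!is.na(summit) & summit < 0L] <- NA_integer_
    mcols(gr)$summit <- summit
  }
  PeakSet(gr, shapeClass = if (format == "narrowPeak") "narrow" else "broad",
          label = label, genome = genome)
}

#' Write a peak set as a BED-family file
#'
#' Coordinates are converted back to 0-based half-open. Reading the file
#' again reproduces the intervals exactly.
#'
#' @param peaks A [PeakSet-class].
#' @param path Output path.
#' @param format `"bed"`, `"narrowPeak"` or `"broadPeak"`.
#' @return `path`, invisibly.
#' @export
writePeaks <- function(peaks, path,
                       format = c("bed", "narrowPeak", "broadPeak")) {
  format <- match.arg(format)
  n <- length(peaks)
  sc <- if ("score" %in% colnames(mcols(peaks))) mcols(peaks)$score else rep(0, n)
  base <- data.frame(
    chrom = as.character(seqnames(peaks)),
    start = start(peaks) - 1L, end = end(peaks),
    name = if (!is.null(names(peaks)) && n) names(peaks) else
      sprintf("peak_%d", seq_len(max(n, 0))),
    score = sc, strand = rep(".", n)
  )
  if (format == "narrowPeak") {
    summit <- if ("summit" %in% colnames(mcols(peaks)))
      mcols(peaks)$summit else rep(NA_integer_, n)
    summit[is.na(summit)] <- -1L
    base <- cbind(base, signalValue = 0, pValue = -1, qValue = -1, peak = summit)
  } else if (format == "broadPeak") {
    base <- cbind(base, signalValue = 0, pValue = -1, qValue = -1)
  }
  write.table(base, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a SNP table
#'
#' TSV with columns `chrom`, `pos` (1-based) and optionally `pvalue`.
#' A header line is detected automatically.
#'
#' @param path Path to the file.
#' @param genome Optional [GenomeModel-class].
#' @param label Label for the set.
#' @param stripChr Remove a leading `"chr"` from chromosome names.
#' @return A [SnpRanges-class].
#' @export
readSnps <- function(path, genome = NULL, label = basename(path),
                     stripChr = TRUE) {
  first <- readLines(path, n = 1)
  hasHeader <- grepl("chrom|pos", tolower(first))
  tab <- read.table(path, sep = "\t", header = hasHeader,
                    stringsAsFactors = FALSE)
  if (!hasHeader)
    names(tab)[seq_len(min(3, ncol(tab)))] <-
      c("chrom", "pos", "pvalue")[seq_len(min(3, ncol(tab)))]
  if (stripChr) tab$chrom <- sub("^chr", "", as.character(tab$chrom))
  SnpRanges(tab$chrom, tab$pos,
         pvalue = if ("pvalue" %in% names(tab)) tab$pvalue else NULL,
         label = label, genome = genome)
}

#' Write a SNP set as a TSV
#' @param snps A [SnpRanges-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSnps <- function(snps, path) {
  tab <- data.frame(chrom = as.character(seqnames(snps)), pos = start(snps))
  if ("pvalue" %in% colnames(mcols(snps))) tab$pvalue <- mcols(snps)$pvalue
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a chromatin-state segmentation from BED4
#'
#' Column 4 carries the state label. Coordinates converted from 0-based.
#'
#' @param path Path to the file.
#' @param genome Optional [GenomeModel-class].
#' @param stripChr Remove a leading `"chr"` prefix.
#' @return A [StateSegmentation-class].
#' @export
readSegmentation <- function(path, genome = NULL, stripChr = TRUE) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)[, 1:4]
  names(tab) <- c("chrom", "start", "end", "state")
  if (stripChr) tab$chrom <- sub("^chr", "", tab$chrom)
  gr <- GRanges(tab$chrom, IRanges(tab$start + 1L, tab$end),
                state = as.character(tab$state))
  if (!is.null(genome)) {
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(genome@seqinfo)
    GenomeInfoDb::seqinfo(gr) <- genome@seqinfo
  }
  StateSegmentation(gr)
}

#' Write a segmentation as BED4
#' @param seg A [StateSegmentation-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSegmentation <- function(seg, path) {
  tab <- data.frame(chrom = as.character(seqnames(seg)),
                    start = start(seg) - 1L, end = end(seg),
                    state = mcols(seg)$state)
  write.table(tab, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a counts TSV (features x samples)
#'
#' First column = feature id, header row = sample names.
#'
#' @param path Path to the file.
#' @return Integer matrix with feature rownames.
#' @export
readCountsTsv <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, row.names = 1,
                    check.names = FALSE)
  as.matrix(tab)
}

#' Write a counts matrix as TSV
#' @param mat Matrix with rownames (features) and colnames (samples).
#' @param path Output path.
#' @param idCol Name of the leading id column.
#' @return `path`, invisibly.
#' @export
writeCountsTsv <- function(mat, path, idCol = "feature") {
  tab <- data.frame(id = rownames(mat), mat, check.names = FALSE)
  names(tab)[1] <- idCol
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' TSV with columns `sample`, `animal`, `tissue` and optionally `libSize`
#' (the full library size: total fragments sequenced for the sample).
#'
#' @param path Path to the file.
#' @return A `data.frame`.
#' @export
readSampleSheet <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("sample", "animal", "tissue")
  if (!all(need %in% names(tab)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$sample)) stop("duplicate sample names in sample sheet")
  tab
}

#' Read a genotype dosage matrix
#'
#' TSV whose rows are SNPs. The first two columns are `chrom` and `pos`;
#' remaining columns are per-individual dosages in \{0, 1, 2\} with `NA`
#' allowed.
#'
#' @param path Path to the file.
#' @param stripChr Remove a leading `"chr"` prefix.
#' @return A list with `snps` (a [SnpRanges-class]) and `dosages` (SNP x
#'   individual integer matrix, rownames `chrom:pos`).
#' @export
readGenotypes <- function(path, stripChr = TRUE) {
  tab <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  chrom <- as.character(tab[[1]])
  if (stripChr) chrom <- sub("^chr", "", chrom)
  pos <- as.integer(tab[[2]])
  dos <- as.matrix(tab[, -(1:2), drop = FALSE])
  storage.mode(dos) <- "integer"
  if (any(!is.na(dos) & !(dos %in% 0:2)))
    stop("dosages must be 0, 1, 2 or NA")
  rownames(dos) <- paste0(chrom, ":", pos)
  o <- order(chrom, pos)
  list(snps = SnpRanges(chrom[o], pos[o]), dosages = dos[o, , drop = FALSE])
}
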