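#' Configuration for the synthetic-data generators
#'
#' Defaults emulate the study design the pipeline targets: a multi-tissue,
#' multi-animal histone-mark experiment on a mammalian genome. The genome
#' is scaled to 10 chromosomes of 5 Mb — large enough that 100-kb
#' distance-to-TSS bands up to 1 Mb are populated, small enough for fast
#' runs. Narrow peaks average ~500 bp and broad peaks ~1100 bp, matching
#' typical point-source (H3K4Me3/H3K27ac/CTCF) and domain
#' (H3K4Me1/H3K27Me3) mark widths; six tissues with three animals each
#' mirror the 6-tissue, 2-3-cow design. Counts are negative binomial
#' (dispersion 0.1) to carry the overdispersion a differential-binding
#' test must survive.
#'
#' @param seed Integer seed; every generator is a pure function of the
#'   config including this seed.
#' @param nChroms,chromLengthBp Genome shape (all chromosomes autosomal).
#' @param nGenes Number of genes.
#' @param geneRegionFraction Fraction of each chromosome (from its start)
#'   in which genes are placed; the gene-free remainder populates distant
#'   distance-to-TSS bands.
#' @param nTissues,nAnimals Sample grid (samples = tissues x animals).
#' @param nPeaks Latent consensus-skeleton peaks.
#' @param peakShape `"narrow"` or `"broad"`.
#' @param narrowWidthBp,broadWidthBp Mean peak widths.
#' @param dropout Per-sample probability that a skeleton peak is missed.
#' @param jitterBp Maximum per-sample jitter of each peak edge.
#' @param bgPeakRate Extra per-sample background peaks, as a fraction of
#'   `nPeaks`.
#' @param dispersion Negative-binomial dispersion of peak counts.
#' @param nDbPeaks,dbFold,dbTissue Planted differential-binding effects:
#'   `nDbPeaks` peaks get `dbFold`-fold higher binding in `dbTissue`
#'   (index into the tissue list).
#' @param nCorrelatedPairs,targetR,corrSigma,corrDispersion Planted
#'   peak-gene correlations: latent-factor sharing at correlation
#'   `targetR`, log-scale signal sd `corrSigma`, and a reduced dispersion
#'   for those features so count noise attenuates the correlation only
#'   mildly.
#' @param nActivePerTissue,nInactive,nTissueSpecific Planted activity
#'   labels satisfying the all-animals `> 200` / `< 10` rules.
#' @param snpRho Planted SNP enrichment: in-peak density relative to the
#'   genome-wide mean density, so the enrichment fold estimates `snpRho`.
#' @param nSnps SNPs per simulated set.
#' @param bandRho Optional per-band `rho` vector for band-specific planting.
#' @param nIndividuals,ldBlockSize,ldBlockR2 Genotype simulation: block
#'   size in SNPs and target within-block dosage `r^2`.
#' @param nStates Chromatin states in the simulated segmentation.
#' @return A validated list of class `SimConfig`.
#' @export
simConfig <- function(seed = 1L,
                      nChroms = 10L, chromLengthBp = 5e6, nGenes = 400L,
                      geneRegionFraction = 0.6,
                      nTissues = 6L, nAnimals = 3L,
                      nPeaks = 2000L, peakShape = "narrow",
                      narrowWidthBp = 500, broadWidthBp = 1100,
                      dropout = 0.2, jitterBp = 50, bgPeakRate = 0.1,
                      dispersion = 0.1,
                      nDbPeaks = 200L, dbFold = 4, dbTissue = 1L,
                      nCorrelatedPairs = 100L, targetR = 0.9,
                      corrSigma = 1.0, corrDispersion = 0.02,
                      nActivePerTissue = 30L, nInactive = 30L,
                      nTissueSpecific = 10L,
                      snpRho = 3, nSnps = 5000L, bandRho = NULL,
                      nIndividuals = 100L, ldBlockSize = 20L, ldBlockR2 = 0.9,
                      nStates = 7L) {
  cfg <- as.list(environment())
  stopifnot(cfg$nChroms > 0, cfg$chromLengthBp > 0, cfg$nGenes >= 0,
            cfg$nTissues > 0, cfg$nAnimals > 0, cfg$nPeaks > 0,
            cfg$dropout >= 0, cfg$dropout <= 1,
            cfg$dispersion >= 0, cfg$dbFold > 0, cfg$snpRho > 0,
            abs(cfg$targetR) < 1, cfg$ldBlockR2 > 0, cfg$ldBlockR2 <= 1,
            cfg$peakShape %in% c("narrow", "broad"))
  class(cfg) <- "SimConfig"
  cfg
}

#' @export
print.SimConfig <- function(x, ...) {
  cat(sprintf(
    "SimConfig: seed %d; %d x %.2g-Mb chromosomes, %d genes; %d tissues x %d animals; %d %s peaks\n",
    x$seed, x$nChroms, x$chromLengthBp / 1e6, x$nGenes,
    x$nTissues, x$nAnimals, x$nPeaks, x$peakShape))
  invisible(x)
}

.simSeed <- function(config, stage) {
  set.seed((config$seed * 101L + stage) %% .Machine$integer.max)
}

#' Simulate a genome model and gene annotation
#'
#' Genes are placed without overlap (one per equal-width slot within the
#' gene-bearing portion of each chromosome) with random strand; the TSS
#' list derives from the models.
#'
#' @param config A [simConfig()].
#' @return List with `genome` (a [GenomeModel-class]) and `genes`
#'   (`GRanges` with `gene_id`).
#' @export
simulateAnnotation <- function(config) {
  .simSeed(config, 1L)
  chroms <- as.character(seq_len(config$nChroms))
  genome <- GenomeModel(chroms, rep(config$chromLengthBp, config$nChroms))
  if (config$nGenes == 0) {
    genes <- GRanges(seqinfo = genome@seqinfo)
    mcols(genes)$gene_id <- character(0)
    return(list(genome = genome, genes = genes))
  }
  perChrom <- rep(config$nGenes %/% config$nChroms, config$nChroms)
  extra <- config$nGenes %% config$nChroms
  if (extra) perChrom[seq_len(extra)] <- perChrom[seq_len(extra)] + 1L
  region <- floor(config$chromLengthBp * config$geneRegionFraction)
  out <- list()
  gid <- 0L
  for (i in seq_len(config$nChroms)) {
    n <- perChrom[i]
    if (n == 0) next
    slot <- region %/% n
    if (slot < 200)
      stop("genes do not fit: increase chromLengthBp or reduce nGenes")
    maxW <- max(min(slot %/% 2, 20000L), 100L)
    w <- pmax(100L, as.integer(runif(n, 0.2, 1) * maxW))
    offset <- vapply(seq_len(n), function(k)
      as.integer(runif(1, 0, slot - w[k])), 0L)
    s <- (seq_len(n) - 1L) * slot + offset + 1L
    out[[i]] <- GRanges(chroms[i], IRanges(s, width = w),
                        strand = sample(c("+", "-"), n, replace = TRUE),
                        gene_id = sprintf("gene_%04d", gid + seq_len(n)),
                        seqinfo = genome@seqinfo)
    gid <- gid + n
  }
  list(genome = genome, genes = sort(do.call(c, out), ignore.strand = TRUE))
}

# Sample n distinct positions uniformly over a set of disjoint ranges.
.samplePositions <- function(gr, n) {
  w <- as.numeric(width(gr))
  total <- sum(w)
  if (n > total) stop("not enough bases to place distinct positions")
  off <- sample.int(total, n)
  cum <- cumsum(w)
  idx <- findInterval(off - 1, c(0, cum), rightmost.closed = FALSE)
  pos <- start(gr)[idx] + (off - c(0, cum)[idx] - 1)
  GRanges(seqnames(gr)[idx], IRanges(pos, width = 1L),
          seqinfo = GenomeInfoDb::seqinfo(gr))
}

#' Simulate replicated peak calls
#'
#' A latent consensus skeleton of non-overlapping peaks is drawn once;
#' each replicate sample observes each skeleton peak with probability
#' `1 - dropout`, with edges jittered by up to `jitterBp`, plus
#' `bgPeakRate * nPeaks` background peaks of its own. Narrow peaks carry
#' summits. With zero dropout and jitter, every sample reproduces the
#' skeleton, so the min-support-2 consensus equals the skeleton.
#'
#' @param config A [simConfig()].
#' @param genome A [GenomeModel-class].
#' @param nSamples Number of replicate samples (default tissues x animals).
#' @return List with `skeleton` (a [PeakSet-class]) and `samples` (list of
#'   [PeakSet-class]).
#' @export
simulatePeaks <- function(config, genome,
                          nSamples = config$nTissues * config$nAnimals) {
  .simSeed(config, 2L)
  meanW <- if (config$peakShape == "narrow") config$narrowWidthBp else
    config$broadWidthBp
  chroms <- genome@autosomes
  L <- GenomeInfoDb::seqlengths(genome@seqinfo)[chroms]
  n <- config$nPeaks
  perChrom <- as.integer(round(n * L / sum(as.numeric(L))))
  perChrom[1] <- n - sum(perChrom[-1])
  sk <- list()
  for (i in seq_along(chroms)) {
    m <- perChrom[i]
    if (m <= 0) next
    slot <- L[i] %/% m
    w <- pmax(50L, as.integer(rnorm(m, meanW, meanW / 5)))
    w <- pmin(w, as.integer(slot - 2L))
    off <- vapply(seq_len(m), function(k)
      as.integer(runif(1, 0, slot - w[k] - 1)), 0L)
    s <- (seq_len(m) - 1L) * slot + off + 1L
    sk[[i]] <- GRanges(chroms[i], IRanges(s, width = w),
                       seqinfo = genome@seqinfo)
  }
  skGr <- sort(do.call(c, sk), ignore.strand = TRUE)
  if (config$peakShape == "narrow")
    mcols(skGr)$summit <- as.integer(floor(width(skGr) *
                                             runif(length(skGr), 0.3, 0.7)))
  skeleton <- PeakSet(skGr, shapeClass = config$peakShape,
                      label = "skeleton", genome = genome)

  lim <- GenomeInfoDb::seqlengths(genome@seqinfo)
  samples <- lapply(seq_len(nSamples), function(s) {
    keep <- runif(length(skGr)) >= config$dropout
    gr <- skGr[keep]
    if (length(gr) && config$jitterBp > 0) {
      js <- as.integer(round(runif(length(gr), -config$jitterBp, config$jitterBp)))
      je <- as.integer(round(runif(length(gr), -config$jitterBp, config$jitterBp)))
      ns <- pmax(start(gr) + js, 1L)
      ne <- pmin(end(gr) + je, lim[as.character(seqnames(gr))])
      bad <- ne <= ns
      ns[bad] <- start(gr)[bad]; ne[bad] <- end(gr)[bad]
      gr <- GRanges(seqnames(gr), IRanges(ns, ne), seqinfo = genome@seqinfo)
      if (config$peakShape == "narrow")
        mcols(gr)$summit <- as.integer(floor(width(gr) *
                                               runif(length(gr), 0.3, 0.7)))
    }
    nBg <- as.integer(round(config$nPeaks * config$bgPeakRate))
    if (nBg > 0) {
      bgPos <- .samplePositions(.genomeSpace(genome, TRUE), nBg)
      bw <- pmax(50L, as.integer(rnorm(nBg, meanW, meanW / 5)))
      bg <- GRanges(seqnames(bgPos),
                    IRanges(start(bgPos),
                            width = pmin(bw, lim[as.character(seqnames(bgPos))] -
                                           start(bgPos) + 1L)),
                    seqinfo = genome@seqinfo)
      if (config$peakShape == "narrow")
        mcols(bg)$summit <- as.integer(floor(width(bg) *
                                               runif(nBg, 0.3, 0.7)))
      gr <- c(gr, bg)
    }
    PeakSet(gr, shapeClass = config$peakShape,
            label = sprintf("sample_%02d", s), genome = genome)
  })
  list(skeleton = skeleton, samples = samples)
}

#' Simulate peak counts and gene expression with planted structure
#'
#' Negative-binomial peak counts over a tissues x animals sample grid with
#' per-sample library sizes; a labelled subset of peaks carries a
#' `dbFold`-fold binding increase in the focal tissue. Gene expression is
#' planted so that designated genes satisfy the all-animals `> 200`
#' (active) or `< 10` (inactive) rules in designated tissues, including
#' tissue-specific genes (active in one tissue, `< 10` everywhere else).
#' Designated (peak, gene) pairs share a latent per-sample factor so their
#' signals correlate at `targetR` before count noise.
#'
#' @param config A [simConfig()].
#' @param consensus A [PeakSet-class] whose rows the counts describe.
#' @param genes `GRanges` of gene models.
#' @param pairs Optional data frame of candidate (peak, gene) pairs (as
#'   from [pairPeaksGenes()]) from which correlated pairs are planted;
#'   `NULL` plants correlations on arbitrary peak-gene index pairs.
#' @return List: `peakCounts`, `geneCounts` (matrices), `sampleSheet`
#'   (with `libSize`), and `groundTruth` (planted DB peak ids and tissue,
#'   correlated pairs with target r, active/inactive/tissue-specific gene
#'   ids per tissue).
#' @export
simulateCounts <- function(config, consensus, genes, pairs = NULL) {
  .simSeed(config, 3L)
  nP <- length(consensus)
  peakIds <- if (!is.null(names(consensus))) names(consensus) else
    sprintf("peak_%d", seq_len(nP))
  geneIds <- mcols(genes)$gene_id
  nG <- length(geneIds)
  tissues <- sprintf("tissue%02d", seq_len(config$nTissues))
  animals <- sprintf("animal%02d", seq_len(config$nAnimals))
  sheet <- expand.grid(animal = animals, tissue = tissues,
                       stringsAsFactors = FALSE)
  sheet$sample <- paste(sheet$tissue, sheet$animal, sep = "_")
  nS <- nrow(sheet)
  sheet$libSize <- round(runif(nS, 0.7, 1.4) * 2e6)

  rnb <- function(n, mu, disp) {
    if (disp <= 0) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / disp)
  }

  # --- planted peak-gene correlated pairs ---------------------------------
  nCorr <- min(config$nCorrelatedPairs, nP, nG)
  if (!is.null(pairs) && nrow(pairs) > 0) {
    cand <- pairs[!duplicated(pairs$peak_id) & !duplicated(pairs$gene_id), ,
                  drop = FALSE]
    cand <- head(cand, nCorr)
    corrPeakIdx <- match(cand$peak_id, peakIds)
    corrGeneIdx <- match(cand$gene_id, geneIds)
    nCorr <- nrow(cand)
  } else {
    corrPeakIdx <- seq_len(nCorr)
    corrGeneIdx <- seq_len(nCorr)
  }
  r <- config$targetR
  z <- matrix(rnorm(nCorr * nS), nCorr, nS)
  e1 <- matrix(rnorm(nCorr * nS), nCorr, nS)
  e2 <- matrix(rnorm(nCorr * nS), nCorr, nS)
  sgn <- sign(r)
  peakSig <- sqrt(abs(r)) * z + sqrt(1 - abs(r)) * e1
  geneSig <- sgn * sqrt(abs(r)) * z + sqrt(1 - abs(r)) * e2

  # --- peak counts --------------------------------------------------------
  baseMu <- exp(rnorm(nP, log(150), 0.4))
  dbIdx <- integer(0)
  dbTissueName <- tissues[config$dbTissue]
  if (config$nDbPeaks > 0) {
    avail <- setdiff(seq_len(nP), corrPeakIdx)
    dbIdx <- head(avail, min(config$nDbPeaks, length(avail)))
  }
  libFac <- sheet$libSize / mean(sheet$libSize)
  peakCounts <- matrix(0L, nP, nS, dimnames = list(peakIds, sheet$sample))
  inFocal <- sheet$tissue == dbTissueName
  for (s in seq_len(nS)) {
    mu <- baseMu * libFac[s]
    if (length(dbIdx) && inFocal[s]) mu[dbIdx] <- mu[dbIdx] * config$dbFold
    disp <- rep(config$dispersion, nP)
    if (nCorr > 0) {
      mu[corrPeakIdx] <- exp(log(500) + config$corrSigma * peakSig[, s]) *
        libFac[s]
      disp[corrPeakIdx] <- config$corrDispersion
    }
    cnt <- numeric(nP)
    for (d in unique(disp)) {
      ii <- disp == d
      cnt[ii] <- rnb(sum(ii), mu[ii], d)
    }
    peakCounts[, s] <- as.integer(cnt)
  }

  # --- gene expression ----------------------------------------------------
  geneCounts <- matrix(0L, nG, nS, dimnames = list(geneIds, sheet$sample))
  # ambient expression: moderate, clear of both thresholds on average
  geneCounts[, ] <- as.integer(rnb(nG * nS, 60, 0.3))
  usable <- setdiff(seq_len(nG), corrGeneIdx)
  take <- function(n) {
    if (length(usable) < n)
      stop("config plants more genes than available: increase nGenes")
    got <- head(usable, n); usable <<- setdiff(usable, got); got
  }
  activeGenes <- list(); tsGenes <- list()
  plantHigh <- function(idx, cols) {
    geneCounts[idx, cols] <<- matrix(
      201L + as.integer(rnb(length(idx) * length(cols), 600, 0.1)),
      length(idx), length(cols))
  }
  plantLow <- function(idx, cols) {
    geneCounts[idx, cols] <<- matrix(
      pmin(as.integer(rpois(length(idx) * length(cols), 1)), 9L),
      length(idx), length(cols))
  }
  for (tt in tissues) {
    cols <- which(sheet$tissue == tt)
    aIdx <- take(config$nActivePerTissue)
    plantHigh(aIdx, cols)
    activeGenes[[tt]] <- geneIds[aIdx]
    sIdx <- take(config$nTissueSpecific)
    plantHigh(sIdx, cols)
    plantLow(sIdx, which(sheet$tissue != tt))
    tsGenes[[tt]] <- geneIds[sIdx]
  }
  iIdx <- take(config$nInactive)
  plantLow(iIdx, seq_len(nS))
  # correlated genes: latent-factor driven counts, low dispersion
  if (nCorr > 0) {
    for (s in seq_len(nS)) {
      geneCounts[corrGeneIdx, s] <- as.integer(
        rnb(nCorr, exp(log(500) + config$corrSigma * geneSig[, s]),
            config$corrDispersion))
    }
  }

  list(
    peakCounts = peakCounts,
    geneCounts = geneCounts,
    sampleSheet = sheet[, c("sample", "animal", "tissue", "libSize")],
    groundTruth = list(
      dbPeaks = peakIds[dbIdx], dbTissue = dbTissueName,
      correlatedPairs = data.frame(peak_id = peakIds[corrPeakIdx],
                                   gene_id = geneIds[corrGeneIdx],
                                   target_r = rep(r, length(corrPeakIdx)),
                                   stringsAsFactors = FALSE),
      activeGenes = activeGenes,
      tissueSpecificGenes = tsGenes,
      inactiveGenes = geneIds[iIdx]
    )
  )
}

#' Simulate a SNP set with planted enrichment in regions
#'
#' Each SNP falls inside the region bases with probability
#' `rho * A / D` (in-region density relative to the genome-wide mean
#' density), otherwise uniformly outside, so the enrichment fold
#' `(C/A)/(B/D)` is a consistent estimator of `rho`. With `bandRho`, SNPs
#' are allocated evenly across distance-to-TSS bands and the planting is
#' band-specific (requires `genes`).
#'
#' @param config A [simConfig()] (fields `snpRho`, `nSnps`, `bandRho`).
#' @param genome A [GenomeModel-class].
#' @param regions A [PeakSet-class] of target regions.
#' @param genes Gene models, required when `bandRho` is set.
#' @param bands Distance bands for `bandRho` (default
#'   [defaultDistanceBands()]).
#' @param withPvalues Attach uniform p-values.
#' @param label Label for the set.
#' @return List with `snps` (a [SnpRanges-class]) and `groundTruth`
#'   (`inRegion` logical, and band index under `bandRho`).
#' @export
simulateSnps <- function(config, genome, regions, genes = NULL,
                         bands = defaultDistanceBands(),
                         withPvalues = FALSE, label = "simulated_snps") {
  .simSeed(config, 4L)
  space <- .genomeSpace(genome, TRUE)
  D <- autosomalBp(genome)
  reg <- GenomicRanges::intersect(reduce(.asGRanges(regions)), space,
                                  ignore.strand = TRUE)

  if (is.null(config$bandRho)) {
    A <- sum(as.numeric(width(reg)))
    pIn <- config$snpRho * A / D
    if (pIn > 1) stop("snpRho * A / D exceeds 1: reduce rho or region size")
    nIn <- rbinom(1, config$nSnps, pIn)
    outSpace <- GenomicRanges::setdiff(space, reg, ignore.strand = TRUE)
    posIn <- if (nIn > 0) .samplePositions(reg, nIn) else NULL
    posOut <- if (config$nSnps - nIn > 0)
      .samplePositions(outSpace, config$nSnps - nIn) else NULL
    gr <- if (is.null(posIn)) posOut else
      if (is.null(posOut)) posIn else c(posIn, posOut)
    inRegion <- rep(c(TRUE, FALSE), c(nIn, config$nSnps - nIn))
    bandIdx <- rep(NA_integer_, config$nSnps)
  } else {
    stopifnot(!is.null(genes), length(config$bandRho) == nrow(bands))
    tss <- geneTss(genes)
    anchors <- anchorRanges(regions)
    peakDist <- suppressWarnings(distanceToNearestTss(anchors, tss))
    perBand <- config$nSnps %/% nrow(bands)
    grs <- list(); inRegion <- logical(0); bandIdx <- integer(0)
    for (i in seq_len(nrow(bands))) {
      lo <- bands$lower[i]; hi <- bands$upper[i]
      inHi <- GenomicRanges::intersect(
        reduce(trim(suppressWarnings(GRanges(
          seqnames(tss), IRanges(pmax(start(tss) - (hi - 1), 1L),
                                 start(tss) + (hi - 1)),
          seqinfo = GenomeInfoDb::seqinfo(tss))))), space,
        ignore.strand = TRUE)
      bandSpace <- if (lo == 0) inHi else GenomicRanges::setdiff(
        inHi, GenomicRanges::intersect(
          reduce(trim(suppressWarnings(GRanges(
            seqnames(tss), IRanges(pmax(start(tss) - (lo - 1), 1L),
                                   start(tss) + (lo - 1)),
            seqinfo = GenomeInfoDb::seqinfo(tss))))), space,
          ignore.strand = TRUE), ignore.strand = TRUE)
      Db <- sum(as.numeric(width(bandSpace)))
      if (Db == 0) next
      pk <- which(!is.na(peakDist) & peakDist >= lo & peakDist < hi)
      selReg <- reduce(granges(regions)[mcols(anchors)$peakIdx[pk]])
      Ab <- sum(as.numeric(width(GenomicRanges::intersect(
        selReg, space, ignore.strand = TRUE))))
      inBand <- GenomicRanges::intersect(bandSpace, selReg,
                                         ignore.strand = TRUE)
      outBand <- GenomicRanges::setdiff(bandSpace, selReg,
                                        ignore.strand = TRUE)
      pIn <- min(config$bandRho[i] * Ab / Db, 1)
      if (sum(width(inBand)) == 0) pIn <- 0
      nIn <- rbinom(1, perBand, pIn)
      if (nIn > 0) {
        grs[[length(grs) + 1]] <- .samplePositions(inBand, nIn)
        inRegion <- c(inRegion, rep(TRUE, nIn))
        bandIdx <- c(bandIdx, rep(i, nIn))
      }
      if (perBand - nIn > 0) {
        grs[[length(grs) + 1]] <- .samplePositions(outBand, perBand - nIn)
        inRegion <- c(inRegion, rep(FALSE, perBand - nIn))
        bandIdx <- c(bandIdx, rep(i, perBand - nIn))
      }
    }
    gr <- do.call(c, grs)
  }
  snps <- SnpRanges(as.character(seqnames(gr)), start(gr),
                 pvalue = if (withPvalues) runif(length(gr)) else NULL,
                 label = label, genome = genome)
  list(snps = snps,
       groundTruth = list(inRegion = inRegion, band = bandIdx))
}

#' Simulate block-LD genotype dosages
#'
#' SNPs are grouped into consecutive blocks of `ldBlockSize` per
#' chromosome. Within a block, every SNP is a noisy copy of the same pair
#' of latent haplotypes: each allele is flipped with the probability that
#' yields an expected pairwise dosage `r^2` of `ldBlockR2`. Blocks are
#' independent of each other.
#'
#' @param config A [simConfig()].
#' @param snps A [SnpRanges-class] (order defines blocks).
#' @return List with `dosages` (SNP x individual integer matrix) and
#'   `blocks` (block index per SNP).
#' @export
simulateGenotypes <- function(config, snps) {
  .simSeed(config, 5L)
  n <- length(snps)
  nInd <- config$nIndividuals
  # corr(noisy copies) = (1-2*eps)^2 per haplotype; dosage r^2 = corr^2
  eps <- (1 - config$ldBlockR2^(1 / 4)) / 2
  chrom <- as.character(seqnames(snps))
  blocks <- integer(n)
  b <- 0L
  for (chr in unique(chrom)) {
    idx <- which(chrom == chr)
    nb <- ceiling(length(idx) / config$ldBlockSize)
    blocks[idx] <- b + rep(seq_len(nb), each = config$ldBlockSize)[seq_along(idx)]
    b <- b + nb
  }
  dos <- matrix(0L, n, nInd,
                dimnames = list(paste0(chrom, ":", start(snps)),
                                sprintf("ind%03d", seq_len(nInd))))
  for (bk in unique(blocks)) {
    idx <- which(blocks == bk)
    p <- runif(1, 0.2, 0.8)
    h1 <- rbinom(nInd, 1, p)
    h2 <- rbinom(nInd, 1, p)
    for (i in idx) {
      f1 <- rbinom(nInd, 1, eps)
      f2 <- rbinom(nInd, 1, eps)
      dos[i, ] <- as.integer(abs(h1 - f1) + abs(h2 - f2))
    }
  }
  list(dosages = dos, blocks = blocks)
}

#' Simulate a chromatin-state segmentation
#'
#' Tiles the genome into bins and assigns one of `nStates` state labels;
#' most of the genome is the quiescent "no_signal" state, and bins
#' overlapping the promoters of supplied active genes are preferentially
#' assigned the "active_promoter" state, so overlap enrichment of that
#' state in active promoters exceeds 1. Adjacent same-state bins are
#' merged; the segmentation tiles the genome completely.
#'
#' @param config A [simConfig()].
#' @param genome A [GenomeModel-class].
#' @param genes Gene models.
#' @param activeGeneIds Gene ids treated as active (their promoters seed
#'   the "active_promoter" state); default none.
#' @param binBp Bin width.
#' @return A [StateSegmentation-class].
#' @export
simulateSegmentation <- function(config, genome, genes,
                                 activeGeneIds = character(0), binBp = 1000) {
  .simSeed(config, 6L)
  stateNames <- c("inactive_promoter", "repressed", "no_signal",
                  "hyperChIPable", "active_enhancer", "permissive",
                  "active_promoter")[seq_len(min(config$nStates, 7L))]
  if (config$nStates > 7)
    stateNames <- c(stateNames, sprintf("state_%d", 8:config$nStates))
  base <- rep(0.4 / (length(stateNames) - 1), length(stateNames))
  base[stateNames == "no_signal"] <- 0.6
  base <- base / sum(base)
  tiles <- GenomicRanges::tileGenome(
    GenomeInfoDb::seqlengths(genome@seqinfo), tilewidth = binBp,
    cut.last.tile.in.chrom = TRUE)
  st <- sample(stateNames, length(tiles), replace = TRUE, prob = base)
  if (length(activeGeneIds) && "active_promoter" %in% stateNames) {
    act <- genes[mcols(genes)$gene_id %in% activeGeneIds]
    if (length(act)) {
      prom <- buildPromoters(act)
      hit <- overlapsAny(tiles, granges(prom), ignore.strand = TRUE)
      flip <- hit & runif(length(tiles)) < 0.8
      st[flip] <- "active_promoter"
    }
  }
  # merge adjacent same-state bins per chromosome
  mcols(tiles)$state <- st
  merged <- list()
  for (chr in seqlevels(tiles)) {
    tt <- tiles[seqnames(tiles) == chr]
    if (length(tt) == 0) next
    rl <- rle(mcols(tt)$state)
    ends <- cumsum(rl$lengths)
    starts <- c(1L, head(ends, -1) + 1L)
    merged[[chr]] <- GRanges(chr,
                             IRanges(start(tt)[starts], end(tt)[ends]),
                             state = rl$values,
                             seqinfo = GenomeInfoDb::seqinfo(tiles))
  }
  StateSegmentation(do.call(c, unname(merged)),
                    nStates = length(stateNames))
}
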