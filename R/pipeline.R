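#' Pipeline configuration
#'
#' Bundles the synthetic-data configuration with every analysis threshold.
#' Defaults are the values the pipeline is built around: activity calls at
#' counts over 200 (all animals) and under 10, 2-kb promoters with 8-kb
#' proximal regions, 100-kb peak-gene pairing, differential binding at
#' p < 0.05 and 2-fold, distance bands of 100 kb up to 1 Mb with at least
#' 10 SNPs per band, and LD pruning at r^2 < 0.5 in 1-Mb windows with a
#' 50-SNP step.
#'
#' @param sim A [simConfig()].
#' @param activeMin,inactiveMax Gene-activity thresholds.
#' @param promoterBp,proximalBp Region construction widths.
#' @param pairingWindow Peak-gene pairing window in bp.
#' @param alpha Significance threshold (DB test and correlation screen).
#' @param minFold DB fold threshold (natural scale).
#' @param minSupport Consensus support threshold.
#' @param bands Distance bands data frame (`lower`/`upper`).
#' @param minSnps Minimum SNPs per band.
#' @param r2Max,windowBp,stepSnps LD-pruning parameters.
#' @return A validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(sim = simConfig(),
                           activeMin = 200, inactiveMax = 10,
                           promoterBp = 2000, proximalBp = 8000,
                           pairingWindow = 100000,
                           alpha = 0.05, minFold = 2, minSupport = 2,
                           bands = defaultDistanceBands(),
                           minSnps = 10,
                           r2Max = 0.5, windowBp = 1e6, stepSnps = 50) {
  cfg <- as.list(environment())
  stopifnot(activeMin > 0, inactiveMax > 0, promoterBp > 0, proximalBp > 0,
            pairingWindow > 0, alpha > 0, alpha < 1, minFold > 0,
            minSupport >= 1, minSnps >= 0, r2Max > 0, r2Max <= 1,
            windowBp > 0, stepSnps >= 1)
  if (any(bands$upper <= bands$lower) ||
      (nrow(bands) > 1 && any(bands$lower[-1] < bands$upper[-nrow(bands)])))
    stop("bands must be ordered, non-overlapping, with upper > lower")
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys override [pipelineConfig()] arguments; keys under `sim`
#' override [simConfig()] arguments. Validation runs before any
#' computation.
#'
#' @param path Path to a YAML file.
#' @return A `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  simArgs <- y$sim %||% list()
  y$sim <- NULL
  if (!is.null(y$bands)) y$bands <- as.data.frame(y$bands)
  do.call(pipelineConfig, c(list(sim = do.call(simConfig, simArgs)), y))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stageOrder <- c("simulate", "consensus", "annotate", "diffbind",
                 "correlate", "enrich", "prune")

.needFile <- function(path, producer) {
  if (!file.exists(path))
    stop(sprintf("missing input '%s': run the '%s' stage first",
                 basename(path), producer))
  path
}

#' Run the analysis pipeline
#'
#' Orchestrates the stages `simulate` (genome, genes, replicate peak
#' calls), `consensus`, `annotate` (counts, activity calls, promoter and
#' proximal regions), `diffbind`, `correlate`, `enrich` (SNP sets, peak
#' and band enrichment, chromatin-state overlap) and `prune` (genotypes,
#' LD pruning, enrichment of the pruned set). `"all"` runs everything in
#' order. Outputs are plain TSV/BED files under `outDir` plus a
#' `manifest.json` recording the package version, seed, parameters and an
#' md5 checksum per output file; rerunning with the same configuration
#' reproduces every file byte for byte.
#'
#' @param outDir Output directory (created if needed).
#' @param config A [pipelineConfig()] or path to a YAML file.
#' @param stages Character vector of stages, or `"all"`.
#' @return Invisibly, the manifest as a list.
#' @export
runPipeline <- function(outDir, config = pipelineConfig(), stages = "all") {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "PipelineConfig"))
  if (identical(stages, "all")) stages <- .stageOrder
  bad <- setdiff(stages, .stageOrder)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- .stageOrder[.stageOrder %in% stages]
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  sim <- config$sim
  pth <- function(...) file.path(outDir, ...)
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    message(sprintf("[%s] done in %.1fs", stage,
                    proc.time()[["elapsed"]] - t0))
    res
  }
  peakFmt <- if (sim$peakShape == "narrow") "narrowPeak" else "broadPeak"
  nSamples <- sim$nTissues * sim$nAnimals

  if ("simulate" %in% stages) tick("simulate", {
    ann <- simulateAnnotation(sim)
    sizes <- data.frame(
      name = GenomeInfoDb::seqnames(ann$genome@seqinfo),
      len = GenomeInfoDb::seqlengths(ann$genome@seqinfo))
    write.table(sizes, pth("genome.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    writeGeneModels(ann$genes, pth("genes.tsv"))
    pk <- simulatePeaks(sim, ann$genome, nSamples = nSamples)
    dir.create(pth("peaks"), showWarnings = FALSE)
    for (i in seq_along(pk$samples))
      writePeaks(pk$samples[[i]],
                 pth("peaks", sprintf("sample_%02d.%s", i, peakFmt)),
                 format = peakFmt)
  })

  genome <- readGenome(.needFile(pth("genome.tsv"), "simulate"))
  genes <- readGeneModels(.needFile(pth("genes.tsv"), "simulate"),
                          genome = genome)

  if ("consensus" %in% stages) tick("consensus", {
    files <- sort(list.files(pth("peaks"), full.names = TRUE))
    if (length(files) == 0)
      stop("missing input 'peaks/': run the 'simulate' stage first")
    sets <- lapply(files, readPeaks, format = peakFmt, genome = genome)
    cons <- consensusPeaks(sets, genome, minSupport = config$minSupport)
    names(cons) <- sprintf("peak_%d", seq_along(cons))
    writePeaks(cons, pth("consensus.bed"), format = "bed")
  })

  readConsensus <- function() {
    cons <- readPeaks(.needFile(pth("consensus.bed"), "consensus"),
                      format = "bed", genome = genome)
    ps <- PeakSet(granges(cons), shapeClass = sim$peakShape,
                  label = "consensus", genome = genome)
    names(ps) <- sprintf("peak_%d", seq_along(ps))
    ps
  }

  if ("annotate" %in% stages) tick("annotate", {
    cons <- readConsensus()
    cnt <- simulateCounts(sim, cons, genes,
                          pairs = pairPeaksGenes(cons, genes,
                                                 window = config$pairingWindow))
    writeCountsTsv(cnt$peakCounts, pth("peak_counts.tsv"), idCol = "peak_id")
    writeCountsTsv(cnt$geneCounts, pth("gene_counts.tsv"), idCol = "gene_id")
    write.table(cnt$sampleSheet, pth("samples.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(cnt$groundTruth, pth("ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    tissues <- unique(cnt$sampleSheet$tissue)
    act <- do.call(rbind, lapply(tissues, function(tt)
      classifyGeneActivity(cnt$geneCounts, cnt$sampleSheet, tt,
                           config$activeMin, config$inactiveMax)))
    ts <- do.call(rbind, lapply(tissues, function(tt) {
      g <- tissueSpecificActive(cnt$geneCounts, cnt$sampleSheet, tt,
                                config$activeMin, config$inactiveMax)
      if (length(g)) data.frame(gene_id = g, tissue = tt) else NULL
    }))
    act$tissue_specific <- paste(act$gene_id, act$tissue) %in%
      (if (is.null(ts)) character(0) else paste(ts$gene_id, ts$tissue))
    write.table(act, pth("gene_activity.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    writePeaks(buildPromoters(genes, config$promoterBp),
               pth("promoters.bed"), format = "bed")
    writePeaks(buildProximal(genes, config$promoterBp, config$proximalBp),
               pth("proximal.bed"), format = "bed")
  })

  readCountsBundle <- function() {
    list(peak = readCountsTsv(.needFile(pth("peak_counts.tsv"), "annotate")),
         gene = readCountsTsv(.needFile(pth("gene_counts.tsv"), "annotate")),
         sheet = readSampleSheet(.needFile(pth("samples.tsv"), "annotate")))
  }

  if ("diffbind" %in% stages) tick("diffbind", {
    b <- readCountsBundle()
    cons <- readConsensus()
    tissues <- unique(b$sheet$tissue)
    db <- do.call(rbind, lapply(tissues, function(tt)
      differentialBindingTest(b$peak, b$sheet, tt, alpha = config$alpha,
                              minFold = config$minFold,
                              libSizes = b$sheet$libSize)))
    idx <- match(db$peak_id, names(cons))
    db <- cbind(db[, "peak_id", drop = FALSE],
                chrom = as.character(seqnames(cons))[idx],
                start = start(cons)[idx] - 1L, end = end(cons)[idx],
                db[, setdiff(names(db), "peak_id")])
    write.table(db, pth("db_results.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  })

  if ("correlate" %in% stages) tick("correlate", {
    b <- readCountsBundle()
    cons <- readConsensus()
    prs <- pairPeaksGenes(cons, genes, window = config$pairingWindow)
    f <- tmmFactors(b$peak, libSizes = b$sheet$libSize)
    cpm <- normalizedCpm(b$peak, f, b$sheet$libSize)
    res <- correlatePeakGene(prs, cpm, b$gene, alpha = config$alpha)
    write.table(res, pth("correlations.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(correlationSummary(res), pth("correlation_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writePeaks(correlatedPeakSet(res, cons, alpha = config$alpha),
               pth("correlated_peaks.bed"), format = "bed")
  })

  if ("enrich" %in% stages) tick("enrich", {
    cons <- readConsensus()
    sn <- simulateSnps(sim, genome, cons, genes = genes,
                       bands = config$bands, withPvalues = TRUE)
    writeSnps(sn$snps, pth("snps.tsv"))
    results <- list(snpEnrichment(sn$snps, cons, genome))
    corFile <- pth("correlated_peaks.bed")
    if (file.exists(corFile)) {
      corPeaks <- readPeaks(corFile, format = "bed", genome = genome)
      corPeaks <- PeakSet(granges(corPeaks), shapeClass = sim$peakShape,
                          label = "correlated_peaks", genome = genome)
      if (length(corPeaks))
        results <- c(results, list(snpEnrichment(sn$snps, corPeaks, genome)))
    }
    write.table(enrichmentReport(results), pth("enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    bandTab <- distanceStratifiedEnrichment(sn$snps, cons, genes, genome,
                                            bands = config$bands,
                                            minSnps = config$minSnps)
    write.table(bandTab, pth("enrichment_by_distance.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    truth <- if (file.exists(pth("ground_truth.json")))
      jsonlite::read_json(pth("ground_truth.json")) else NULL
    activeIds <- if (!is.null(truth)) unlist(truth$activeGenes) else character(0)
    seg <- simulateSegmentation(sim, genome, genes,
                                activeGeneIds = activeIds)
    writeSegmentation(seg, pth("states.bed"))
    ov <- stateOverlapEnrichment(
      seg, list(promoters = buildPromoters(genes, config$promoterBp),
                peaks = cons), genome)
    fold <- data.frame(state = rownames(ov$fold), ov$fold,
                       genome_fraction = ov$genomeFraction,
                       check.names = FALSE)
    write.table(fold, pth("state_enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  })

  if ("prune" %in% stages) tick("prune", {
    snps <- readSnps(.needFile(pth("snps.tsv"), "enrich"), genome = genome)
    gt <- simulateGenotypes(sim, snps)
    dosTab <- data.frame(chrom = as.character(seqnames(snps)),
                         pos = start(snps), gt$dosages,
                         check.names = FALSE)
    write.table(dosTab, pth("genotypes.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    pruned <- windowPrune(snps, gt$dosages, windowBp = config$windowBp,
                          stepSnps = config$stepSnps, r2Max = config$r2Max,
                          mode = "by_pvalue")
    writeSnps(pruned, pth("snps_pruned.tsv"))
    cons <- readConsensus()
    res <- list(snpEnrichment(snps, cons, genome),
                snpEnrichment(pruned, cons, genome))
    res[[1]]@snpLabel <- "all_snps"
    res[[2]]@snpLabel <- "ld_pruned"
    write.table(enrichmentReport(res), pth("enrichment_pruned.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  })

  # manifest: parameters + checksums; no timestamps so reruns are identical
  files <- sort(setdiff(list.files(outDir, recursive = TRUE),
                        "manifest.json"))
  cfgOut <- config
  cfgOut$bands <- as.list(cfgOut$bands)
  class(cfgOut) <- NULL
  cfgOut$sim <- unclass(cfgOut$sim)
  manifest <- list(
    package = "EpiEnrich",
    version = as.character(utils::packageVersion("EpiEnrich")),
    seed = sim$seed,
    stages = stages,
    parameters = cfgOut,
    outputs = lapply(setNames(files, files), function(f)
      unname(tools::md5sum(file.path(outDir, f))))
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
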