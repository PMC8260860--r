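smallCfg <- function(...) {
  args <- list(seed = 3, nChroms = 3, chromLengthBp = 1e6, nGenes = 60,
               nPeaks = 200, nSnps = 400, nCorrelatedPairs = 10,
               nActivePerTissue = 3, nTissueSpecific = 2, nInactive = 3,
               nTissues = 3, nAnimals = 2)
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(simConfig, args)
}

test_that("generators are pure functions of the config seed", {
  cfg <- smallCfg()
  a1 <- simulateAnnotation(cfg)
  a2 <- simulateAnnotation(cfg)
  expect_identical(a1$genes, a2$genes)
  p1 <- simulatePeaks(cfg, a1$genome, nSamples = 4)
  p2 <- simulatePeaks(cfg, a1$genome, nSamples = 4)
  expect_identical(granges(p1$skeleton), granges(p2$skeleton))
  expect_identical(lapply(p1$samples, granges), lapply(p2$samples, granges))
  s1 <- simulateSnps(cfg, a1$genome, p1$skeleton)
  s2 <- simulateSnps(cfg, a1$genome, p1$skeleton)
  expect_identical(start(s1$snps), start(s2$snps))
  g1 <- simulateGenotypes(cfg, s1$snps)
  g2 <- simulateGenotypes(cfg, s1$snps)
  expect_identical(g1$dosages, g2$dosages)
  # a different seed changes the draw
  b <- simulateAnnotation(smallCfg(seed = 4))
  expect_false(identical(start(a1$genes), start(b$genes)))
})

test_that("annotation respects gene counts and placement constraints", {
  cfg <- smallCfg()
  ann <- simulateAnnotation(cfg)
  expect_length(ann$genes, 60)
  expect_false(anyDuplicated(mcols(ann$genes)$gene_id) > 0)
  # non-overlapping placement
  expect_length(GenomicRanges::reduce(ann$genes, ignore.strand = TRUE), 60)
  # confined to the gene-bearing fraction of each chromosome
  expect_true(all(end(ann$genes) <= 1e6 * cfg$geneRegionFraction))
  # empty-gene config yields a genome only
  ann0 <- simulateAnnotation(smallCfg(nGenes = 0))
  expect_length(ann0$genes, 0)
  expect_s4_class(ann0$genome, "GenomeModel")
})

test_that("noise-free replicates reproduce the skeleton consensus", {
  cfg <- smallCfg(dropout = 0, jitterBp = 0, bgPeakRate = 0)
  ann <- simulateAnnotation(cfg)
  pk <- simulatePeaks(cfg, ann$genome, nSamples = 4)
  cons <- consensusPeaks(pk$samples, ann$genome, minSupport = 2)
  expect_identical(granges(cons, use.mcols = FALSE),
                   granges(pk$skeleton, use.mcols = FALSE))
  # total dropout leaves nothing
  cfg1 <- smallCfg(dropout = 1, bgPeakRate = 0)
  pk1 <- simulatePeaks(cfg1, ann$genome, nSamples = 4)
  expect_length(consensusPeaks(pk1$samples, ann$genome, 2), 0)
})

test_that("summits stay inside simulated narrow peaks", {
  cfg <- smallCfg()
  ann <- simulateAnnotation(cfg)
  pk <- simulatePeaks(cfg, ann$genome, nSamples = 3)
  for (s in pk$samples) {
    expect_true(all(mcols(s)$summit >= 0))
    expect_true(all(mcols(s)$summit < width(s)))
  }
})

test_that("planted activity labels close the loop through the classifier", {
  cfg <- smallCfg()
  ann <- simulateAnnotation(cfg)
  pk <- simulatePeaks(cfg, ann$genome, nSamples = 4)
  cons <- consensusPeaks(pk$samples, ann$genome, 2)
  names(cons) <- sprintf("peak_%d", seq_along(cons))
  cnt <- simulateCounts(cfg, cons, ann$genes)
  gt <- cnt$groundTruth
  for (tt in unique(cnt$sampleSheet$tissue)) {
    act <- classifyGeneActivity(cnt$geneCounts, cnt$sampleSheet, tt)
    active <- act$gene_id[act$status == "active"]
    inactive <- act$gene_id[act$status == "inactive"]
    expect_true(all(gt$activeGenes[[tt]] %in% active))
    expect_true(all(gt$tissueSpecificGenes[[tt]] %in% active))
    expect_true(all(gt$inactiveGenes %in% inactive))
    ts <- tissueSpecificActive(cnt$geneCounts, cnt$sampleSheet, tt)
    expect_setequal(ts, gt$tissueSpecificGenes[[tt]])
  }
})

test_that("planted correlated pairs realize the target correlation", {
  cfg <- smallCfg(nCorrelatedPairs = 40, nTissues = 6, nAnimals = 3,
                  nGenes = 150)
  ann <- simulateAnnotation(cfg)
  pk <- simulatePeaks(cfg, ann$genome, nSamples = 4)
  cons <- consensusPeaks(pk$samples, ann$genome, 2)
  names(cons) <- sprintf("peak_%d", seq_along(cons))
  cnt <- simulateCounts(cfg, cons, ann$genes)
  prs <- cnt$groundTruth$correlatedPairs
  cpm <- normalizedCpm(cnt$peakCounts,
                       libSizes = cnt$sampleSheet$libSize, log = TRUE)
  r <- vapply(seq_len(nrow(prs)), function(i)
    cor(cpm[prs$peak_id[i], ], log2(cnt$geneCounts[prs$gene_id[i], ] + 0.5)),
    0)
  expect_gt(mean(r), 0.75)  # attenuated but close to the planted 0.9
})

test_that("SNP planting with rho = 1 is uniform over the genome", {
  cfg <- smallCfg(snpRho = 1, nSnps = 2000)
  ann <- simulateAnnotation(cfg)
  pk <- simulatePeaks(cfg, ann$genome, nSamples = 1)
  sn <- simulateSnps(cfg, ann$genome, pk$skeleton)
  r <- snpEnrichment(sn$snps, pk$skeleton, ann$genome)
  # binomial fluctuation around fold 1
  p <- r@A / r@D
  se <- sqrt((1 - p) / (r@B * p))
  expect_lt(abs(r@fold - 1), 4 * se)
  # empty regions -> pure uniform, fold undefined (A = 0)
  empty <- PeakSet(GRanges(seqinfo = ann$genome@seqinfo), genome = ann$genome)
  sn0 <- simulateSnps(cfg, ann$genome, empty)
  expect_length(sn0$snps, 2000)
})

test_that("block genotypes hit the target within-block r2", {
  cfg <- smallCfg(nIndividuals = 200, ldBlockSize = 5, ldBlockR2 = 1)
  ann <- simulateAnnotation(cfg)
  pk <- simulatePeaks(cfg, ann$genome, nSamples = 1)
  sn <- simulateSnps(cfg, ann$genome, pk$skeleton)
  gt <- simulateGenotypes(cfg, sn$snps)
  # flip probability 0: perfect within-block correlation
  b1 <- which(gt$blocks == gt$blocks[1])
  for (i in b1[-1])
    expect_equal(pairwiseR2(gt$dosages[b1[1], ], gt$dosages[i, ]), 1)
  # cross-block r2 is near the 1/n expectation for independent vectors
  other <- which(gt$blocks != gt$blocks[1])[1:20]
  r2s <- vapply(other, function(i)
    suppressWarnings(pairwiseR2(gt$dosages[b1[1], ], gt$dosages[i, ])), 0)
  expect_lt(mean(r2s), 4 / 200)
})

test_that("simulated segmentations tile the genome with planted promoters", {
  cfg <- smallCfg()
  ann <- simulateAnnotation(cfg)
  active <- head(mcols(ann$genes)$gene_id, 20)
  seg <- simulateSegmentation(cfg, ann$genome, ann$genes,
                              activeGeneIds = active)
  # full tiling: state fractions sum to 1
  ov <- stateOverlapEnrichment(
    seg, list(act_prom = granges(buildPromoters(
      ann$genes[mcols(ann$genes)$gene_id %in% active]))), ann$genome)
  expect_equal(sum(ov$genomeFraction), 1)
  expect_gt(ov$fold["active_promoter", "act_prom"], 1)
  expect_equal(sum(as.numeric(width(seg))),
               3 * 1e6)
})
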