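test_that("the worked quadruple gives fold 5 with exact tails", {
  gm <- GenomeModel("1", 1000)
  pk <- PeakSet(GRanges("1", IRanges(1, 100)), genome = gm)
  sn <- SnpRanges("1", c(10, 20, 30, 40, 50, 150, 300, 450, 600, 750),
               genome = gm)
  r <- snpEnrichment(sn, pk, gm)
  expect_equal(r@A, 100); expect_equal(r@B, 10); expect_equal(r@C, 5)
  expect_equal(r@D, 1000)
  expect_equal(r@fold, 5)
  oracle <- oracleHyperTails(100, 10, 5, 1000)
  expect_equal(r@pEnrich, oracle$pEnrich, tolerance = 1e-12)
  expect_equal(r@pDeplete, oracle$pDeplete, tolerance = 1e-12)
  # the two tails share the observed outcome
  expect_gte(r@pEnrich + r@pDeplete, 1)
})

test_that("fold obeys the algebraic identity C*D/(A*B)", {
  set.seed(19)
  for (i in 1:50) {
    D <- sample(100:10000, 1)
    A <- sample.int(D - 1, 1)
    B <- sample.int(min(D, 500), 1)
    C <- sample(0:min(A, B), 1)
    tails <- EpiEnrich:::.hyperTails(A, B, C, D)
    r <- EpiEnrich:::.enrichResult(A, B, C, D)
    expect_equal(r@fold, C * D / (A * B), tolerance = 1e-12)
    oracle <- oracleHyperTails(A, B, C, D)
    expect_equal(tails$pEnrich, oracle$pEnrich, tolerance = 1e-10)
    expect_equal(tails$pDeplete, oracle$pDeplete, tolerance = 1e-10)
  }
})

test_that("degenerate quadruples are flagged undefined, not 0/0", {
  gm <- GenomeModel("1", 1000)
  emptyPeaks <- PeakSet(GRanges(seqinfo = gm@seqinfo), genome = gm)
  sn <- SnpRanges("1", c(10, 20), genome = gm)
  r <- snpEnrichment(sn, emptyPeaks, gm)
  expect_false(r@defined)
  expect_true(is.na(r@fold))
  pk <- PeakSet(GRanges("1", IRanges(1, 100)), genome = gm)
  snOff <- SnpRanges("2", 5, genome = GenomeModel(c("1", "2"), c(1000, 500),
                                               autosomes = c("1", "2")))
  # SNP set empty after autosome restriction to a genome without SNPs under test
  gmX <- GenomeModel(c("1", "X"), c(1000, 500), autosomes = "1")
  snX <- SnpRanges("X", c(5, 10), genome = gmX)
  rX <- snpEnrichment(snX, PeakSet(GRanges("1", IRanges(1, 100)), genome = gmX),
                      gmX)
  expect_false(rX@defined)
})

test_that("only autosomal bases and SNPs enter the quadruple", {
  gmX <- GenomeModel(c("1", "X"), c(1000, 1000), autosomes = "1")
  pk <- PeakSet(GRanges(c("1", "X"), IRanges(c(1, 1), c(100, 100))),
                genome = gmX)
  sn <- SnpRanges(c("1", "1", "X"), c(50, 500, 50), genome = gmX)
  r <- snpEnrichment(sn, pk, gmX)
  expect_equal(r@A, 100)   # X peak excluded
  expect_equal(r@B, 2)     # X SNP excluded
  expect_equal(r@D, 1000)  # autosomal bp only
})

test_that("region boundaries are handled half-open after conversion", {
  gm <- GenomeModel("1", 1000)
  # 0-based region [100, 200): SNP at 0-based 100 inside, at 200 outside
  pk <- PeakSet(GRanges("1", IRanges(101, 200)), genome = gm)
  snIn <- SnpRanges("1", 101, genome = gm)   # 0-based 100
  snOut <- SnpRanges("1", 201, genome = gm)  # 0-based 200
  expect_equal(snpEnrichment(snIn, pk, gm)@C, 1)
  expect_equal(snpEnrichment(snOut, pk, gm)@C, 0)
})

test_that("enrichment ignores duplicate SNP records", {
  gm <- GenomeModel("1", 1000)
  pk <- PeakSet(GRanges("1", IRanges(1, 100)), genome = gm)
  a <- SnpRanges("1", c(10, 20, 500), genome = gm)
  b <- SnpRanges("1", c(10, 10, 20, 20, 500), genome = gm)
  expect_equal(as.data.frame(snpEnrichment(a, pk, gm)),
               as.data.frame(snpEnrichment(b, pk, gm)))
})

test_that("band restriction reproduces the unstratified result near TSS", {
  gm <- GenomeModel("1", 1e6)
  genes <- GRanges("1", IRanges(500001, 520000), strand = "+",
                   gene_id = "g", seqinfo = gm@seqinfo)
  # everything within 50 kb of the TSS at 500001
  pk <- PeakSet(GRanges("1", IRanges(c(460001, 510001), width = 2000)),
                "broad", genome = gm)
  sn <- SnpRanges("1", c(460501, 461000, 470000, 480000, 490000, 505000,
                      510500, 511000, 515000, 518000), genome = gm)
  tab <- distanceStratifiedEnrichment(sn, pk, genes, gm, minSnps = 10)
  un <- snpEnrichment(sn, pk, gm)
  expect_equal(tab$A[1], un@A)
  expect_equal(tab$B[1], un@B)
  expect_equal(tab$C[1], un@C)
  # band-1 D is the bp within 100 kb of the TSS, not the whole genome
  expect_equal(tab$D[1], 2 * 100000 - 1)
  expect_equal(tab$fold[1], tab$C[1] * tab$D[1] / (tab$A[1] * tab$B[1]))
  # all other bands have no SNPs -> NA
  expect_true(all(is.na(tab$fold[-1])))
})

test_that("bands with fewer than 10 SNPs report NA", {
  gm <- GenomeModel("1", 1e6)
  genes <- GRanges("1", IRanges(500001, 520000), strand = "+",
                   gene_id = "g", seqinfo = gm@seqinfo)
  pk <- PeakSet(GRanges("1", IRanges(510001, 512000)), "broad", genome = gm)
  sn <- SnpRanges("1", seq(501000, 509000, by = 1000), genome = gm)  # 9 SNPs
  tab <- distanceStratifiedEnrichment(sn, pk, genes, gm, minSnps = 10)
  expect_equal(tab$B[1], 9)
  expect_true(is.na(tab$fold[1]))
  tab2 <- distanceStratifiedEnrichment(sn, pk, genes, gm, minSnps = 9)
  expect_false(is.na(tab2$fold[1]))
})

test_that("a state equal to an annotation has fold D/A on its diagonal", {
  gm <- GenomeModel("1", 100000)
  seg <- StateSegmentation(GRanges("1", IRanges(c(1, 10001), c(10000, 100000)),
                                   state = c("s1", "s2"),
                                   seqinfo = gm@seqinfo))
  ann <- list(mirror = GRanges("1", IRanges(1, 10000)))
  ov <- stateOverlapEnrichment(seg, ann, gm)
  expect_equal(ov$fold["s1", "mirror"], 100000 / 10000)
  expect_equal(ov$fold["s2", "mirror"], 0)
  # tiling states: genome fractions sum to 1
  expect_equal(sum(ov$genomeFraction), 1)
})

test_that("enrichment reports bind rows and average folds", {
  mk <- function(fold, region, snp) {
    r <- EpiEnrich:::.enrichResult(100, 10, fold * 100 * 10 / 1000, 1000)
    r@regionLabel <- region; r@snpLabel <- snp
    r
  }
  single <- enrichmentReport(list(mk(2, "m1", "qtl")))
  expect_equal(nrow(single), 1)
  tab <- enrichmentReport(list(mk(2, "m1", "qtl"), mk(4, "m2", "qtl")),
                          averageBy = "snpLabel")
  expect_equal(tab$mean_fold, 3)
  same <- enrichmentReport(list(mk(2, "m1", "qtl"), mk(2, "m2", "qtl")),
                           averageBy = "snpLabel")
  expect_equal(same$mean_fold, 2)
})
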