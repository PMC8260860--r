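gm <- GenomeModel(as.character(1:3), c(10000, 8000, 6000))

writeLinesTmp <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}

test_that("narrowPeak fields map onto intervals and summits", {
  f <- writeLinesTmp("1\t100\t700\tp1\t0\t.\t5.1\t8.2\t6.0\t250")
  p <- readPeaks(f, "narrowPeak", gm)
  expect_s4_class(p, "PeakSet")
  expect_equal(start(p), 101)       # 0-based 100 -> 1-based 101
  expect_equal(end(p), 700)
  expect_equal(mcols(p)$summit, 250L)
  expect_equal(peakAnchors(p), 351) # 0-based 350
  expect_identical(shapeClass(p), "narrow")
})

test_that("empty, malformed and out-of-bounds peak files are handled", {
  expect_length(readPeaks(writeLinesTmp(character(0)), "bed", gm), 0)
  expect_error(readPeaks(writeLinesTmp("1\t500\t100\tp"), "bed", gm),
               "line 1")
  expect_error(readPeaks(writeLinesTmp("1\t100\t100\tp"), "bed", gm),
               "start < end")
  expect_error(readPeaks(writeLinesTmp("1\t100\t20000\tp"), "bed", gm),
               "beyond chromosome")
  expect_error(readPeaks(writeLinesTmp("7\t10\t20\tp"), "bed", gm),
               "unknown chromosome")
  expect_message(
    p <- readPeaks(writeLinesTmp(c("7\t10\t20\tp", "1\t10\t20\tq")), "bed",
                   gm, unknownChrom = "skip"),
    "skipped")
  expect_length(p, 1)
})

test_that("BED round-trip reproduces intervals exactly", {
  set.seed(11)
  gr <- randomIntervals(80, gm)
  mcols(gr)$summit <- as.integer(floor(width(gr) / 3))
  p <- PeakSet(gr, "narrow", genome = gm)
  f <- tempfile(fileext = ".narrowPeak")
  writePeaks(p, f, "narrowPeak")
  p2 <- readPeaks(f, "narrowPeak", gm)
  expect_identical(granges(p2, use.mcols = FALSE), granges(p, use.mcols = FALSE))
  expect_equal(mcols(p2)$summit, mcols(p)$summit)
})

test_that("coverage counts each base once", {
  p <- PeakSet(GRanges("1", IRanges(c(1, 51), c(100, 150))), genome = gm)
  expect_equal(coverageBp(p, gm), 150)
  p2 <- PeakSet(GRanges("1", IRanges(c(1, 21), c(10, 30))), genome = gm)
  expect_equal(coverageBp(p2, gm), 20)
})

test_that("coverage matches the per-base bitmap oracle on random sets", {
  set.seed(42)
  for (rep in 1:5) {
    gr <- randomIntervals(200, gm)
    p <- PeakSet(gr, genome = gm)
    expect_equal(coverageBp(p, gm), oracleCoverageBp(gr, gm))
  }
})

test_that("consensus of overlapping replicates is their intersection", {
  a <- PeakSet(GRanges("1", IRanges(1, 100)), genome = gm)
  b <- PeakSet(GRanges("1", IRanges(51, 150)), genome = gm)
  emptyGr <- GRanges(seqinfo = gm@seqinfo)
  cempty <- PeakSet(emptyGr, genome = gm)
  cons <- consensusPeaks(list(a, b, cempty), gm, minSupport = 2)
  expect_equal(as.character(granges(cons)), "1:51-100")
  expect_equal(mcols(cons)$maxSupport, 2)
})

test_that("consensus of identical replicates is idempotent", {
  a <- PeakSet(GRanges("2", IRanges(101, 600)), genome = gm)
  cons <- consensusPeaks(list(a, a, a), gm, minSupport = 2)
  expect_identical(granges(cons, use.mcols = FALSE), granges(a, use.mcols = FALSE))
  expect_equal(mcols(cons)$maxSupport, 3)
})

test_that("consensus equals the per-base vote oracle and is monotone", {
  set.seed(7)
  for (rep in 1:5) {
    sets <- lapply(1:5, function(i)
      PeakSet(randomIntervals(40, gm, maxWidth = 800), genome = gm))
    grl <- lapply(sets, granges)
    cons2 <- consensusPeaks(sets, gm, minSupport = 2)
    expect_identical(grKey(granges(cons2)), grKey(oracleConsensus(grl, gm, 2)))
    # monotone: support never increases covered bp
    cov <- vapply(1:5, function(k)
      coverageBp(consensusPeaks(sets, gm, minSupport = k), gm), 0)
    expect_true(all(diff(cov) <= 0))
    # minSupport = 1 equals the merged union
    expect_equal(cov[1], coverageBp(PeakSet(do.call(c, grl), genome = gm), gm))
  }
})

test_that("union coverage is subadditive with equality iff disjoint", {
  a <- GRanges("1", IRanges(1, 100))
  b <- GRanges("1", IRanges(200, 300))
  gm1 <- GenomeModel("1", 1000)
  expect_equal(coverageBp(PeakSet(c(a, b), genome = gm1), gm1),
               coverageBp(PeakSet(a, genome = gm1), gm1) +
                 coverageBp(PeakSet(b, genome = gm1), gm1))
  b2 <- GRanges("1", IRanges(50, 300))
  expect_lt(coverageBp(PeakSet(c(a, b2), genome = gm1), gm1),
            coverageBp(PeakSet(a, genome = gm1), gm1) +
              coverageBp(PeakSet(b2, genome = gm1), gm1))
})

test_that("consensus rejects bad support thresholds", {
  a <- PeakSet(GRanges("1", IRanges(1, 10)), genome = gm)
  expect_error(consensusPeaks(list(a), gm, minSupport = 0), "minSupport")
  expect_warning(cons <- consensusPeaks(list(a), gm, minSupport = 2),
                 "exceeds")
  expect_length(cons, 0)
})

test_that("anchors use summits for narrow and midpoints for broad peaks", {
  gr <- GRanges("1", IRanges(101, 700))
  mcols(gr)$summit <- 250L
  expect_equal(peakAnchors(PeakSet(gr, "narrow", genome = gm)), 351)
  # broad 0-based (1000, 2000) -> midpoint 1500 (0-based) = 1501 (1-based)
  b <- PeakSet(GRanges("1", IRanges(1001, 2000)), "broad", genome = gm)
  expect_equal(peakAnchors(b), 1501)
  # floor convention: 0-based (0,3) -> 1; 1-based interval [1,3] -> 2
  b2 <- PeakSet(GRanges("1", IRanges(1, 3)), "broad", genome = gm)
  expect_equal(peakAnchors(b2), 2)
  # narrow without summit falls back to midpoint with a warning
  n2 <- PeakSet(GRanges("1", IRanges(1001, 2000)), "narrow", genome = gm)
  expect_warning(a <- peakAnchors(n2), "midpoint")
  expect_equal(a, 1501)
})

test_that("distance to nearest TSS matches the exhaustive scan", {
  tss <- GRanges(c("1", "1"), IRanges(c(1000, 10000), width = 1))
  pos <- GRanges("1", IRanges(500, width = 1))
  expect_equal(distanceToNearestTss(pos, tss), 500)
  expect_equal(distanceToNearestTss(GRanges("1", IRanges(1000, width = 1)), tss), 0)

  set.seed(5)
  tssR <- GRanges(sample(c("1", "2"), 10, TRUE),
                  IRanges(sample.int(8000, 10), width = 1))
  posR <- GRanges(sample(c("1", "2"), 100, TRUE),
                  IRanges(sample.int(6000, 100), width = 1))
  expect_equal(
    distanceToNearestTss(posR, tssR),
    oracleNearestTss(as.character(seqnames(posR)), start(posR),
                     as.character(seqnames(tssR)), start(tssR)))
  # chromosome without TSS -> NA with warning
  expect_warning(
    d <- distanceToNearestTss(GRanges("3", IRanges(5, width = 1)), tssR),
    "without a TSS")
  expect_true(is.na(d))
})
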