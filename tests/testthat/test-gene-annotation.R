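gm <- GenomeModel("1", 100000)

mkExpr <- function(mat, tissues) {
  sheet <- data.frame(sample = colnames(mat),
                      animal = sprintf("a%d", seq_len(ncol(mat))),
                      tissue = tissues, stringsAsFactors = FALSE)
  list(mat = mat, sheet = sheet)
}

test_that("activity thresholds are strict on both sides", {
  mat <- rbind(
    g1 = c(250, 300, 210),   # all over 200 -> active
    g2 = c(0, 5, 9),         # all under 10 -> inactive
    g3 = c(250, 5, 300),     # mixed -> ambiguous
    g4 = c(200, 300, 400),   # 200 is not over 200 -> ambiguous
    g5 = c(9, 9, 10)         # 10 is not under 10 -> ambiguous
  )
  colnames(mat) <- c("s1", "s2", "s3")
  e <- mkExpr(mat, rep("mammary", 3))
  act <- classifyGeneActivity(e$mat, e$sheet, "mammary")
  expect_equal(as.character(act$status),
               c("active", "inactive", "ambiguous", "ambiguous", "ambiguous"))
  expect_error(classifyGeneActivity(e$mat, e$sheet, "liver"), "absent")
})

test_that("each gene gets exactly one activity status", {
  set.seed(3)
  mat <- matrix(rnbinom(300, mu = 100, size = 2), 50, 6,
                dimnames = list(sprintf("g%d", 1:50), sprintf("s%d", 1:6)))
  e <- mkExpr(mat, rep(c("liver", "heart"), each = 3))
  act <- classifyGeneActivity(e$mat, e$sheet, "liver")
  expect_equal(nrow(act), 50)
  expect_false(any(is.na(act$status)))
  expect_true(all(table(act$gene_id) == 1))
})

test_that("tissue-specific genes are active focally and silent elsewhere", {
  mat <- rbind(
    gA = c(300, 400, 2, 5),   # specific to mammary
    gB = c(300, 400, 250, 260), # active in both -> not specific
    gC = c(50, 60, 2, 5)
  )
  colnames(mat) <- sprintf("s%d", 1:4)
  e <- mkExpr(mat, c("mammary", "mammary", "liver", "liver"))
  expect_equal(tissueSpecificActive(e$mat, e$sheet, "mammary"), "gA")
  expect_length(tissueSpecificActive(e$mat, e$sheet, "liver"), 0)
  # subset property: specific implies active
  act <- classifyGeneActivity(e$mat, e$sheet, "mammary")
  expect_true(all(tissueSpecificActive(e$mat, e$sheet, "mammary") %in%
                    act$gene_id[act$status == "active"]))
})

test_that("promoters span 2 kb upstream of the TSS, strand-aware", {
  genes <- GRanges("1", IRanges(c(10001, 5001), c(12000, 9000)),
                   strand = c("+", "-"),
                   gene_id = c("gp", "gm"),
                   seqinfo = gm@seqinfo)
  prom <- buildPromoters(genes)
  # + strand TSS at 0-based 10000: promoter 0-based [8000, 10000)
  gp <- prom[mcols(prom)$gene_id == "gp"]
  expect_equal(c(start(gp) - 1, end(gp)), c(8000, 10000))
  # - strand TSS at 1-based 9000: width-2000 window downstream in genome coords
  gmr <- prom[mcols(prom)$gene_id == "gm"]
  expect_equal(width(gmr), 2000)
  expect_equal(start(gmr), 9001)
})

test_that("promoters clip at chromosome edges", {
  genes <- GRanges("1", IRanges(501, 2000), strand = "+",
                   gene_id = "g", seqinfo = gm@seqinfo)
  prom <- buildPromoters(genes)
  expect_equal(c(start(prom) - 1, end(prom)), c(0, 500))
  gEnd <- GRanges("1", IRanges(98000, 99500), strand = "-",
                  gene_id = "h", seqinfo = gm@seqinfo)
  promEnd <- buildPromoters(gEnd)
  expect_equal(end(promEnd), 100000)  # clipped at chromosome length
  expect_lt(width(promEnd), 2000)
})

test_that("proximal regions sit upstream of the promoter, never overlapping", {
  genes <- GRanges("1", IRanges(c(20001, 8001), c(30000, 30000)),
                   strand = c("+", "+"),
                   gene_id = c("g1", "g2"), seqinfo = gm@seqinfo)
  prox <- buildProximal(genes)
  g1 <- prox[mcols(prox)$gene_id == "g1"]
  # + strand TSS 0-based 20000 -> proximal [10000, 18000)
  expect_equal(c(start(g1) - 1, end(g1)), c(10000, 18000))
  # TSS 0-based 8000 -> clips to [0, 6000)
  g2 <- prox[mcols(prox)$gene_id == "g2"]
  expect_equal(c(start(g2) - 1, end(g2)), c(0, 6000))
  prom <- buildPromoters(genes)
  expect_length(GenomicRanges::intersect(granges(prom), granges(prox)), 0)
})

test_that("strand flip mirrors promoter geometry around the TSS", {
  genes <- GRanges("1", IRanges(40001, 50000), strand = "+",
                   gene_id = "g", seqinfo = gm@seqinfo)
  flipped <- genes
  strand(flipped) <- "-"
  pp <- buildPromoters(genes)
  pm <- buildPromoters(flipped)
  tssP <- start(genes)
  tssM <- end(flipped)
  # distances from TSS to promoter edges are mirrored
  expect_equal(tssP - end(pp), start(pm) - tssM)
  expect_equal(tssP - start(pp), end(pm) - tssM)
})

test_that("gene models load from TSV and GTF with derived TSS", {
  tsv <- tempfile(fileext = ".tsv")
  write.table(data.frame(gene_id = c("a", "b"), chrom = "1",
                         start = c(100, 5000), end = c(1000, 8000),
                         strand = c("+", "-")),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  g1 <- readGeneModels(tsv, genome = gm)
  expect_equal(start(geneTss(g1)), c(100, 8000))

  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("1\tsrc\tgene\t100\t1000\t.\t+\t.\t",
           "gene_id \"a\";"),
    paste0("1\tsrc\tgene\t5000\t8000\t.\t-\t.\t",
           "gene_id \"b\";")), gtf)
  g2 <- readGeneModels(gtf, genome = gm)
  expect_equal(sort(mcols(g2)$gene_id), c("a", "b"))
  expect_equal(start(geneTss(g2)), start(geneTss(g1)))
})
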