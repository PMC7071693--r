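test_that("geneModelsFromExons unions overlapping exons per gene", {
  ex <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(c(101, 151, 401, 1001), c(250, 300, 700, 1100)),
    strand = c("+", "+", "+", "-"))
  genes <- geneModelsFromExons(ex, c("gA", "gA", "gA", "gB"))
  expect_setequal(names(genes), c("gA", "gB"))
  expect_equal(GenomicRanges::start(genes[["gA"]]), c(101, 401))
  expect_equal(GenomicRanges::end(genes[["gA"]]), c(300, 700))
  expect_equal(unname(S4Vectors::mcols(genes)$exonicLength),
               c(200 + 300, 100))
})

test_that("genes spanning several chromosomes or strands are dropped", {
  ex <- GenomicRanges::GRanges(
    c("chr1", "chr2", "chr1"),
    IRanges::IRanges(c(1, 1, 500), width = 100),
    strand = c("+", "+", "+"))
  expect_warning(genes <- geneModelsFromExons(ex, c("bad", "bad", "ok")),
                 "multiple chromosomes")
  expect_identical(names(genes), "ok")
})

test_that("computeTpm matches the length-normalized rate formula", {
  ex <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(1, 1001), c(500, 3000)),
                               strand = "+")
  genes <- geneModelsFromExons(ex, c("g1", "g2"))
  cnt <- c(g1 = 50, g2 = 100)
  tpm <- computeTpm(cnt, genes)
  rate <- c(50 / 500, 100 / 2000)
  expect_equal(unname(tpm), rate / sum(rate) * 1e6)
  ## genes missing from the count vector count as zero
  tpm2 <- computeTpm(c(g1 = 50), genes)
  expect_equal(unname(tpm2), c(1e6, 0))
  expect_warning(z <- computeTpm(c(g1 = 0, g2 = 0), genes), "all-zero")
  expect_equal(unname(z), c(0, 0))
})

test_that("filterExpressed uses an inclusive threshold", {
  ex <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 101, 201),
                                                        width = 50),
                               strand = "+")
  genes <- geneModelsFromExons(ex, c("g1", "g2", "g3"))
  tpm <- c(g1 = 0.49, g2 = 0.5, g3 = 10)
  kept <- filterExpressed(genes, tpm, threshold = 0.5)
  expect_setequal(names(kept), c("g2", "g3"))
  expect_error(filterExpressed(genes, c(g1 = 1)), "every gene")
})

test_that("makeBins tiles the concatenated exon space", {
  ## 500 exonic bases in two exons -> bins of 200, 200, 100; the second
  ## bin spans the splice junction
  ex <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(101, 401),
                                                        c(350, 650)),
                               strand = "+")
  genes <- geneModelsFromExons(ex, c("g1", "g1"))
  bins <- makeBins(genes, 200L)
  expect_s4_class(bins, "TranscriptomeBins")
  expect_equal(length(bins), 3L)
  bd <- binData(bins)
  expect_equal(bd$txStart, c(0L, 200L, 400L))
  expect_equal(bd$txEnd, c(200L, 400L, 500L))
  blk <- binBlocks(bins)
  expect_equal(lengths(blk), c(g1.1 = 1L, g1.2 = 2L, g1.3 = 1L))
  expect_equal(GenomicRanges::start(blk[[2]]), c(301, 401))
  expect_equal(GenomicRanges::end(blk[[2]]), c(350, 550))
  expect_equal(sum(GenomicRanges::width(blk[[2]])), 200)
})

test_that("makeBins keeps a short trailing bin", {
  ex <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 201), strand = "+")
  genes <- geneModelsFromExons(ex, "g1")
  bins <- makeBins(genes, 100L)
  expect_equal(binData(bins)$txEnd - binData(bins)$txStart,
               c(100L, 100L, 1L))
})

test_that("txToGenome and genomeToTx invert each other on a minus-strand gene", {
  ex <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(101, 301),
                                                        c(150, 320)),
                               strand = "-")
  genes <- geneModelsFromExons(ex, "g1")
  exons <- genes[[1]]
  len <- sum(GenomicRanges::width(exons))
  tx <- 0:(len - 1)
  gpos <- txToGenome(exons, tx)
  ## offset 0 is the rightmost base of the rightmost exon
  expect_equal(gpos[1], 320)
  expect_equal(gpos, exonicBases5to3(exons))
  expect_equal(genomeToTx(exons, gpos), tx)
  ## intronic position maps to NA, out-of-range offsets error
  expect_true(is.na(genomeToTx(exons, 200L)))
  expect_error(txToGenome(exons, len), "out of range")
})

test_that("readGeneModels parses the fixture GTF into union exons", {
  dir <- tempfile("fixtures")
  on.exit(unlink(dir, recursive = TRUE))
  paths <- makeFixtures(dir)
  genes <- readGeneModels(paths$gtf)
  expect_setequal(names(genes), c("gA", "gB", "gC", "gD"))
  ## gA has two transcripts; union exons are 101-300 and 401-700
  expect_equal(GenomicRanges::start(genes[["gA"]]), c(101, 401))
  expect_equal(GenomicRanges::end(genes[["gA"]]), c(300, 700))
  expect_equal(unname(S4Vectors::mcols(genes)$exonicLength),
               c(500, 500, 500, 500))
  suppressWarnings(
    expect_error(readGeneModels(file.path(dir, "absent.gtf")), "GTF"))
})
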