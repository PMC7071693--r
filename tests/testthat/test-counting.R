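fixDir <- tempfile("fixtures")
fixtures <- makeFixtures(fixDir)

test_that("CIGAR reference widths cover M/D/N/=/X and skip clips", {
  w <- meripmix:::.cigarRefWidth(c("50M", "20M150N30M", "10S40M", "25M5D10M",
                                   "10M2I10M", "5H20M", "*", NA))
  expect_equal(w, c(50L, 200L, 40L, 40L, 20L, 20L, NA, NA))
})

test_that("readEvents reduces single-end records to 5' positions", {
  ev <- readEvents(fixtures$ipSe, paired = FALSE, minMapq = 1L)
  md <- S4Vectors::metadata(ev)
  ## unmapped r5, secondary r4 and duplicate r3 are dropped by flag;
  ## r14 (MAPQ 0) is dropped by the threshold
  expect_equal(md$nEvents, 10L)
  expect_false(md$paired)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(ev)),
                   pos = GenomicRanges::start(ev),
                   strand = as.character(GenomicRanges::strand(ev)))
  ## r12: minus strand, pos 90, 20M -> 5' end at 109 (outside gA's exons)
  expect_true(any(df$chrom == "chrT1" & df$pos == 109 & df$strand == "-"))
  ## r2: minus strand, pos 201, 50M -> 5' end at 250
  expect_true(any(df$chrom == "chrT1" & df$pos == 250 & df$strand == "-"))
  ## r6: junction read 20M150N30M at 230 -> plus-strand 5' end stays at 230
  expect_true(any(df$chrom == "chrT1" & df$pos == 230 & df$strand == "+"))
  ## r11: soft clip 10S40M at 550 -> 5' end at 550 (clip never shifts pos)
  expect_true(any(df$chrom == "chrT2" & df$pos == 550 & df$strand == "+"))
  expect_error(readEvents(file.path(fixDir, "missing.bam")), "not found")
})

test_that("lowering minMapq retains the MAPQ-0 record", {
  ev <- readEvents(fixtures$ipSe, paired = FALSE, minMapq = 0L)
  expect_equal(S4Vectors::metadata(ev)$nEvents, 11L)
})

test_that("paired-end mode counts each proper pair once via its first mate", {
  ev <- readEvents(fixtures$ipPe, paired = TRUE)
  ## p1, p2, p4, p5 are proper pairs (p3 has an unmapped mate, p6 is
  ## duplicate-marked); one event per fragment
  expect_equal(length(ev), 4L)
  df <- data.frame(pos = GenomicRanges::start(ev),
                   strand = as.character(GenomicRanges::strand(ev)))
  ## p2's first mate is the reverse record at 420 (40M): 5' end 459
  expect_true(any(df$pos == 459 & df$strand == "-"))
  ## p5's first mate is the reverse record at 481 (40M): 5' end 520
  expect_true(any(df$pos == 520 & df$strand == "-"))
})

test_that("single-end mode warns when paired flags are present", {
  expect_warning(readEvents(fixtures$ipPe, paired = FALSE),
                 "paired-end flags")
})

test_that("strand compatibility implements both library protocols", {
  comp <- meripmix:::.strandCompatible
  ev <- c("+", "-", "*")
  expect_equal(comp(ev, c("+", "+", "+"), "none"), c(TRUE, TRUE, TRUE))
  expect_equal(comp(ev, c("+", "+", "+"), "forward"), c(TRUE, FALSE, TRUE))
  expect_equal(comp(ev, c("+", "+", "+"), "reverse"), c(FALSE, TRUE, TRUE))
  expect_error(comp("+", "+", "bogus"), "strandedness")
})

test_that("countEvents respects bin blocks and gene strand", {
  genes <- readGeneModels(fixtures$gtf)
  bins <- makeBins(genes, 200L)
  ## one plus-strand event inside gC and gD's shared interval
  ev <- GenomicRanges::GRanges("chrT2", IRanges::IRanges(450, 450),
                               strand = "+")
  none <- countEvents(ev, bins, "none")
  expect_equal(sum(none), 2L)  # multi-overlap: both genes counted
  fwd <- countEvents(ev, bins, "forward")
  hitGenes <- unique(binData(bins)$geneId[fwd > 0])
  expect_identical(hitGenes, "gC")  # only the sense gene
  rev <- countEvents(ev, bins, "reverse")
  expect_identical(unique(binData(bins)$geneId[rev > 0]), "gD")
  ## an intronic event counts nowhere
  evIntron <- GenomicRanges::GRanges("chrT1", IRanges::IRanges(350, 350),
                                     strand = "+")
  expect_equal(sum(countEvents(evIntron, bins, "none")), 0L)
})

test_that("countBins assembles a valid BinCounts object", {
  genes <- readGeneModels(fixtures$gtf)
  bins <- makeBins(genes, 200L)
  ipEv <- readEvents(fixtures$ipSe)
  inEv <- readEvents(fixtures$inputSe)
  cm <- countBins(ipEv, inEv, bins, "none")
  expect_s4_class(cm, "BinCounts")
  expect_equal(nrow(cm), length(bins))
  expect_equal(colnames(cm), c("ip", "input"))
  expect_true(all(ipCounts(cm) >= 0))
  expect_equal(S4Vectors::metadata(cm)$strandedness, "none")
  expect_equal(sum(inputCounts(cm)), 8L)  # every input read lands in a bin
})

test_that("countGenes feeds the expression filter", {
  genes <- readGeneModels(fixtures$gtf)
  inEv <- readEvents(fixtures$inputSe)
  gcnt <- countGenes(inEv, genes, "none")
  expect_equal(gcnt, c(gA = 2L, gB = 2L, gC = 2L, gD = 2L))
  ## strand-aware: the two input reads in each gene are on the gene strand
  expect_equal(countGenes(inEv, genes, "forward"),
               c(gA = 2L, gB = 2L, gC = 2L, gD = 2L))
  expect_equal(sum(countGenes(inEv, genes, "reverse")), 0L)
})
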