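## A small fitted scenario shared by the calling tests
set.seed(21)
callT <- 4000
callMu <- rep(c(2, 5, 10, 0.5), length.out = callT)
callSim <- simulateCounts(callMu, a = 2,
                          list(b = 4, c = 0.08, k = 3L, piS = 0.2),
                          seed = 21)
callBg <- new("BackgroundFit", kind = "constant", coefficients = list(),
              a = 2, mu = callMu, regressionBic = NA_real_,
              groups = data.frame(), zeroMu = 0.5, model = NULL)
callFit <- fitMixture(bg = callBg, Y = callSim$Y, kGrid = 3L, modes = "1S")

test_that("posteriorNull returns calibrated-looking probabilities", {
  pt <- posteriorNull(callSim$Y, callFit)
  expect_true(all(pt$postNull >= 0 & pt$postNull <= 1))
  expect_named(pt, c("p0", "p1", "postNull"))
  ## truly enriched bins concentrate at low posterior-null
  expect_lt(mean(pt$postNull[callSim$truth$Z == 1]),
            mean(pt$postNull[callSim$truth$Z == 0]))
  ## a large count under a small background mean is near-certain signal
  big <- which.max(callSim$Y)
  expect_lt(pt$postNull[big], 0.01)
})

test_that("fdrSelect matches the exhaustive prefix oracle on edge cases", {
  expect_identical(fdrSelect(numeric(), 0.05), integer())
  expect_identical(fdrSelect(c(0.9, 0.8), 0.05), integer())
  expect_equal(sort(fdrSelect(c(0.01, 0.2, 0.03), 0.05)), c(1L, 3L))
  ## tie groups never split: both 0.04 bins enter together or not at all
  ps <- c(0.01, 0.04, 0.04, 0.9)
  expect_equal(sort(fdrSelect(ps, 0.05)), sort(fdrSelectOracle(ps, 0.05)))
  expect_error(fdrSelect(0.5, 0), "cutoff")
  expect_error(fdrSelect(0.5, 1), "cutoff")
})

test_that("the estimated FDR of a non-empty selection never exceeds the cutoff", {
  set.seed(22)
  for (i in 1:20) {
    ps <- runif(200)^3
    sel <- fdrSelect(ps, 0.05)
    if (length(sel)) expect_lte(mean(ps[sel]), 0.05)
  }
})

test_that("mergeBins joins transcript-adjacent bins within one gene", {
  ## gene g01: bins 1-5; gene g02: bins 6-10 (binSize 100)
  Y <- c(50, 60, 0, 0, 40, 0, 70, 0, 0, 0)
  X <- rep(1L, 10)
  cm <- toyBinCounts(Y, X, binsPerGene = 5L, binSize = 100L)
  post <- ifelse(Y > 0, 0.01, 0.9)
  sig <- which(Y > 0)
  regions <- mergeBins(cm, sig, post)
  mc <- S4Vectors::mcols(regions)
  ## bins 1+2 merge; bin 5 stands alone (gap at 3-4); bin 7 is its own
  ## region in the second gene
  expect_equal(length(regions), 3L)
  expect_equal(mc$geneId, c("g01", "g01", "g02"))
  expect_equal(mc$nBins, c(2L, 1L, 1L))
  expect_equal(mc$score, c(60, 40, 70))
  expect_equal(mc$name, c("g01:1", "g01:2", "g02:1"))
  expect_equal(mc$txStart, c(0L, 400L, 100L))
  expect_equal(mc$txEnd, c(200L, 500L, 200L))
  ## adjacent bins of *different* genes never merge: bin 5 (end of g01)
  ## and bin 6 (start of g02) are genomically far anyway, but check the
  ## gene boundary rule directly
  r2 <- mergeBins(cm, c(5L, 6L), rep(0.01, 10))
  expect_equal(length(r2), 2L)
  expect_equal(length(mergeBins(cm, integer(), post)), 0L)
})

test_that("callRegions controls the direct-posterior FDR end to end", {
  cm <- toyBinCounts(callSim$Y[1:1000], rep(1L, 1000),
                     binsPerGene = 5L, binSize = 100L)
  ## rebuild a fit whose background matches this subset
  bg <- new("BackgroundFit", kind = "constant", coefficients = list(),
            a = 2, mu = callMu[1:1000], regressionBic = NA_real_,
            groups = data.frame(), zeroMu = 0.5, model = NULL)
  fit <- fitMixture(bg = bg, Y = callSim$Y[1:1000], kGrid = 3L, modes = "1S")
  regions <- callRegions(cm, fit, fdrCutoff = 0.05)
  md <- S4Vectors::metadata(regions)
  expect_true(length(regions) > 0)
  expect_lte(md$estimatedFdr, 0.05)
  expect_equal(length(md$postNull), 1000L)
  expect_equal(sum(S4Vectors::mcols(regions)$nBins), md$nSelectedBins)
  ## minScore filters whole regions
  rHi <- callRegions(cm, fit, fdrCutoff = 0.05, minScore = 1e6)
  expect_equal(length(rHi), 0L)
})

test_that("BED12 output round-trips and is schema-valid", {
  Y <- c(50, 60, 0, 0, 40, 0, 70, 0, 0, 0)
  cm <- toyBinCounts(Y, rep(1L, 10), binsPerGene = 5L, binSize = 100L)
  post <- ifelse(Y > 0, 0.01, 0.9)
  regions <- mergeBins(cm, which(Y > 0), post)
  path <- tempfile(fileext = ".bed")
  writeBed12(regions, path)
  lines <- readLines(path)
  expect_equal(length(lines), 3L)
  fields <- strsplit(lines, "\t")
  expect_true(all(lengths(fields) == 12L))
  ## sorted by (chrom, chromStart); 0-based starts; block lists end with a
  ## trailing comma per BED12 practice
  starts <- as.integer(vapply(fields, `[[`, "", 2))
  expect_true(!is.unsorted(starts))
  expect_true(all(grepl(",$", vapply(fields, `[[`, "", 11))))
  back <- readBed12(path)
  expect_equal(length(back), 3L)
  expect_setequal(S4Vectors::mcols(back)$name,
                  S4Vectors::mcols(regions)$name)
  ## coordinates survive the round trip
  ord <- match(S4Vectors::mcols(regions)$name, S4Vectors::mcols(back)$name)
  expect_equal(GenomicRanges::start(back)[ord],
               GenomicRanges::start(regions))
  expect_equal(GenomicRanges::end(back)[ord], GenomicRanges::end(regions))
  ## empty region set -> empty file
  writeBed12(regions[0], path)
  expect_equal(length(readLines(path)), 0L)
})

test_that("writeBed12 can clamp scores into the nominal BED range", {
  Y <- c(5000, 0, 0, 0, 0)
  cm <- toyBinCounts(Y, rep(1L, 5), binsPerGene = 5L, binSize = 100L)
  regions <- mergeBins(cm, 1L, rep(0.01, 5))
  path <- tempfile(fileext = ".bed")
  writeBed12(regions, path, clampScore = TRUE)
  expect_equal(as.integer(strsplit(readLines(path), "\t")[[1]][5]), 1000L)
  writeBed12(regions, path)
  expect_equal(as.integer(strsplit(readLines(path), "\t")[[1]][5]), 5000L)
})
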