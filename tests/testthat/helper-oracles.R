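## Independent reference implementations used to cross-check the package's
## numerics, plus small constructors for synthetic objects.

## Brute-force signal density: Y = N + S + k with N ~ NB(a, a/(a+mu)) and
## S ~ NB(b, c/(c+1)). The double sum over (N, S) outcomes is finite and
## exact because N + S = y - k bounds both terms.
bruteSignal1S <- function(y, a, mu, b, c, k) {
  vapply(y, function(yy) {
    if (yy < k) return(0)
    s <- 0:(yy - k)
    sum(stats::dnbinom(yy - k - s, size = a, prob = a / (a + mu)) *
        stats::dnbinom(s, size = b, prob = c / (c + 1)))
  }, 0)
}

bruteSignal2S <- function(y, a, mu, b1, c1, b2, c2, piS1, k) {
  piS1 * bruteSignal1S(y, a, mu, b1, c1, k) +
    (1 - piS1) * bruteSignal1S(y, a, mu, b2, c2, k)
}

## Exhaustive best-prefix FDR selection: scan every prefix length of the
## ascending posterior order, keep the largest one whose mean is at or
## below the cutoff and whose boundary does not split a tie group.
fdrSelectOracle <- function(postNull, cutoff) {
  n <- length(postNull)
  if (n == 0) return(integer())
  ord <- order(postNull)
  ps <- postNull[ord]
  best <- 0L
  for (m in seq_len(n)) {
    splitsTie <- m < n && ps[m + 1] == ps[m]
    if (!splitsTie && mean(ps[seq_len(m)]) <= cutoff) best <- m
  }
  if (best == 0L) integer() else ord[seq_len(best)]
}

## Exonic bases of a gene enumerated 5' -> 3' (independent of the package's
## offset arithmetic): per-base oracle for the coordinate mapping.
exonicBases5to3 <- function(exons) {
  st <- GenomicRanges::start(exons)
  en <- GenomicRanges::end(exons)
  strand <- as.character(GenomicRanges::strand(exons)[1])
  if (strand == "-") {
    ord <- order(st, decreasing = TRUE)
    unlist(lapply(ord, function(e) seq(en[e], st[e])))
  } else {
    ord <- order(st)
    unlist(lapply(ord, function(e) seq(st[e], en[e])))
  }
}

## A BinCounts object over a toy scaffold of equal-length single-exon
## plus-strand genes, with the given IP/input counts.
toyBinCounts <- function(Y, X, binsPerGene = 5L, binSize = 100L) {
  T <- length(Y)
  stopifnot(T %% binsPerGene == 0, length(X) == T)
  nGenes <- T %/% binsPerGene
  geneLen <- binsPerGene * binSize
  starts <- 1L + (seq_len(nGenes) - 1L) * (geneLen + 200L)
  exons <- GenomicRanges::GRanges(
    "chrZ", IRanges::IRanges(starts, width = geneLen), strand = "+")
  genes <- geneModelsFromExons(exons, sprintf("g%02d", seq_len(nGenes)))
  bins <- makeBins(genes, binSize)
  rr <- binBlocks(bins)
  bd <- binData(bins)
  colnames(bd)[colnames(bd) == "strand"] <- "geneStrand"
  S4Vectors::mcols(rr) <- bd
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = cbind(ip = as.integer(Y), input = as.integer(X))),
    rowRanges = rr,
    colData = S4Vectors::DataFrame(sample = c("ip", "input"),
                                   row.names = c("ip", "input")))
  new("BinCounts", se)
}

## Synthetic per-group background tables for the regression tests: a known
## mean law on a grid of input counts with multiplicative log-normal noise.
syntheticGroups <- function(x, muFun, noiseSd, n = 500L, seed = 1) {
  set.seed(seed)
  mu <- muFun(x) * exp(stats::rnorm(length(x), 0, noiseSd))
  data.frame(x = x, n = rep(as.integer(n), length(x)), mu = mu,
             var = mu * 2, aGroup = NA_real_)
}
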