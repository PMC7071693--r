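#' Simulate an input sample over a gene/bin scaffold
#'
#' Gene-level expression is drawn log-normally; each gene's bins receive
#' NB-distributed input counts around the gene's expression level, so the
#' dispersion of input counts is expression-driven. A fraction of genes
#' can be silenced (zero expression, hence all-zero input bins).
#'
#' @param T Total number of bins.
#' @param nGenes Number of genes the bins are split across.
#' @param meanlog,sdlog Log-normal parameters of the per-bin expression
#'   level (defaults `log(8)` and 0.6).
#' @param inputSize NB size of input counts around the gene level
#'   (default 5).
#' @param zeroGeneFrac Fraction of genes with zero expression (default 0).
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @return List: `X` (input counts), `geneId` (per bin), `lambda`
#'   (per-gene expression level).
#' @export
simulateInput <- function(T, nGenes, meanlog = log(8), sdlog = 0.6,
                          inputSize = 5, zeroGeneFrac = 0, seed = 1) {
  stopifnot(T >= 1, nGenes >= 1)
  set.seed(seed)
  lambda <- stats::rlnorm(nGenes, meanlog, sdlog)
  if (zeroGeneFrac > 0) {
    nz <- floor(nGenes * zeroGeneFrac)
    if (nz > 0) lambda[sample.int(nGenes, nz)] <- 0
  }
  geneId <- sprintf("g%03d", rep(seq_len(nGenes), length.out = T))
  geneId <- sort(geneId)
  lam <- lambda[as.integer(sub("g", "", geneId))]
  X <- integer(T)
  pos <- lam > 0
  X[pos] <- stats::rnbinom(sum(pos), size = inputSize, mu = lam[pos])
  list(X = X, geneId = geneId, lambda = lambda)
}

#' Simulate IP bin counts from the mixture model
#'
#' Exactly the generative recipe of the model: every bin draws a
#' background count `N_j ~ NB(a, a/(a+mu_j))`; bins latently labelled as
#' signal (probability `piS`, component 1 vs 2 with probability `piS1`
#' in 2S) add a signal count from the corresponding `NB(b, c/(c+1))`
#' plus the minimum count `k`.
#'
#' @param mu Per-bin background means (length T).
#' @param a Background NB size.
#' @param params Signal parameter list (1S: `b`, `c`, `k`, `piS`;
#'   2S: adds `b1`, `c1`, `b2`, `c2`, `piS1`).
#' @param seed Integer seed.
#' @return List: `Y` (counts) and `truth` (`Z` labels: 0 background,
#'   1/2 signal component; `N`, `S`, the generating `params`, `seed`).
#' @export
simulateCounts <- function(mu, a, params, seed = 1) {
  set.seed(seed)
  T <- length(mu)
  N <- stats::rnbinom(T, size = a, mu = mu)
  Z <- integer(T)
  S <- integer(T)
  sig <- stats::runif(T) < params$piS
  k <- params$k
  if (is.null(params$b1)) {
    Z[sig] <- 1L
    S[sig] <- stats::rnbinom(sum(sig), size = params$b,
                             prob = params$c / (params$c + 1))
  } else {
    comp1 <- sig & (stats::runif(T) < params$piS1)
    comp2 <- sig & !comp1
    Z[comp1] <- 1L; Z[comp2] <- 2L
    S[comp1] <- stats::rnbinom(sum(comp1), size = params$b1,
                               prob = params$c1 / (params$c1 + 1))
    S[comp2] <- stats::rnbinom(sum(comp2), size = params$b2,
                               prob = params$c2 / (params$c2 + 1))
  }
  Y <- N + ifelse(sig, S + k, 0L)
  list(Y = as.integer(Y),
       truth = list(Z = Z, N = N, S = S, params = params, a = a,
                    seed = seed))
}

#' The default parameter-recovery scenario
#'
#' The documented, seeded study condition used throughout the test
#' simulations: T bins, background size `a = 2`, signal proportion
#' `piS = 0.15`, signal `NB(b = 4, c = 0.04)` (mean 100), minimum count
#' `k = 3`; the true background mean follows the input count
#' (`mu_j = X_j` for positive input, 0.5 for zero input).
#'
#' @param seed Integer seed.
#' @param T Number of bins (default 5e4).
#' @param piS,a,b,c,k Generating parameters (defaults as above).
#' @return List: `X`, `mu` (true means), `Y`, `truth`, `params`.
#' @export
recoveryScenario <- function(seed, T = 5e4, piS = 0.15, a = 2, b = 4,
                             c = 0.04, k = 3L) {
  inp <- simulateInput(T, nGenes = max(1, T %/% 25), seed = seed)
  mu <- ifelse(inp$X >= 1, as.numeric(inp$X), 0.5)
  params <- list(b = b, c = c, k = as.integer(k), piS = piS)
  sim <- simulateCounts(mu, a, params, seed = seed + 1000L)
  list(X = inp$X, mu = mu, Y = sim$Y, truth = sim$truth, params = params,
       a = a)
}

#' Goodness-of-fit frequency table
#'
#' Re-simulates IP counts from the fitted parameters (conditioning on
#' the observed per-bin background means) once per signal mode and
#' tabulates the frequency of every count value for the observed data
#' and both simulations.
#'
#' @param Y Observed IP bin counts.
#' @param fit A [MixtureFit-class] object (both mode fits are used when
#'   available; the selected mode's parameters otherwise).
#' @param seed Integer seed for the re-simulation.
#' @return `data.frame` with columns `count` (strictly increasing),
#'   `observed`, `sim1S`, `sim2S`; every frequency column sums to
#'   `length(Y)`.
#' @export
gofTable <- function(Y, fit, seed = 1) {
  mu <- fit@background@mu
  a <- fit@background@a
  getParams <- function(mode) {
    opt <- fit@fits[[mode]]
    if (!is.null(opt)) opt$fit$params
    else if (fit@mode == mode) fit@params
    else NULL
  }
  sim <- function(params, s) {
    if (is.null(params)) return(NULL)
    simulateCounts(mu, a, params, seed = s)$Y
  }
  y1 <- sim(getParams("1S"), seed)
  y2 <- sim(getParams("2S"), seed + 1L)
  counts <- 0:max(Y, y1, y2)
  freq <- function(y) {
    if (is.null(y)) return(rep(NA_integer_, length(counts)))
    tabulate(y + 1L, nbins = length(counts))
  }
  data.frame(count = counts, observed = freq(Y), sim1S = freq(y1),
             sim2S = freq(y2))
}

## ---- fixtures -------------------------------------------------------------

.fixtureGtfLines <- function() {
  att <- function(g, t) sprintf('gene_id "%s"; transcript_id "%s";', g, t)
  row <- function(chr, src, type, s, e, strand, at)
    paste(chr, src, type, s, e, ".", strand, ".", at, sep = "\t")
  c(
    ## gA: two transcripts; union exons 101-300 and 401-700 (+)
    row("chrT1", "test", "exon", 101, 250, "+", att("gA", "gA.t1")),
    row("chrT1", "test", "exon", 401, 700, "+", att("gA", "gA.t1")),
    row("chrT1", "test", "exon", 151, 300, "+", att("gA", "gA.t2")),
    ## gB: minus strand, junction-spanning middle bin
    row("chrT1", "test", "exon", 1201, 1400, "-", att("gB", "gB.t1")),
    row("chrT1", "test", "exon", 1501, 1800, "-", att("gB", "gB.t1")),
    ## gC / gD: antisense pair overlapping on chrT2:401-600
    row("chrT2", "test", "exon", 101, 600, "+", att("gC", "gC.t1")),
    row("chrT2", "test", "exon", 401, 900, "-", att("gD", "gD.t1"))
  )
}

.samHeader <- c("@HD\tVN:1.6\tSO:coordinate",
                "@SQ\tSN:chrT1\tLN:3000",
                "@SQ\tSN:chrT2\tLN:2000")

.samLine <- function(qname, flag, rname, pos, mapq, cigar,
                     rnext = "*", pnext = 0, tlen = 0, seqlen = NULL) {
  seq <- if (is.null(seqlen) || is.na(seqlen)) "*"
         else paste(rep("A", seqlen), collapse = "")
  paste(qname, flag, rname, pos, mapq, cigar, rnext, pnext, tlen, seq, "*",
        sep = "\t")
}

.fixtureSamSE <- function() {
  c(.samHeader,
    .samLine("r5",  4,    "*",     0,    0,  "*"),
    .samLine("r12", 16,   "chrT1", 90,   50, "20M", seqlen = 20),
    .samLine("r1",  0,    "chrT1", 150,  50, "50M", seqlen = 50),
    .samLine("r3",  1024, "chrT1", 150,  50, "50M", seqlen = 50),
    .samLine("r2",  16,   "chrT1", 201,  50, "50M", seqlen = 50),
    .samLine("r6",  0,    "chrT1", 230,  50, "20M150N30M", seqlen = 50),
    .samLine("r13", 0,    "chrT1", 330,  50, "50M", seqlen = 50),
    .samLine("r4",  256,  "chrT1", 450,  50, "50M", seqlen = 50),
    .samLine("r8",  0,    "chrT1", 1350, 50, "30M", seqlen = 30),
    .samLine("r7",  16,   "chrT1", 1621, 50, "50M", seqlen = 50),
    .samLine("r14", 0,    "chrT2", 150,  0,  "50M", seqlen = 50),
    .samLine("r10", 16,   "chrT2", 411,  50, "40M", seqlen = 40),
    .samLine("r9",  0,    "chrT2", 450,  50, "40M", seqlen = 40),
    .samLine("r11", 0,    "chrT2", 550,  50, "10S40M", seqlen = 50))
}

.fixtureSamPE <- function() {
  c(.samHeader,
    .samLine("p1", 99,   "chrT1", 120, 50, "40M", "=", 260, 180, 40),
    .samLine("p6", 1123, "chrT1", 130, 50, "40M", "=", 270, 180, 40),
    .samLine("p3", 73,   "chrT1", 150, 50, "40M", "=", 150, 0,   40),
    .samLine("p1", 147,  "chrT1", 260, 50, "40M", "=", 120, -180, 40),
    .samLine("p6", 1171, "chrT1", 270, 50, "40M", "=", 130, -180, 40),
    .samLine("p2", 163,  "chrT1", 280, 50, "40M", "=", 420, 180,  40),
    .samLine("p2", 83,   "chrT1", 420, 50, "40M", "=", 280, -180, 40),
    .samLine("p4", 99,   "chrT2", 430, 50, "40M", "=", 520, 130,  40),
    .samLine("p5", 83,   "chrT2", 481, 50, "40M", "=", 380, -140, 40),
    .samLine("p4", 147,  "chrT2", 520, 50, "40M", "=", 430, -130, 40),
    .samLine("p5", 163,  "chrT2", 380, 50, "40M", "=", 481, 140,  40))
}

.fixtureInputSE <- function() {
  ## two plain reads inside each gene so every gene passes the TPM filter
  c(.samHeader,
    .samLine("i1", 0,  "chrT1", 110,  50, "20M", seqlen = 20),
    .samLine("i2", 0,  "chrT1", 450,  50, "20M", seqlen = 20),
    .samLine("i3", 16, "chrT1", 1231, 50, "20M", seqlen = 20),
    .samLine("i4", 16, "chrT1", 1681, 50, "20M", seqlen = 20),
    .samLine("i5", 0,  "chrT2", 120,  50, "20M", seqlen = 20),
    .samLine("i6", 0,  "chrT2", 320,  50, "20M", seqlen = 20),
    .samLine("i7", 16, "chrT2", 731,  50, "20M", seqlen = 20),
    .samLine("i8", 16, "chrT2", 811,  50, "20M", seqlen = 20))
}

## hand-computed expected IP bin counts for every protocol combination
.fixtureManifest <- function() {
  bins <- c("gA.1", "gA.2", "gA.3", "gB.1", "gB.2", "gB.3",
            "gC.1", "gC.2", "gC.3", "gD.1", "gD.2", "gD.3")
  man <- rbind(
    data.frame(protocol = "single", strandedness = "none", bin = bins,
               count = c(4, 0, 0, 1, 1, 0, 0, 2, 1, 0, 1, 2)),
    data.frame(protocol = "single", strandedness = "forward", bin = bins,
               count = c(2, 0, 0, 1, 0, 0, 0, 1, 1, 0, 0, 1)),
    data.frame(protocol = "single", strandedness = "reverse", bin = bins,
               count = c(2, 0, 0, 0, 1, 0, 0, 1, 0, 0, 1, 1)),
    data.frame(protocol = "paired", strandedness = "none", bin = bins,
               count = c(1, 1, 0, 0, 0, 0, 0, 1, 1, 0, 1, 1)),
    data.frame(protocol = "paired", strandedness = "forward", bin = bins,
               count = c(1, 0, 0, 0, 0, 0, 0, 1, 0, 0, 1, 0)),
    data.frame(protocol = "paired", strandedness = "reverse", bin = bins,
               count = c(0, 1, 0, 0, 0, 0, 0, 0, 1, 0, 0, 1))
  )
  man
}

#' Write the miniature GTF/SAM counting fixtures
#'
#' A two-chromosome toy genome with four genes: a plus-strand gene with
#' two transcripts (exercising the exon union), a minus-strand gene with
#' a junction-spanning bin, and an overlapping antisense gene pair. The
#' single-end and paired-end IP SAM files cover duplicate-marked,
#' secondary, unmapped, soft-clipped, junction-spanning and
#' low-mapping-quality records on both strands. The accompanying
#' manifest holds the hand-computed expected IP bin counts for each of
#' the six protocol combinations (bin size 200).
#'
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named list of the written paths (`gtf`, `ipSe`,
#'   `ipPe`, `inputSe`, `manifest`).
#' @export
makeFixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(gtf = file.path(dir, "toy.gtf"),
                ipSe = file.path(dir, "ip_se.sam"),
                ipPe = file.path(dir, "ip_pe.sam"),
                inputSe = file.path(dir, "input_se.sam"),
                manifest = file.path(dir, "manifest.tsv"))
  writeLines(.fixtureGtfLines(), paths$gtf)
  writeLines(.fixtureSamSE(), paths$ipSe)
  writeLines(.fixtureSamPE(), paths$ipPe)
  writeLines(.fixtureInputSE(), paths$inputSe)
  utils::write.table(.fixtureManifest(), paths$manifest, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Write a synthetic MeRIP-Seq dataset (GTF + IP/input SAM)
#'
#' Generates a transcriptome of single-exon genes on one toy chromosome,
#' draws input bin counts from the expression model of
#' [simulateInput()], derives the true background means from the input
#' counts via a log-linear law, draws IP counts from the mixture model,
#' and materializes each count as a single-base read (5' position
#' uniform within the bin, read strand equal to the gene strand) in
#' coordinate-sorted SAM files. Intended for end-to-end pipeline runs at
#' desk scale.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param nGenes Number of genes (default 20; two are left unexpressed).
#' @param geneLength Exonic length per gene (default 1000).
#' @param binSize Bin size the gene length is a multiple of (default 200).
#' @param piS,a,b,c,k Mixture parameters of the IP counts (defaults:
#'   0.15, 2, 3, 0.1, 3 - signal mean 30, sized for small files).
#' @return Invisibly, list of paths (`gtf`, `ip`, `input`) plus the
#'   generating truth (`X`, `Y`, `Z`, `geneId`).
#' @export
writeSyntheticDataset <- function(dir, seed = 1, nGenes = 20,
                                  geneLength = 1000, binSize = 200,
                                  piS = 0.15, a = 2, b = 3, c = 0.1,
                                  k = 3L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  binsPerGene <- geneLength %/% binSize
  T <- nGenes * binsPerGene
  inp <- simulateInput(T, nGenes, zeroGeneFrac = 2 / nGenes, seed = seed)
  mu <- ifelse(inp$X >= 1, pmax(as.numeric(inp$X), 0.5), 0.5)
  sim <- simulateCounts(mu, a, list(b = b, c = c, k = as.integer(k),
                                    piS = piS), seed = seed + 1L)
  Y <- sim$Y
  gap <- 500L
  starts <- 1000L + (seq_len(nGenes) - 1L) * (geneLength + gap)
  strands <- rep(c("+", "-"), length.out = nGenes)
  gids <- sprintf("g%03d", seq_len(nGenes))
  chrLen <- max(starts) + geneLength + 1000L
  gtf <- vapply(seq_len(nGenes), function(g) {
    paste("chrS1", "sim", "exon", starts[g], starts[g] + geneLength - 1L,
          ".", strands[g], ".",
          sprintf('gene_id "%s"; transcript_id "%s.t1";', gids[g], gids[g]),
          sep = "\t")
  }, "")
  writeLines(gtf, file.path(dir, "genes.gtf"))
  set.seed(seed + 2L)
  makeReads <- function(counts, prefix) {
    pos <- integer(0); strand <- character(0)
    for (j in seq_len(T)) {
      if (counts[j] == 0) next
      g <- (j - 1L) %/% binsPerGene + 1L
      bin <- (j - 1L) %% binsPerGene
      txOff <- bin * binSize + sample.int(binSize, counts[j],
                                          replace = TRUE) - 1L
      gpos <- if (strands[g] == "-") {
        starts[g] + geneLength - 1L - txOff
      } else {
        starts[g] + txOff
      }
      pos <- c(pos, gpos)
      strand <- c(strand, rep(strands[g], counts[j]))
    }
    o <- order(pos)
    pos <- pos[o]; strand <- strand[o]
    lines <- c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:chrS1\tLN:%d", chrLen),
               vapply(seq_along(pos), function(i) {
                 .samLine(sprintf("%s%06d", prefix, i),
                          if (strand[i] == "-") 16L else 0L,
                          "chrS1", pos[i], 50, "1M", seqlen = 1)
               }, ""))
    lines
  }
  ## per-bin geneId follows the scaffold order of simulateInput (sorted ids)
  writeLines(makeReads(inp$X, "in"), file.path(dir, "input.sam"))
  writeLines(makeReads(Y, "ip"), file.path(dir, "ip.sam"))
  invisible(list(gtf = file.path(dir, "genes.gtf"),
                 ip = file.path(dir, "ip.sam"),
                 input = file.path(dir, "input.sam"),
                 X = inp$X, Y = Y, Z = sim$truth$Z,
                 geneId = rep(gids, each = binsPerGene)))
}
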