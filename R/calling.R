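#' Posterior probability of background membership per bin
#'
#' For 1S: `(1 - piS) p0 / [(1 - piS) p0 + piS p1]`; for 2S the signal
#' term is `piS [piS1 p1 + (1 - piS1) p2]` with the two distinct signal
#' densities. A bin where the total density underflows to zero is
#' assigned posterior-null 1 with a warning.
#'
#' @param Y IP bin counts.
#' @param fit A [MixtureFit-class] object.
#' @return A `data.frame` with `postNull`, `p0`, `p1` (and `p2` for 2S).
#' @export
posteriorNull <- function(Y, fit) {
  bg <- fit@background
  mu <- bg@mu
  stopifnot(length(Y) == length(mu))
  a <- bg@a
  p <- fit@params
  cache <- .mixCache(Y, mu, a)
  p0 <- cache$p0
  if (fit@mode == "1S") {
    p1 <- .signalDens(cache, p$b, p$c, p$k)
    sig <- p1
    out <- data.frame(p0 = p0, p1 = p1)
  } else {
    p1 <- .signalDens(cache, p$b1, p$c1, p$k)
    p2 <- .signalDens(cache, p$b2, p$c2, p$k)
    sig <- p$piS1 * p1 + (1 - p$piS1) * p2
    out <- data.frame(p0 = p0, p1 = p1, p2 = p2)
  }
  num <- (1 - p$piS) * p0
  den <- num + p$piS * sig
  post <- rep(1, length(Y))
  ok <- den > 0
  if (!all(ok))
    warning(sum(!ok), " bin(s) with zero total density; posterior-null ",
            "set to 1")
  post[ok] <- num[ok] / den[ok]
  out$postNull <- post
  out
}

#' Direct posterior-probability FDR selection
#'
#' Bins are ranked by ascending posterior-null; the largest prefix whose
#' running mean posterior-null (the estimated FDR of the called set) is
#' at most `cutoff` is selected. Tied posterior values enter or leave
#' together: the prefix boundary never splits a tie group.
#'
#' @param postNull Posterior-null probabilities.
#' @param cutoff FDR cutoff in (0, 1); default 0.05.
#' @return Integer indices of the selected bins (possibly empty), in
#'   ascending posterior order.
#' @export
fdrSelect <- function(postNull, cutoff = 0.05) {
  stopifnot(cutoff > 0, cutoff < 1)
  n <- length(postNull)
  if (n == 0) return(integer())
  ord <- order(postNull)
  ps <- postNull[ord]
  runMean <- cumsum(ps) / seq_len(n)
  groupEnd <- c(ps[-1] != ps[-n], TRUE)
  okEnds <- which(groupEnd & runMean <= cutoff)
  if (length(okEnds) == 0) return(integer())
  ord[seq_len(max(okEnds))]
}

#' Merge significant bins into enriched regions
#'
#' Within each gene, selected bins that are adjacent in transcript
#' coordinates (one bin's `txEnd` equals the next bin's `txStart`) are
#' merged; bins of different genes never merge. The region score is the
#' maximum IP bin count among the merged bins; genomic blocks are
#' concatenated and re-merged where contiguous.
#'
#' @param cm A [BinCounts-class] object.
#' @param sigIdx Indices of the significant bins.
#' @param postNull Per-bin posterior-null probabilities.
#' @return A [GenomicRanges::GRanges] of regions with metadata columns
#'   `name`, `geneId`, `score`, `nBins`, `txStart`, `txEnd`,
#'   `meanPostNull`, `minPostNull`, and a `blocks` `GRangesList` column.
#' @export
mergeBins <- function(cm, sigIdx, postNull) {
  empty <- GenomicRanges::GRanges()
  S4Vectors::mcols(empty) <- S4Vectors::DataFrame(
    name = character(), geneId = character(), score = integer(),
    nBins = integer(), txStart = integer(), txEnd = integer(),
    meanPostNull = numeric(), minPostNull = numeric())
  if (length(sigIdx) == 0) return(empty)
  bd <- SummarizedExperiment::rowData(cm)
  blocks <- SummarizedExperiment::rowRanges(cm)
  Y <- ipCounts(cm)
  sigIdx <- sigIdx[order(bd$geneId[sigIdx], bd$txStart[sigIdx])]
  gene <- bd$geneId[sigIdx]
  txS <- bd$txStart[sigIdx]
  txE <- bd$txEnd[sigIdx]
  newRegion <- c(TRUE, gene[-1] != gene[-length(gene)] |
                       txS[-1] != txE[-length(txE)])
  regId <- cumsum(newRegion)
  regs <- lapply(split(seq_along(sigIdx), regId), function(ii) {
    idx <- sigIdx[ii]
    blk <- GenomicRanges::reduce(unlist(blocks[idx], use.names = FALSE))
    g <- bd$geneId[idx[1]]
    GenomicRanges::GRanges(
      bd$chrom[idx[1]],
      IRanges::IRanges(min(GenomicRanges::start(blk)),
                       max(GenomicRanges::end(blk))),
      strand = bd$geneStrand[idx[1]],
      geneId = g,
      score = max(Y[idx]),
      nBins = length(idx),
      txStart = min(bd$txStart[idx]),
      txEnd = max(bd$txEnd[idx]),
      meanPostNull = mean(postNull[idx]),
      minPostNull = min(postNull[idx]),
      blocks = GenomicRanges::GRangesList(blk)
    )
  })
  out <- unlist(GenomicRanges::GRangesList(lapply(regs, function(r) {
    S4Vectors::mcols(r)$blocks <- NULL; r
  })))
  S4Vectors::mcols(out)$blocks <- GenomicRanges::GRangesList(
    lapply(regs, function(r) S4Vectors::mcols(r)$blocks[[1]]))
  ## region index within gene, in transcript order
  ord <- order(S4Vectors::mcols(out)$geneId, S4Vectors::mcols(out)$txStart)
  out <- out[ord]
  gid <- S4Vectors::mcols(out)$geneId
  idxInGene <- stats::ave(seq_along(gid), gid, FUN = seq_along)
  S4Vectors::mcols(out)$name <- paste0(gid, ":", idxInGene)
  out
}

#' Call enriched regions from a fitted mixture
#'
#' Computes posterior-null probabilities, applies direct-posterior FDR
#' selection at the bin level, merges adjacent significant bins into
#' regions, and optionally filters on the region score.
#'
#' @param cm A [BinCounts-class] object.
#' @param fit A [MixtureFit-class] object.
#' @param fdrCutoff FDR cutoff (default 0.05).
#' @param minScore Optional minimum region score (max IP bin count);
#'   regions below are dropped.
#' @param dedup Collapse regions identical in (chrom, start, end, strand,
#'   blocks) that arise from overlapping same-strand genes.
#' @return Regions `GRanges` as from [mergeBins()]; `metadata()` carries
#'   `estimatedFdr` (mean posterior-null of the selected bin set),
#'   `nSelectedBins`, and the per-bin `postNull` vector.
#' @export
callRegions <- function(cm, fit, fdrCutoff = 0.05, minScore = NULL,
                        dedup = FALSE) {
  pt <- posteriorNull(ipCounts(cm), fit)
  sig <- fdrSelect(pt$postNull, fdrCutoff)
  regions <- mergeBins(cm, sig, pt$postNull)
  est <- if (length(sig)) mean(pt$postNull[sig]) else NA_real_
  if (!is.null(minScore))
    regions <- regions[S4Vectors::mcols(regions)$score >= minScore]
  if (dedup && length(regions) > 1) {
    key <- paste(GenomicRanges::seqnames(regions),
                 GenomicRanges::start(regions),
                 GenomicRanges::end(regions),
                 GenomicRanges::strand(regions),
                 vapply(S4Vectors::mcols(regions)$blocks, function(b)
                   paste(GenomicRanges::start(b), GenomicRanges::width(b),
                         collapse = ";"), ""))
    regions <- regions[!duplicated(key)]
  }
  S4Vectors::metadata(regions) <- list(estimatedFdr = est,
                                       nSelectedBins = length(sig),
                                       postNull = pt$postNull)
  regions
}

#' Write enriched regions as BED12
#'
#' One record per region: `chromStart` is 0-based, blocks carry the
#' junction structure, the score is the raw maximum IP bin count (use
#' `clampScore = TRUE` for the BED-nominal 0-1000 range), `thickStart` /
#' `thickEnd` span the region, `itemRgb` is 0. Records are sorted by
#' (chrom, chromStart).
#'
#' @param regions Regions from [callRegions()].
#' @param path Output file.
#' @param clampScore Clamp scores into `[0, 1000]` (default `FALSE`).
#' @return Invisibly, the path.
#' @export
writeBed12 <- function(regions, path, clampScore = FALSE) {
  if (length(regions) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  o <- order(as.character(GenomicRanges::seqnames(regions)),
             GenomicRanges::start(regions))
  regions <- regions[o]
  mc <- S4Vectors::mcols(regions)
  chrom <- as.character(GenomicRanges::seqnames(regions))
  chromStart <- GenomicRanges::start(regions) - 1L
  chromEnd <- GenomicRanges::end(regions)
  score <- mc$score
  if (clampScore) score <- pmin(pmax(score, 0L), 1000L)
  lines <- vapply(seq_along(regions), function(i) {
    blk <- mc$blocks[[i]]
    bs <- GenomicRanges::start(blk) - 1L - chromStart[i]
    bw <- GenomicRanges::width(blk)
    paste(chrom[i], chromStart[i], chromEnd[i], mc$name[i], score[i],
          as.character(GenomicRanges::strand(regions))[i],
          chromStart[i], chromEnd[i], 0L, length(blk),
          paste0(paste(bw, collapse = ","), ","),
          paste0(paste(bs, collapse = ","), ","),
          sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED12 file written by [writeBed12()]
#'
#' @param path BED12 file.
#' @return A `GRanges` with `name`, `score` and a `blocks` column.
#' @export
readBed12 <- function(path) {
  tb <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = c("character", "integer", "integer",
                                         "character", "integer", "character",
                                         "integer", "integer", "character",
                                         "integer", "character", "character"))
  gr <- GenomicRanges::GRanges(tb$V1,
                               IRanges::IRanges(tb$V2 + 1L, tb$V3),
                               strand = tb$V6, name = tb$V4, score = tb$V5)
  blocks <- lapply(seq_len(nrow(tb)), function(i) {
    bw <- as.integer(strsplit(tb$V11[i], ",")[[1]])
    bs <- as.integer(strsplit(tb$V12[i], ",")[[1]])
    GenomicRanges::GRanges(tb$V1[i],
                           IRanges::IRanges(tb$V2[i] + bs + 1L, width = bw),
                           strand = tb$V6[i])
  })
  S4Vectors::mcols(gr)$blocks <- GenomicRanges::GRangesList(blocks)
  gr
}
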