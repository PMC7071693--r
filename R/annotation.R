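#' Read union-exon gene models from a GTF file
#'
#' Exon features are grouped by `gene_id` and, per gene, the union of the
#' exons of all transcripts is taken (overlapping exons merged), yielding a
#' single linear concatenated-exon coordinate system per gene. GTF
#' coordinates are 1-based inclusive and are kept as such inside
#' `GRanges`.
#'
#' @param path Path to a GTF file.
#' @return A named [GenomicRanges::GRangesList], one element per gene,
#'   holding the reduced (sorted, non-overlapping) exons. `mcols()` carries
#'   `exonicLength`.
#' @export
readGeneModels <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) stop("failed to parse GTF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  ex <- gr[!is.na(gr$type) & gr$type == "exon"]
  if (length(ex) == 0)
    stop("GTF contains no exon features: ", path, call. = FALSE)
  if (is.null(ex$gene_id) || anyNA(ex$gene_id) || any(ex$gene_id == ""))
    stop("exon feature without gene_id attribute in ", path, call. = FALSE)
  geneModelsFromExons(ex, ex$gene_id)
}

#' Build gene models from an exon GRanges
#'
#' Workhorse behind [readGeneModels()], exposed so that programmatically
#' constructed annotations (e.g. from the simulator) can skip the GTF
#' round-trip.
#'
#' @param exons A `GRanges` of exons (1-based inclusive, stranded).
#' @param geneIds Character vector parallel to `exons`.
#' @return A named `GRangesList` of reduced exons with `exonicLength` in
#'   `mcols()`.
#' @export
geneModelsFromExons <- function(exons, geneIds) {
  grl <- GenomicRanges::reduce(S4Vectors::split(exons, geneIds))
  # a gene model must live on one chromosome and one strand
  nchr <- vapply(GenomicRanges::seqnames(grl), function(x) length(unique(x)), 1L)
  nstr <- vapply(GenomicRanges::strand(grl), function(x) length(unique(x)), 1L)
  bad <- nchr > 1L | nstr > 1L
  if (any(bad)) {
    warning("dropping ", sum(bad),
            " gene(s) with exons on multiple chromosomes/strands")
    grl <- grl[!bad]
  }
  S4Vectors::mcols(grl)$exonicLength <- sum(GenomicRanges::width(grl))
  if (any(S4Vectors::mcols(grl)$exonicLength == 0))
    stop("gene model with zero exonic length")
  grl
}

#' Transcripts-per-million from gene-level counts
#'
#' `TPM_g = (count_g / length_g) / sum_h(count_h / length_h) * 1e6`, with
#' `length_g` the union-exon length. When every count is zero all TPM are
#' zero (with a warning) rather than dividing by zero.
#'
#' @param geneCounts Named numeric vector of per-gene read counts.
#' @param genes Gene models as returned by [readGeneModels()]; only genes
#'   present here are scored.
#' @return Named numeric vector of TPM values, in the order of `genes`.
#' @export
computeTpm <- function(geneCounts, genes) {
  len <- S4Vectors::mcols(genes)$exonicLength
  cnt <- geneCounts[names(genes)]
  cnt[is.na(cnt)] <- 0
  if (any(cnt < 0)) stop("negative gene counts")
  rate <- cnt / len
  tot <- sum(rate)
  if (tot == 0) {
    warning("all gene counts are zero; returning all-zero TPM")
    tpm <- rate
  } else {
    tpm <- rate / tot * 1e6
  }
  names(tpm) <- names(genes)
  tpm
}

#' Filter gene models by expression
#'
#' @param genes A `GRangesList` of gene models.
#' @param tpm Named TPM vector covering every gene in `genes`.
#' @param threshold Minimum TPM (inclusive); default 0.5.
#' @return The expressed subset of `genes`, order preserved.
#' @export
filterExpressed <- function(genes, tpm, threshold = 0.5) {
  if (!all(names(genes) %in% names(tpm)))
    stop("tpm must be defined for every gene")
  genes[tpm[names(genes)] >= threshold]
}

## Exons of one gene ordered 5'->3' on the gene's strand, with the
## cumulative transcript offset at which each exon starts.
.txExonTable <- function(exons) {
  st <- GenomicRanges::start(exons)
  en <- GenomicRanges::end(exons)
  strand <- as.character(GenomicRanges::strand(exons)[1])
  ord <- if (strand == "-") order(st, decreasing = TRUE) else order(st)
  st <- st[ord]; en <- en[ord]
  w <- en - st + 1L
  list(start = st, end = en, width = w,
       cum = cumsum(c(0L, w))[seq_along(w)],
       strand = strand,
       chrom = as.character(GenomicRanges::seqnames(exons)[1]),
       total = sum(w))
}

## Map a half-open transcript interval [txStart, txEnd) (0-based offsets in
## concatenated-exon space) to genomic blocks (1-based inclusive GRanges).
.txIntervalToBlocks <- function(tab, txStart, txEnd) {
  hit <- which(tab$cum < txEnd & tab$cum + tab$width > txStart)
  gs <- ge <- integer(length(hit))
  for (i in seq_along(hit)) {
    e <- hit[i]
    ls <- max(txStart, tab$cum[e]) - tab$cum[e]  # local offsets within exon
    le <- min(txEnd, tab$cum[e] + tab$width[e]) - tab$cum[e]
    if (tab$strand == "-") {
      gs[i] <- tab$end[e] - le + 1L
      ge[i] <- tab$end[e] - ls
    } else {
      gs[i] <- tab$start[e] + ls
      ge[i] <- tab$start[e] + le - 1L
    }
  }
  gr <- GenomicRanges::GRanges(tab$chrom, IRanges::IRanges(gs, ge),
                               strand = tab$strand)
  sort(gr)
}

#' Map transcript offsets of a gene to genomic positions
#'
#' Offset 0 is the 5'-most exonic base of the gene (the genomically
#' rightmost base for minus-strand genes).
#'
#' @param exons Reduced exons of one gene (`GRanges`).
#' @param txPos Integer vector of 0-based transcript offsets.
#' @return Integer vector of genomic positions (1-based).
#' @export
txToGenome <- function(exons, txPos) {
  tab <- .txExonTable(exons)
  if (any(txPos < 0 | txPos >= tab$total)) stop("transcript offset out of range")
  e <- findInterval(txPos, tab$cum)
  local <- txPos - tab$cum[e]
  if (tab$strand == "-") tab$end[e] - local else tab$start[e] + local
}

#' Map genomic positions to transcript offsets of a gene
#'
#' Inverse of [txToGenome()]; positions outside the gene's exons yield
#' `NA`.
#'
#' @param exons Reduced exons of one gene (`GRanges`).
#' @param genomePos Integer vector of genomic positions (1-based).
#' @return Integer vector of 0-based transcript offsets (`NA` if intronic
#'   or outside the gene).
#' @export
genomeToTx <- function(exons, genomePos) {
  tab <- .txExonTable(exons)
  out <- rep(NA_integer_, length(genomePos))
  for (e in seq_along(tab$start)) {
    inside <- genomePos >= tab$start[e] & genomePos <= tab$end[e]
    local <- if (tab$strand == "-") tab$end[e] - genomePos[inside]
             else genomePos[inside] - tab$start[e]
    out[inside] <- tab$cum[e] + local
  }
  out
}

#' Tile expressed genes with fixed-size transcriptome bins
#'
#' Each gene's concatenated exon space `[0, exonicLength)` is tiled 5'->3'
#' with `binSize`-base bins (the last bin may be shorter but is kept as
#' long as it has at least one base). Every bin is back-projected to its
#' genomic blocks; a bin spanning a splice junction yields two or more
#' blocks. Bins are strictly per-gene: overlapping genes keep separate,
#' possibly overlapping, bins.
#'
#' @param genes A `GRangesList` of gene models (e.g. from
#'   [readGeneModels()] after [filterExpressed()]).
#' @param binSize Bin width in bases (default 200).
#' @return A [TranscriptomeBins-class] object.
#' @export
makeBins <- function(genes, binSize = 200L) {
  binSize <- as.integer(binSize)
  if (binSize < 1L) stop("binSize must be >= 1")
  if (length(genes) == 0) stop("no genes to bin")
  allBlocks <- vector("list", 0L)
  rows <- vector("list", length(genes))
  for (g in seq_along(genes)) {
    exons <- genes[[g]]
    if (length(exons) == 0) stop("gene with empty exon list: ", names(genes)[g])
    tab <- .txExonTable(exons)
    starts <- seq.int(0L, tab$total - 1L, by = binSize)
    ends <- pmin(starts + binSize, tab$total)
    blk <- vector("list", length(starts))
    for (i in seq_along(starts))
      blk[[i]] <- .txIntervalToBlocks(tab, starts[i], ends[i])
    allBlocks <- c(allBlocks, blk)
    rows[[g]] <- S4Vectors::DataFrame(
      geneId = names(genes)[g],
      index = seq_along(starts),
      txStart = starts, txEnd = ends,
      chrom = tab$chrom, strand = tab$strand
    )
  }
  bd <- do.call(rbind, rows)
  grl <- GenomicRanges::GRangesList(allBlocks)
  names(grl) <- paste0(bd$geneId, ".", bd$index)
  new("TranscriptomeBins", blocks = grl, binData = bd, binSize = binSize)
}
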