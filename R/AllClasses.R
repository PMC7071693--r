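#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames rowRanges rowData
#' @importFrom IRanges IRanges
#' @import GenomicRanges
NULL

#' TranscriptomeBins: fixed-size bins in concatenated-exon coordinates
#'
#' Each bin lives in the transcript coordinate system of one gene (the
#' 5'-to-3' concatenation of the gene's union exons) and carries its
#' back-projection to genomic blocks, so that a bin spanning a splice
#' junction maps to two or more genomic intervals.
#'
#' @slot blocks A [GenomicRanges::GRangesList] with one element per bin;
#'   each element holds the genomic blocks of that bin (strand-aware,
#'   sorted by genomic start).
#' @slot binData A [S4Vectors::DataFrame] with one row per bin: `geneId`,
#'   `index` (ordinal within gene, 1-based), `txStart`, `txEnd` (0-based
#'   half-open offsets in concatenated-exon coordinates), `chrom`,
#'   `strand`.
#' @slot binSize Integer scalar, the tiling width in bases (last bin of a
#'   gene may be shorter).
#'
#' @seealso [makeBins()], [txToGenome()]
#' @export
setClass("TranscriptomeBins",
  representation(
    blocks  = "GRangesList",
    binData = "DataFrame",
    binSize = "integer"
  )
)

setValidity("TranscriptomeBins", function(object) {
  msg <- character()
  bd <- object@binData
  if (length(object@blocks) != nrow(bd))
    msg <- c(msg, "blocks and binData must have the same length")
  need <- c("geneId", "index", "txStart", "txEnd", "chrom", "strand")
  if (!all(need %in% colnames(bd)))
    msg <- c(msg, paste("binData must have columns:", paste(need, collapse = ", ")))
  if (length(msg) == 0 && nrow(bd) > 0) {
    w <- sum(GenomicRanges::width(object@blocks))
    if (!all(w == bd$txEnd - bd$txStart))
      msg <- c(msg, "sum of block widths must equal txEnd - txStart for every bin")
    if (any(bd$txEnd - bd$txStart > object@binSize))
      msg <- c(msg, "no bin may be wider than binSize")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn TranscriptomeBins-class Number of bins.
#' @param x,object A `TranscriptomeBins` object.
#' @export
setMethod("length", "TranscriptomeBins", function(x) nrow(x@binData))

#' @describeIn TranscriptomeBins-class Per-bin metadata (`DataFrame`).
#' @export
binData <- function(x) x@binData

#' @describeIn TranscriptomeBins-class Genomic blocks (`GRangesList`).
#' @export
binBlocks <- function(x) x@blocks

setMethod("show", "TranscriptomeBins", function(object) {
  cat("TranscriptomeBins with", length(object), "bins over",
      length(unique(object@binData$geneId)), "genes; binSize =",
      object@binSize, "\n")
})

#' BinCounts: IP and input counts over transcriptome bins
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] whose rows are
#' transcriptome bins (rowRanges holds the genomic blocks of each bin as a
#' `GRangesList`) and whose single assay `"counts"` has two columns, `ip`
#' and `input`. Per-bin transcript coordinates are kept in `rowData`.
#'
#' @seealso [countBins()], [ipCounts()], [inputCounts()]
#' @export
setClass("BinCounts", contains = "RangedSummarizedExperiment")

setValidity("BinCounts", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  if (!all(c("ip", "input") %in% colnames(object)))
    msg <- c(msg, "columns 'ip' and 'input' are required")
  if (length(msg) == 0) {
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (any(cnt < 0) || any(cnt != floor(cnt)))
      msg <- c(msg, "counts must be non-negative integers")
  }
  if (length(msg)) msg else TRUE
})

#' IP counts of a BinCounts object
#' @param object A [BinCounts-class] object.
#' @return Integer vector of per-bin IP counts.
#' @export
ipCounts <- function(object) {
  SummarizedExperiment::assay(object, "counts")[, "ip"]
}

#' Input counts of a BinCounts object
#' @param object A [BinCounts-class] object.
#' @return Integer vector of per-bin input counts.
#' @export
inputCounts <- function(object) {
  SummarizedExperiment::assay(object, "counts")[, "input"]
}

#' BackgroundFit: the estimated negative-binomial background component
#'
#' Holds the NB size parameter `a`, the per-bin background means `mu`
#' (driven solely by the input bin count through a log-log regression),
#' the kind of regression selected by BIC and its coefficients, plus the
#' per-group diagnostics the fit was derived from.
#'
#' @slot kind `"rlm"` or `"gam"`.
#' @slot coefficients Named list: for `rlm`, `beta0` and `beta1`; for
#'   `gam`, `beta0` and the spline coefficient vector `beta` (length 9 by
#'   default).
#' @slot a NB size parameter (positive).
#' @slot mu Per-bin background means, all `>= muFloor`.
#' @slot regressionBic BIC of the selected regression.
#' @slot groups `data.frame` of per-input-count group statistics
#'   (`x`, `n`, `mu`, `var`, `aGroup`, `fitted`).
#' @slot zeroMu Background mean assigned to bins with input count 0.
#' @slot model The fitted regression object (used for prediction).
#' @export
setClass("BackgroundFit",
  representation(
    kind          = "character",
    coefficients  = "list",
    a             = "numeric",
    mu            = "numeric",
    regressionBic = "numeric",
    groups        = "data.frame",
    zeroMu        = "numeric",
    model         = "ANY"
  )
)

setValidity("BackgroundFit", function(object) {
  msg <- character()
  if (!object@kind %in% c("rlm", "gam", "constant"))
    msg <- c(msg, "kind must be 'rlm', 'gam' or 'constant'")
  if (length(object@a) != 1 || object@a <= 0)
    msg <- c(msg, "a must be a positive scalar")
  if (length(object@mu) && any(object@mu <= 0))
    msg <- c(msg, "all background means must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BackgroundFit", function(object) {
  cat("BackgroundFit (", object@kind, ")\n", sep = "")
  cat("  size a =", signif(object@a, 4),
      "| bins =", length(object@mu),
      "| regression BIC =", signif(object@regressionBic, 6), "\n")
})

#' MixtureFit: the fitted mixture model for IP bin counts
#'
#' The selected model for the IP counts: a background NB plus, with
#' probability `piS`, a signal component that is a convolution of the
#' background NB with one (1S mode) or a mixture of two (2S mode) signal
#' NBs, offset by the minimum signal count `k`.
#'
#' @slot background A [BackgroundFit-class].
#' @slot mode `"1S"` or `"2S"`.
#' @slot params Named list of signal parameters. 1S: `b`, `c`, `k`, `piS`.
#'   2S: `b1`, `c1`, `b2`, `c2`, `piS1`, `k`, `piS`.
#' @slot loglik Observed-data log-likelihood of the selected fit.
#' @slot bic1S,bic2S BIC of the best fit per mode (over the k grid).
#' @slot optimK Optimized minimum signal count of the selected mode.
#' @slot r Number of signal-side parameters charged in the BIC of the
#'   selected mode (4 for 1S, 7 for 2S).
#' @slot fits Internal list with the per-mode fits (EM traces, per-k BIC
#'   tables).
#' @export
setClass("MixtureFit",
  representation(
    background = "BackgroundFit",
    mode       = "character",
    params     = "list",
    loglik     = "numeric",
    bic1S      = "numeric",
    bic2S      = "numeric",
    optimK     = "integer",
    r          = "integer",
    fits       = "list"
  )
)

setValidity("MixtureFit", function(object) {
  msg <- character()
  if (!object@mode %in% c("1S", "2S"))
    msg <- c(msg, "mode must be '1S' or '2S'")
  if (!is.finite(object@loglik))
    msg <- c(msg, "loglik must be finite")
  p <- object@params
  if (!is.null(p$piS) && (p$piS < 0 || p$piS > 1))
    msg <- c(msg, "piS must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MixtureFit", function(object) {
  cat("MixtureFit, mode ", object@mode, "\n", sep = "")
  cat("  piS =", signif(object@params$piS, 4),
      "| k =", object@optimK,
      "| BIC 1S =", signif(object@bic1S, 6),
      "| BIC 2S =", signif(object@bic2S, 6), "\n")
})

#' Signal proportion of a fitted mixture
#' @param fit A [MixtureFit-class].
#' @return The estimated signal proportion in `[0, 1]`.
#' @export
signalProportion <- function(fit) fit@params$piS
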