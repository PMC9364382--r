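#' Construct a ChromatinExperiment
#'
#' Assemble per-feature binned count matrices into a [ChromatinExperiment].
#' All matrices must share the same dimensions N x L, where N is the number
#' of loci and L = windowSize / binSize the number of bins.
#'
#' @param counts Named list of M numeric matrices (N x L) of non-negative
#'   integral counts; names are the chromatin feature names. A single matrix
#'   is accepted and wrapped.
#' @param binSize Bin width in bp.
#' @param windowSize Window width in bp; defaults to binSize * ncol.
#' @param rowRanges Optional [GenomicRanges::GRanges] of length N with the
#'   locus coordinates (e.g. from [readBedLoci()]); bookkeeping only.
#' @param lociIds Optional character vector of locus identifiers; defaults to
#'   the rownames of the first matrix, if any.
#'
#' @return A [ChromatinExperiment].
#' @examples
#' x <- matrix(rpois(20, 2), nrow = 4)
#' ce <- ChromatinExperiment(list(H3K4me1 = x), binSize = 40)
#' nLoci(ce); nBins(ce)
#' @export
ChromatinExperiment <- function(counts, binSize, windowSize = NULL,
                                rowRanges = NULL, lociIds = NULL) {
  if (is.matrix(counts)) counts <- list(feature1 = counts)
  if (!is.list(counts) || length(counts) == 0L) {
    stop("'counts' must be a non-empty (named) list of matrices")
  }
  if (is.null(names(counts))) {
    names(counts) <- paste0("feature", seq_along(counts))
  }
  dims <- lapply(counts, dim)
  if (any(vapply(dims, is.null, logical(1))) ||
      length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L) {
    stop("all feature count matrices must share identical dimensions N x L")
  }
  counts <- lapply(counts, function(x) {
    storage.mode(x) <- "double"
    x
  })
  L <- ncol(counts[[1]])
  binSize <- as.integer(binSize)
  if (is.null(windowSize)) windowSize <- binSize * L
  windowSize <- as.integer(windowSize)
  if (is.null(lociIds)) lociIds <- rownames(counts[[1]])
  if (!is.null(lociIds)) {
    counts <- lapply(counts, function(x) {
      rownames(x) <- lociIds
      x
    })
  }
  if (is.null(rowRanges)) {
    se <- SummarizedExperiment::SummarizedExperiment(assays = counts)
  } else {
    se <- SummarizedExperiment::SummarizedExperiment(assays = counts,
                                                     rowRanges = rowRanges)
  }
  new("ChromatinExperiment", se, binSize = binSize, windowSize = windowSize)
}

#' @describeIn ChromatinExperiment List of per-feature count matrices.
#' @param object,x A \code{ChromatinExperiment}.
#' @param ... Ignored.
#' @export
setMethod("counts", "ChromatinExperiment", function(object, ...) {
  as.list(SummarizedExperiment::assays(object))
})

#' @describeIn ChromatinExperiment Bin width in bp.
#' @export
setMethod("binSize", "ChromatinExperiment", function(x) x@binSize)

#' @describeIn ChromatinExperiment Window width in bp.
#' @export
setMethod("windowSize", "ChromatinExperiment", function(x) x@windowSize)

#' @describeIn ChromatinExperiment Number of loci N.
#' @export
setMethod("nLoci", "ChromatinExperiment", function(x) nrow(x))

#' @describeIn ChromatinExperiment Number of bins L.
#' @export
setMethod("nBins", "ChromatinExperiment", function(x) ncol(x))

#' @describeIn ChromatinExperiment Number of chromatin features M.
#' @export
setMethod("nFeatures", "ChromatinExperiment", function(x) {
  length(SummarizedExperiment::assays(x, withDimnames = FALSE))
})

#' @describeIn ChromatinExperiment Chromatin feature names.
#' @export
featureNames <- function(x) SummarizedExperiment::assayNames(x)

setMethod("show", "ChromatinExperiment", function(object) {
  cat(sprintf(
    "ChromatinExperiment: %d loci x %d bins (%d bp window, %d bp bins)\n",
    nrow(object), ncol(object), object@windowSize, object@binSize))
  cat("features(", nFeatures(object), "): ",
      paste(SummarizedExperiment::assayNames(object), collapse = ", "),
      "\n", sep = "")
  nz <- vapply(counts(object), function(m) sum(rowSums(m) == 0), numeric(1))
  if (any(nz > 0)) {
    cat("all-zero profiles per feature: ",
        paste(sprintf("%s=%d", SummarizedExperiment::assayNames(object), nz),
              collapse = ", "), "\n", sep = "")
  }
})
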