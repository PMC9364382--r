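#' @importFrom methods setGeneric setMethod setClass setValidity new validObject is slot
#' @importFrom BiocGenerics counts
NULL

#' Bin size accessor
#'
#' Width in base pairs of the genomic bins over which reads were counted.
#'
#' @param x An object with a bin size (e.g. [ChromatinExperiment] or
#'   [ShiftFlipConfig]).
#' @return Integer scalar, bin width in bp.
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' Window size accessor
#'
#' Width in base pairs of the genomic window centred at each locus anchor.
#'
#' @param x A [ChromatinExperiment].
#' @return Integer scalar, window width in bp.
#' @export
setGeneric("windowSize", function(x) standardGeneric("windowSize"))

#' Number of loci
#'
#' @param x A [ChromatinExperiment].
#' @return Integer scalar N, the number of genomic loci.
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))

#' Number of bins per profile
#'
#' @param x A [ChromatinExperiment].
#' @return Integer scalar L = windowSize / binSize.
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' Number of chromatin features
#'
#' @param x A [ChromatinExperiment] or [MixtureModel].
#' @return Integer scalar M.
#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))

#' Number of shift states
#'
#' @param x A [ShiftFlipConfig] or an object carrying one.
#' @return Odd integer S = 2 * maxShiftBp / binSize + 1 (1 when shifting is
#'   disabled).
#' @export
setGeneric("nShiftStates", function(x) standardGeneric("nShiftStates"))

#' Number of mixture components
#'
#' @param x A [MixtureModel] or [DMMFit].
#' @return Integer scalar K.
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' Mixture weights accessor
#'
#' @param x A [MixtureModel] or [DMMFit].
#' @return Numeric simplex vector of length K.
#' @export
setGeneric("mixtureWeights", function(x) standardGeneric("mixtureWeights"))

#' Dirichlet component parameters accessor
#'
#' @param x A [MixtureModel] or [DMMFit].
#' @return Numeric array with dimensions (extended profile length) x M x K.
#' @export
setGeneric("componentAlpha", function(x) standardGeneric("componentAlpha"))

#' Posterior responsibilities accessor
#'
#' @param x A [DMMFit].
#' @return Numeric array N x K x S x 2; each locus slice sums to one.
#' @export
setGeneric("responsibilities", function(x) standardGeneric("responsibilities"))

#' Hard assignments accessor
#'
#' @param x A [DMMFit].
#' @return A data.frame with one row per locus: cluster, shift state, flip
#'   state, shift in bp and the marginal cluster posterior.
#' @export
setGeneric("hardAssignments", function(x) standardGeneric("hardAssignments"))

#' Lower-bound trace accessor
#'
#' @param x A [DMMFit].
#' @return Numeric vector of the EM objective (observed-data log-posterior)
#'   after each iteration.
#' @export
setGeneric("lowerBoundTrace", function(x) standardGeneric("lowerBoundTrace"))
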