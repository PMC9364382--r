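#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assays assayNames
#' @importFrom stats optim kmeans dgamma rgamma rmultinom rpois cor
#' @importFrom utils read.table write.table head
NULL

#' ChromatinExperiment: binned multi-feature coverage profiles
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding, for N genomic loci,
#' the per-bin read counts of M chromatin features in windows of
#' \code{windowSize} bp at resolution \code{binSize} bp. Each assay is one
#' N x L non-negative integer matrix (L = windowSize / binSize); assay names
#' are the feature names. Optional \code{rowRanges} carry the locus
#' coordinates from a BED file; they are bookkeeping only and never enter the
#' likelihood.
#'
#' @slot binSize integer(1), bin width in bp.
#' @slot windowSize integer(1), window width in bp; must be an exact multiple
#'   of \code{binSize}.
#'
#' @seealso [ChromatinExperiment()] for the constructor,
#'   [readCountMatrix()] to load assays from tab-delimited text.
#' @export
setClass("ChromatinExperiment",
  contains = "SummarizedExperiment",
  representation(binSize = "integer", windowSize = "integer")
)

setValidity("ChromatinExperiment", function(object) {
  msg <- character()
  a <- SummarizedExperiment::assays(object, withDimnames = FALSE)
  if (length(a) < 1L) msg <- c(msg, "at least one feature assay is required")
  if (length(object@binSize) != 1L || is.na(object@binSize) ||
      object@binSize < 1L) {
    msg <- c(msg, "binSize must be a single positive integer")
  }
  if (length(object@windowSize) != 1L || is.na(object@windowSize) ||
      object@windowSize < 1L) {
    msg <- c(msg, "windowSize must be a single positive integer")
  }
  if (length(msg) == 0L) {
    if (object@windowSize %% object@binSize != 0L) {
      msg <- c(msg, "windowSize must be an exact multiple of binSize")
    } else if (ncol(object) != object@windowSize %/% object@binSize) {
      msg <- c(msg, sprintf(
        "number of bins (%d) must equal windowSize/binSize (%d)",
        ncol(object), object@windowSize %/% object@binSize))
    }
    for (i in seq_along(a)) {
      x <- a[[i]]
      if (!is.matrix(x) || !is.numeric(x)) {
        msg <- c(msg, sprintf("assay %d is not a numeric matrix", i))
      } else if (anyNA(x) || any(x < 0) || any(x != round(x))) {
        msg <- c(msg, sprintf(
          "assay %d must contain non-negative integral counts", i))
      }
    }
    if (is.null(names(a)) || anyNA(names(a)) || any(names(a) == "")) {
      msg <- c(msg, "all assays (features) must be named")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Hyperparameters of the Gamma priors on component parameters
#'
#' The Dirichlet parameters alpha of every component and feature receive
#' independent Gamma(eta, nu) priors (shape/rate), and the smoothness
#' statistic h = sum_j (alpha_j - alpha_{j-1})^2 of each component profile
#' receives a Gamma(etaH, nuH) prior that favours smooth profiles. Defaults
#' eta = 1.1, nu = 0.1 and etaH = nuH = 10 (smoothness prior with mean 1 and
#' variance 0.1).
#'
#' @slot eta numeric(1), shape of the per-element Gamma prior.
#' @slot nu numeric(1), rate of the per-element Gamma prior.
#' @slot etaH numeric(1), shape of the smoothness Gamma prior.
#' @slot nuH numeric(1), rate of the smoothness Gamma prior.
#' @slot regularize logical(1); when FALSE the smoothness factor is dropped
#'   from the prior (the per-element Gamma factors are kept).
#'
#' @seealso [Hyperparameters()]
#' @export
setClass("Hyperparameters",
  representation(eta = "numeric", nu = "numeric",
                 etaH = "numeric", nuH = "numeric",
                 regularize = "logical")
)

setValidity("Hyperparameters", function(object) {
  v <- c(eta = object@eta, nu = object@nu, etaH = object@etaH,
         nuH = object@nuH)
  if (length(v) != 4L || anyNA(v) || any(v <= 0)) {
    return("eta, nu, etaH, nuH must all be single strictly positive numbers")
  }
  if (length(object@regularize) != 1L || is.na(object@regularize)) {
    return("regularize must be TRUE or FALSE")
  }
  TRUE
})

#' Shift and flip configuration
#'
#' Controls the latent alignment states of the mixture model. With a maximum
#' shift of \code{maxShiftBp} bp at resolution \code{binSize} bp there are
#' S = 2 * maxShiftBp / binSize + 1 shift states; state (S + 1) / 2 is
#' "no shift". Flipping adds a two-valued strand-orientation state. The shift
#' prior is either uniform over states or pyramid-shaped (maximal at the
#' no-shift state, linearly decreasing to zero beyond the maximum shift).
#'
#' @slot shift logical(1), enable shift states.
#' @slot flip logical(1), enable flip states.
#' @slot maxShiftBp integer(1), maximum shift in bp (exact multiple of
#'   binSize; 0 when shifting is disabled).
#' @slot binSize integer(1), bin width in bp.
#' @slot shiftPrior character(1), \code{"uniform"} or \code{"pyramid"}.
#'
#' @seealso [ShiftFlipConfig()], [pyramidShiftPrior()]
#' @export
setClass("ShiftFlipConfig",
  representation(shift = "logical", flip = "logical",
                 maxShiftBp = "integer", binSize = "integer",
                 shiftPrior = "character")
)

setValidity("ShiftFlipConfig", function(object) {
  msg <- character()
  if (object@binSize < 1L) msg <- c(msg, "binSize must be positive")
  if (object@maxShiftBp < 0L) msg <- c(msg, "maxShiftBp must be >= 0")
  if (object@maxShiftBp %% object@binSize != 0L) {
    msg <- c(msg, "maxShiftBp must be an exact multiple of binSize")
  }
  if (object@shift && object@maxShiftBp == 0L) {
    msg <- c(msg, "shifting enabled but maxShiftBp is 0")
  }
  if (!object@shift && object@maxShiftBp != 0L) {
    msg <- c(msg, "maxShiftBp must be 0 when shifting is disabled")
  }
  if (!object@shiftPrior %in% c("uniform", "pyramid")) {
    msg <- c(msg, "shiftPrior must be 'uniform' or 'pyramid'")
  }
  if (length(msg)) msg else TRUE
})

#' Product Dirichlet-multinomial mixture model parameters
#'
#' Parameters of a K-component mixture in which component k models the M
#' chromatin-feature count profiles of a locus as independent
#' Dirichlet-multinomial draws. When shifting is enabled the Dirichlet
#' parameter vectors are extended from L to L + S - 1 positions; the latent
#' shift state selects an L-length window and the flip state optionally
#' reverses it.
#'
#' @slot alpha numeric array (L + S - 1) x M x K of strictly positive
#'   Dirichlet parameters.
#' @slot pi numeric(K) mixture weights (simplex).
#' @slot xi row-stochastic matrix of shift-state priors with S columns and
#'   either one row (shared across loci) or N rows (per locus).
#' @slot zeta row-stochastic matrix of flip-state priors with 2 columns and
#'   one or N rows.
#' @slot config a [ShiftFlipConfig].
#' @slot featureNames character(M).
#' @slot L integer(1), profile length in bins.
#'
#' @seealso [MixtureModel()], [fitDMM()]
#' @export
setClass("MixtureModel",
  representation(alpha = "array", pi = "numeric", xi = "matrix",
                 zeta = "matrix", config = "ShiftFlipConfig",
                 featureNames = "character", L = "integer")
)

setValidity("MixtureModel", function(object) {
  msg <- character()
  S <- nShiftStates(object@config)
  d <- dim(object@alpha)
  if (length(d) != 3L) {
    msg <- c(msg, "alpha must be a 3-d array (L+S-1) x M x K")
  } else {
    if (d[1] != object@L + S - 1L) {
      msg <- c(msg, sprintf("alpha has %d rows; expected L+S-1 = %d",
                            d[1], object@L + S - 1L))
    }
    if (d[2] != length(object@featureNames)) {
      msg <- c(msg, "alpha feature dimension does not match featureNames")
    }
    if (d[3] != length(object@pi)) {
      msg <- c(msg, "alpha component dimension does not match length(pi)")
    }
  }
  if (any(!is.finite(object@alpha)) || any(object@alpha <= 0)) {
    msg <- c(msg, "all alpha elements must be finite and > 0")
  }
  if (any(object@pi < 0) || abs(sum(object@pi) - 1) > 1e-8) {
    msg <- c(msg, "pi must be a probability vector summing to 1")
  }
  if (ncol(object@xi) != S) {
    msg <- c(msg, sprintf("xi must have S = %d columns", S))
  }
  if (ncol(object@zeta) != 2L) msg <- c(msg, "zeta must have 2 columns")
  if (any(abs(rowSums(object@xi) - 1) > 1e-8)) {
    msg <- c(msg, "every row of xi must sum to 1")
  }
  if (any(abs(rowSums(object@zeta) - 1) > 1e-8)) {
    msg <- c(msg, "every row of zeta must sum to 1")
  }
  if (length(msg)) msg else TRUE
})

#' Result of a MAP-EM fit
#'
#' Bundles the converged [MixtureModel], the posterior responsibility tensor
#' over (cluster, shift, flip) states, the per-iteration trace of the EM
#' objective (the observed-data log-posterior, which the EM lower bound
#' touches after every E-step), hard assignments and the information needed
#' to reproduce the fit.
#'
#' @slot model the fitted [MixtureModel].
#' @slot responsibilities N x K x S x 2 array; each locus slice sums to 1.
#' @slot lowerBoundTrace numeric, objective after each EM iteration.
#' @slot nIterations integer(1).
#' @slot converged logical(1).
#' @slot logPosterior numeric(1), final objective value.
#' @slot logLik numeric(1), observed-data log-likelihood at the optimum
#'   (shift/flip marginalized, prior on alpha excluded); used by AIC/BIC.
#' @slot assignments data.frame of hard assignments (see
#'   [computeHardAssignments()]).
#' @slot hyper the [Hyperparameters] used.
#' @slot seed integer(1), master seed of the winning restart.
#'
#' @seealso [fitDMM()], [informationCriteria()]
#' @export
setClass("DMMFit",
  representation(model = "MixtureModel", responsibilities = "array",
                 lowerBoundTrace = "numeric", nIterations = "integer",
                 converged = "logical", logPosterior = "numeric",
                 logLik = "numeric", assignments = "data.frame",
                 hyper = "Hyperparameters", seed = "integer")
)

setValidity("DMMFit", function(object) {
  d <- dim(object@responsibilities)
  if (length(d) != 4L) return("responsibilities must be N x K x S x 2")
  tot <- apply(object@responsibilities, 1L, sum)
  if (any(abs(tot - 1) > 1e-6)) {
    return("responsibilities must sum to 1 per locus")
  }
  TRUE
})
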