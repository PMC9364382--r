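#' Construct a MixtureModel
#'
#' @param alpha Numeric array (L + S - 1) x M x K of positive Dirichlet
#'   parameters (an L x 1 x 1 matrix/vector is promoted for K = M = 1).
#' @param pi Mixture weight simplex of length K.
#' @param config A [ShiftFlipConfig].
#' @param L Profile length in bins; defaults to nrow(alpha) - S + 1.
#' @param xi Shift-state prior: vector of length S (shared across loci) or
#'   an N x S row-stochastic matrix. Default from the config
#'   (uniform/pyramid).
#' @param zeta Flip-state prior: length-2 vector or N x 2 matrix. Default
#'   (0.5, 0.5) when flipping is enabled, else (1, 0).
#' @param featureNames Character vector of length M.
#' @return A [MixtureModel].
#' @export
MixtureModel <- function(alpha, pi, config = ShiftFlipConfig(), L = NULL,
                         xi = NULL, zeta = NULL, featureNames = NULL) {
  if (is.numeric(alpha) && is.null(dim(alpha))) {
    alpha <- array(alpha, dim = c(length(alpha), 1L, 1L))
  }
  if (length(dim(alpha)) == 2L) {
    alpha <- array(alpha, dim = c(dim(alpha), 1L))
  }
  S <- nShiftStates(config)
  if (is.null(L)) L <- dim(alpha)[1] - S + 1L
  if (is.null(featureNames)) {
    featureNames <- dimnames(alpha)[[2]]
    if (is.null(featureNames)) {
      featureNames <- paste0("feature", seq_len(dim(alpha)[2]))
    }
  }
  if (is.null(xi)) xi <- shiftPriorVector(config)
  if (is.null(dim(xi))) xi <- matrix(xi, nrow = 1L)
  if (is.null(zeta)) zeta <- flipPriorVector(config)
  if (is.null(dim(zeta))) zeta <- matrix(zeta, nrow = 1L)
  new("MixtureModel", alpha = alpha, pi = as.numeric(pi), xi = xi,
      zeta = zeta, config = config, featureNames = featureNames,
      L = as.integer(L))
}

#' @describeIn MixtureModel Number of mixture components K.
#' @param x,object A \code{MixtureModel}.
#' @export
setMethod("nComponents", "MixtureModel", function(x) length(x@pi))

#' @describeIn MixtureModel Number of chromatin features M.
#' @export
setMethod("nFeatures", "MixtureModel", function(x) length(x@featureNames))

#' @describeIn MixtureModel Mixture weights.
#' @export
setMethod("mixtureWeights", "MixtureModel", function(x) x@pi)

#' @describeIn MixtureModel Dirichlet parameter array (L+S-1) x M x K.
#' @export
setMethod("componentAlpha", "MixtureModel", function(x) x@alpha)

#' @describeIn MixtureModel Number of shift states.
#' @export
setMethod("nShiftStates", "MixtureModel", function(x) {
  nShiftStates(x@config)
})

setMethod("show", "MixtureModel", function(object) {
  cat(sprintf(
    "MixtureModel: K=%d components, M=%d features, L=%d bins (L_ext=%d)\n",
    nComponents(object), nFeatures(object), object@L, dim(object@alpha)[1]))
  cat("pi:", paste(signif(object@pi, 4), collapse = " "), "\n")
  show(object@config)
})

#' Mean profiles of a mixture model
#'
#' Expected bin proportions alpha / sum(alpha) of every component and
#' feature, evaluated on the window of a given shift/flip state (default:
#' the no-shift, unflipped window).
#'
#' @param model A [MixtureModel].
#' @param s,f Shift and flip state of the window (defaults: centre, 1).
#' @return L x M x K array of bin proportions.
#' @export
componentMeanProfiles <- function(model, s = NULL, f = 1L) {
  S <- nShiftStates(model@config)
  if (is.null(s)) s <- noShiftState(S)
  K <- nComponents(model)
  M <- nFeatures(model)
  out <- array(NA_real_, dim = c(model@L, M, K),
               dimnames = list(NULL, model@featureNames, NULL))
  for (k in seq_len(K)) {
    for (m in seq_len(M)) {
      w <- extractWindow(model@alpha[, m, k], s, f, model@L)
      out[, m, k] <- w / sum(w)
    }
  }
  out
}
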