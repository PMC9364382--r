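#' Construct prior hyperparameters
#'
#' Shape/rate hyperparameters of the regularized Gamma hyperprior on the
#' Dirichlet component parameters. The defaults (\code{eta = 1.1},
#' \code{nu = 0.1}) place a weak prior with mean eta/nu = 11 on every alpha
#' element, and \code{etaH = nuH = 10} gives the smoothness statistic of each
#' profile a Gamma prior with mean 1 and variance 0.1, penalizing rough
#' component profiles.
#'
#' @param eta,nu Shape and rate of the per-element Gamma prior on alpha.
#' @param etaH,nuH Shape and rate of the Gamma prior on the smoothness
#'   statistic h = sum of squared first differences of a component profile.
#' @param regularize When FALSE the smoothness factor is omitted from the
#'   prior (used, e.g., to quantify the effect of regularization).
#' @return A [Hyperparameters] object.
#' @examples
#' Hyperparameters()                   # defaults
#' Hyperparameters(regularize = FALSE) # drop the smoothness factor
#' @export
Hyperparameters <- function(eta = 1.1, nu = 0.1, etaH = 10, nuH = 10,
                            regularize = TRUE) {
  new("Hyperparameters", eta = as.numeric(eta), nu = as.numeric(nu),
      etaH = as.numeric(etaH), nuH = as.numeric(nuH),
      regularize = as.logical(regularize))
}

setMethod("show", "Hyperparameters", function(object) {
  cat(sprintf(
    "Hyperparameters: eta=%g nu=%g | smoothness %s (etaH=%g nuH=%g)\n",
    object@eta, object@nu,
    if (object@regularize) "on" else "off", object@etaH, object@nuH))
})
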