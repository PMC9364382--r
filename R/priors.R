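#' Smoothness statistic of a component profile
#'
#' Sum of squared first differences,
#' \eqn{h = \sum_{j \ge 2} (\alpha_j - \alpha_{j-1})^2}; zero for constant
#' or length-1 profiles. Small h means a smooth profile; the prior places a
#' Gamma(etaH, nuH) density on h.
#'
#' @param alphaKm Numeric vector (one component profile, possibly shift
#'   extended).
#' @return Non-negative scalar.
#' @examples
#' smoothnessTerm(c(1, 2, 4))  # (2-1)^2 + (4-2)^2 = 5
#' @export
smoothnessTerm <- function(alphaKm) {
  if (length(alphaKm) < 2L) return(0)
  sum(diff(alphaKm)^2)
}

#' Gamma log-density, shape/rate parameterization
#' @keywords internal
gammaLogPdf <- function(x, shape, rate) {
  stats::dgamma(x, shape = shape, rate = rate, log = TRUE)
}

## log prior of one component-feature profile (in alpha space)
logPriorAlphaBlock <- function(alphaKm, hyper) {
  val <- sum(gammaLogPdf(alphaKm, hyper@eta, hyper@nu))
  if (hyper@regularize && length(alphaKm) > 1L) {
    val <- val + gammaLogPdf(smoothnessTerm(alphaKm), hyper@etaH, hyper@nuH)
  }
  val
}

## gradient of logPriorAlphaBlock wrt alpha; -Inf prior (h = 0, etaH > 1)
## has no usable gradient -- callers avoid that point
gradLogPriorAlphaBlock <- function(alphaKm, hyper) {
  g <- (hyper@eta - 1) / alphaKm - hyper@nu
  if (hyper@regularize && length(alphaKm) > 1L) {
    h <- smoothnessTerm(alphaKm)
    d <- diff(alphaKm)
    dh <- c(-2 * d[1], 2 * d[-length(d)] - 2 * d[-1], 2 * d[length(d)])
    if (length(alphaKm) == 2L) dh <- c(-2 * d, 2 * d)
    g <- g + ((hyper@etaH - 1) / h - hyper@nuH) * dh
  }
  g
}

#' Log prior density of the component parameters (alpha space)
#'
#' Unnormalized log prior of all component-feature profiles: every alpha
#' element has an independent Gamma(eta, nu) density and, when
#' regularization is on, the smoothness statistic of each profile has a
#' Gamma(etaH, nuH) density. The unknown normalizing constant of the joint
#' prior is omitted (it is constant in alpha). A profile with h = 0 and
#' etaH > 1 yields -Inf, a valid log value.
#'
#' @param model A [MixtureModel], or a 3-d alpha array (L_ext x M x K).
#' @param hyper A [Hyperparameters].
#' @return Scalar log prior (possibly -Inf).
#' @export
logPriorAlpha <- function(model, hyper) {
  alpha <- if (is(model, "MixtureModel")) model@alpha else model
  if (is.null(dim(alpha))) alpha <- array(alpha, c(length(alpha), 1L, 1L))
  val <- 0
  for (k in seq_len(dim(alpha)[3])) {
    for (m in seq_len(dim(alpha)[2])) {
      val <- val + logPriorAlphaBlock(alpha[, m, k], hyper)
    }
  }
  val
}

#' Log prior density in the lambda = log(alpha) parameterization
#'
#' Change of variables alpha = exp(lambda): the density picks up the
#' log-Jacobian sum(lambda), so
#' \code{logPriorLambda(l) == logPriorAlpha(exp(l)) + sum(l)} for all
#' finite lambda. This is the prior the quasi-Newton M-step maximizes.
#'
#' @param lambdaStar Numeric array of the same shape as alpha (any shape;
#'   vectors are promoted).
#' @param hyper A [Hyperparameters].
#' @return Scalar log prior (possibly -Inf).
#' @export
logPriorLambda <- function(lambdaStar, hyper) {
  if (any(lambdaStar > 700)) {
    stop("lambda too large: exp(lambda) would overflow")
  }
  logPriorAlpha(exp(lambdaStar), hyper) + sum(lambdaStar)
}

## gradient of logPriorLambda for one profile block (vector lambda)
gradLogPriorLambdaBlock <- function(lambdaKm, hyper) {
  a <- exp(lambdaKm)
  a * gradLogPriorAlphaBlock(a, hyper) + 1
}
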