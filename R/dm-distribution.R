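#' Dirichlet-multinomial (Polya) log probability mass
#'
#' Log of the proper Dirichlet-multinomial pmf, including the multinomial
#' coefficient, evaluated entirely in log-gamma space:
#' \deqn{\log DM(x \mid \alpha) = \log\frac{n!}{\prod_j x_j!}
#'   + \log\frac{\Gamma(A)}{\Gamma(n + A)}
#'   + \sum_j \log\frac{\Gamma(x_j + \alpha_j)}{\Gamma(\alpha_j)},}
#' with \eqn{n = \sum_j x_j} and \eqn{A = \sum_j \alpha_j}. This is the
#' compound of a multinomial whose probability vector is Dirichlet(alpha)
#' distributed; it is overdispersed relative to the multinomial with the
#' same mean.
#'
#' @param x Non-negative integral count vector of length L.
#' @param alpha Strictly positive numeric vector of length L.
#' @return Log-probability (finite for all valid inputs; 0 when n = 0 or
#'   L = 1).
#' @examples
#' logDirichletMultinomial(c(2, 1), c(1, 2))  # log(0.2)
#' @export
logDirichletMultinomial <- function(x, alpha) {
  if (length(x) != length(alpha)) {
    stop("'x' and 'alpha' must have the same length")
  }
  checkCounts(x)
  if (anyNA(alpha) || any(alpha <= 0)) {
    stop("'alpha' must be strictly positive")
  }
  n <- sum(x)
  A <- sum(alpha)
  lgamma(n + 1) - sum(lgamma(x + 1)) +
    lgamma(A) - lgamma(n + A) +
    sum(lgamma(x + alpha) - lgamma(alpha))
}

#' Multi-feature locus log-likelihood under one component
#'
#' Sum over chromatin features of the Dirichlet-multinomial log mass: the
#' product-Dirichlet-multinomial component likelihood of one locus.
#'
#' @param xStar List of M count vectors (one per feature).
#' @param alphaK List of M positive parameter vectors of matching lengths.
#' @return Log-likelihood of the locus under the component.
#' @export
locusLogLikelihood <- function(xStar, alphaK) {
  if (!is.list(xStar)) xStar <- list(xStar)
  if (!is.list(alphaK)) alphaK <- list(alphaK)
  if (length(xStar) != length(alphaK)) {
    stop("number of features differs between data and parameters")
  }
  sum(mapply(logDirichletMultinomial, xStar, alphaK))
}

#' Per-locus multinomial log-coefficients of a count matrix
#'
#' lgamma(n_i + 1) - sum_j lgamma(x_ij + 1); constant in alpha, needed for
#' the proper likelihood used by AIC/BIC.
#' @keywords internal
multinomialLogCoef <- function(X) {
  lgamma(rowSums(X) + 1) - rowSums(lgamma(X + 1))
}

## --- fast batched evaluation ------------------------------------------------
##
## Count matrices hold small non-negative integers, so lgamma(x_ij + a_p) for
## all loci and all extended parameter positions p is a lookup into the
## (V+1) x L_ext table lgamma(outer(0:V, alphaExt, "+")), V = max(X). The
## E-step and the M-step objective reuse the same table instead of issuing
## N x L x S x 2 special-function calls per window.

#' Per-locus DM log-mass for every (shift, flip) window of one component
#' profile, excluding the multinomial coefficient.
#'
#' @param X N x L count matrix for one feature.
#' @param alphaExt Extended parameter vector of length L + S - 1.
#' @param S Number of shift states.
#' @param nFlip 1 or 2.
#' @return N x S x nFlip array of log-masses.
#' @keywords internal
dmLogMassWindows <- function(X, alphaExt, S, nFlip) {
  N <- nrow(X)
  L <- ncol(X)
  V <- max(X)
  LG <- lgamma(outer(0:V, alphaExt, "+"))   # (V+1) x L_ext lookup table
  lgAlpha <- LG[1L, ]                        # lgamma(alphaExt)
  n <- rowSums(X)
  csum <- c(0, cumsum(alphaExt))
  out <- array(NA_real_, dim = c(N, S, nFlip))
  Xi <- X + 1L                               # row index into LG
  nV1 <- V + 1L
  for (s in seq_len(S)) {
    A <- csum[s + L] - csum[s]
    aTerm <- lgamma(A) - lgamma(n + A)
    for (f in seq_len(nFlip)) {
      idx <- windowIndices(s, f, L)
      # linear indices into LG: column idx[j] for data column j
      lin <- Xi + matrix((idx - 1L) * nV1, nrow = N, ncol = L, byrow = TRUE)
      out[, s, f] <- aTerm + rowSums(matrix(LG[lin], nrow = N)) -
        sum(lgAlpha[idx])
    }
  }
  out
}

#' Observed-data log-likelihood tensor
#'
#' log p(x_i* | z_iksf = 1) summed over features, for every locus and every
#' (component, shift, flip) configuration; the per-locus multinomial
#' coefficients are excluded (add [multinomialLogCoef()] totals for the
#' proper likelihood).
#'
#' @param countsList List of M count matrices N x L.
#' @param model A [MixtureModel].
#' @return N x K x S x 2 array (f = 2 slice finite even when flipping is
#'   disabled; the flip prior removes it downstream).
#' @keywords internal
logLikTensor <- function(countsList, model) {
  S <- nShiftStates(model@config)
  K <- nComponents(model)
  M <- nFeatures(model)
  N <- nrow(countsList[[1]])
  nF <- if (model@config@flip) 2L else 1L
  out <- array(0, dim = c(N, K, S, 2L))
  for (k in seq_len(K)) {
    acc <- array(0, dim = c(N, S, nF))
    for (m in seq_len(M)) {
      acc <- acc + dmLogMassWindows(countsList[[m]], model@alpha[, m, k],
                                    S, nF)
    }
    out[, k, , seq_len(nF)] <- acc
  }
  out
}
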