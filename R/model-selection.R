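#' AIC and BIC of a fitted mixture
#'
#' Criteria are computed from the maximized observed-data log-likelihood
#' (shift/flip states marginalized under their priors; the alpha prior is
#' excluded so regularization strength does not distort model comparison):
#' \code{AIC = 2 p - 2 logL}, \code{BIC = p log(N) - 2 logL} with
#' \code{p = K * M * (L + S - 1) + (K - 1)} free parameters (the optimized
#' Dirichlet parameters, counted at the shift-extended length, plus the free
#' mixture weights; the fixed shift/flip priors and hyperparameters are not
#' counted).
#'
#' @param fit A [DMMFit].
#' @param N Number of loci; defaults to the fit's responsibility rows.
#' @return Named list with \code{aic}, \code{bic}, \code{logLik},
#'   \code{nParameters}.
#' @export
informationCriteria <- function(fit, N = dim(fit@responsibilities)[1]) {
  model <- fit@model
  K <- nComponents(model)
  M <- nFeatures(model)
  Lext <- dim(model@alpha)[1]
  p <- K * M * Lext + (K - 1L)
  list(aic = 2 * p - 2 * fit@logLik,
       bic = p * log(N) - 2 * fit@logLik,
       logLik = fit@logLik, nParameters = p)
}

#' Fit a range of K and select the number of clusters
#'
#' Fits the mixture for every K in \code{kRange} (with restarts) and tabulates
#' AIC and BIC; the selected K per criterion is the minimizer, ties going to
#' the smaller K. Fit failures for individual K are reported and skipped.
#'
#' @param dataset A [ChromatinExperiment].
#' @param kRange Integer vector of component counts to fit.
#' @param config A [ShiftFlipConfig].
#' @param hyper A [Hyperparameters].
#' @param nRestarts Restarts per K.
#' @param maxIter,tol EM controls passed to [fitDMM()].
#' @param seed Master seed; K index i uses \code{seed + 1000 * (i - 1)}.
#' @param verbose Print progress.
#' @return List with \code{table} (data.frame: K, logLik, nParameters, AIC,
#'   BIC, converged, chosenAIC, chosenBIC), \code{bestAIC} and
#'   \code{bestBIC} (the winning [DMMFit]s), and \code{fits} (all fits,
#'   named by K).
#' @export
selectK <- function(dataset, kRange = 1:3, config = ShiftFlipConfig(),
                    hyper = Hyperparameters(), nRestarts = 2L,
                    maxIter = 200L, tol = 1e-6, seed = 1L, verbose = FALSE) {
  kRange <- sort(unique(as.integer(kRange)))
  if (length(kRange) == 0L) stop("kRange must be non-empty")
  N <- nLoci(dataset)
  fits <- list()
  rows <- list()
  for (i in seq_along(kRange)) {
    K <- kRange[i]
    if (verbose) message("fitting K = ", K)
    fit <- tryCatch(
      fitDMM(dataset, K, config, hyper, nRestarts = nRestarts,
             maxIter = maxIter, tol = tol, seed = seed + 1000L * (i - 1L)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      warning(sprintf("K = %d failed: %s", K, conditionMessage(fit)),
              call. = FALSE)
      next
    }
    ic <- informationCriteria(fit, N)
    fits[[as.character(K)]] <- fit
    rows[[length(rows) + 1L]] <- data.frame(
      K = K, logLik = ic$logLik, nParameters = ic$nParameters,
      AIC = ic$aic, BIC = ic$bic, nRestarts = nRestarts,
      converged = fit@converged)
  }
  if (length(rows) == 0L) stop("every K in kRange failed to fit")
  tab <- do.call(rbind, rows)
  tab$chosenAIC <- seq_len(nrow(tab)) == which.min(tab$AIC)
  tab$chosenBIC <- seq_len(nrow(tab)) == which.min(tab$BIC)
  list(table = tab,
       bestAIC = fits[[as.character(tab$K[tab$chosenAIC])]],
       bestBIC = fits[[as.character(tab$K[tab$chosenBIC])]],
       fits = fits)
}
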