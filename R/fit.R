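## E-step core: responsibilities plus the observed-data quantities needed
## for the objective trace and AIC/BIC.
eStepCore <- function(countsList, model, logCoef = NULL) {
  ll <- logLikTensor(countsList, model)
  N <- dim(ll)[1]
  K <- dim(ll)[2]
  S <- dim(ll)[3]
  logXi <- log(model@xi)
  if (nrow(logXi) == 1L) logXi <- logXi[rep(1L, N), , drop = FALSE]
  logZeta <- log(model@zeta)
  if (nrow(logZeta) == 1L) logZeta <- logZeta[rep(1L, N), , drop = FALSE]
  logPi <- log(model@pi)
  for (k in seq_len(K)) {
    for (f in 1:2) {
      ll[, k, , f] <- ll[, k, , f] + logPi[k] + logXi + logZeta[, f]
    }
  }
  flat <- matrix(ll, nrow = N)
  lse <- rowLogSumExp(flat)
  degenerate <- !is.finite(lse)
  resp <- exp(flat - ifelse(degenerate, 0, lse))
  if (any(degenerate)) {
    warning(sum(degenerate), " locus/loci with vanishing likelihood under ",
            "every configuration; assigning uniform responsibilities",
            call. = FALSE)
    resp[degenerate, ] <- 1 / ncol(flat)
    lse[degenerate] <- 0
  }
  resp <- resp / rowSums(resp)
  if (is.null(logCoef)) {
    logCoef <- Reduce(`+`, lapply(countsList, multinomialLogCoef))
  }
  list(resp = array(resp, dim = dim(ll)),
       logLik = sum(lse + logCoef),
       perLocus = lse + logCoef)
}

#' E-step: posterior responsibilities over (cluster, shift, flip)
#'
#' Computes \eqn{E[z_{iksf}] \propto \pi_k \xi_{is} \zeta_{if} \prod_m
#' DM(x_i^{(m)} \mid window(\alpha_k^{(m)}, s, f))}, normalized per locus
#' via log-sum-exp. Loci whose likelihood vanishes under every
#' configuration get uniform responsibilities with a warning.
#'
#' @param dataset A [ChromatinExperiment].
#' @param model A [MixtureModel].
#' @return N x K x S x 2 responsibility array; each locus slice sums to 1.
#' @export
eStep <- function(dataset, model) {
  eStepCore(counts(dataset), model)$resp
}

#' M-step update of the mixture weights
#'
#' \eqn{\pi_k = \frac{1}{N} \sum_i \sum_{s,f} E[z_{iksf}]}.
#'
#' @param responsibilities N x K x S x 2 responsibility array.
#' @return Simplex vector of length K.
#' @export
mStepWeights <- function(responsibilities) {
  piK <- apply(responsibilities, 2L, sum) / dim(responsibilities)[1]
  piK / sum(piK)
}

#' M-step update of the component parameters
#'
#' For each (component, feature) block, maximizes the expected complete-data
#' log-posterior over lambda = log(alpha) by BFGS with analytic gradients
#' (the blocks are separable given the responsibilities). A block whose
#' update fails or degrades its objective keeps its previous parameters, so
#' the generalized-EM ascent contract holds.
#'
#' @param dataset A [ChromatinExperiment].
#' @param responsibilities N x K x S x 2 array from [eStep()].
#' @param model Current [MixtureModel].
#' @param hyper A [Hyperparameters].
#' @param maxit BFGS iteration cap per block per M-step.
#' @return Updated alpha array (same shape as \code{componentAlpha(model)}).
#' @export
mStepAlpha <- function(dataset, responsibilities, model, hyper,
                       maxit = 50L) {
  countsList <- counts(dataset)
  S <- nShiftStates(model@config)
  nF <- if (model@config@flip) 2L else 1L
  K <- nComponents(model)
  M <- nFeatures(model)
  N <- dim(responsibilities)[1]
  alpha <- model@alpha
  for (k in seq_len(K)) {
    W <- matrix(responsibilities[, k, , seq_len(nF)], nrow = N)
    for (m in seq_len(M)) {
      alpha[, m, k] <- mStepAlphaBlock(countsList[[m]], W, alpha[, m, k],
                                       hyper, S, nF, maxit = maxit)
    }
  }
  alpha
}

## Data-driven starting alpha for one block: responsibility-weighted mean
## bin proportions scaled to mean alpha ~ 1, padded into the extended
## vector, with a tiny ramp so the smoothness statistic cannot be exactly 0.
initialAlphaBlock <- function(X, r, L, Lext) {
  wx <- colSums(X * r) + 0.5
  p <- wx / sum(wx)
  a <- pmax(L * p, 1e-3)
  s0 <- (Lext - L) %/% 2L
  ext <- c(rep(a[1L], s0), a, rep(a[L], Lext - L - s0))
  ext + 1e-4 * seq_len(Lext) / Lext
}

#' Initialize a mixture model from soft k-means memberships
#'
#' Cluster memberships are initialized by soft k-means on the row-wise
#' concatenation of all features (each feature profile scaled to
#' proportions): k-means centroids give squared distances d, and memberships
#' softmax(-d / (2T)) with temperature T equal to the mean nearest-centroid
#' squared distance, which keeps them non-degenerate. Responsibilities over
#' shift/flip states are spread by the priors. Component parameters are then
#' initialized by one M-step (maximizing the EM lower bound given those
#' responsibilities), and weights from the membership means.
#'
#' @param dataset A [ChromatinExperiment].
#' @param K Number of components (1 <= K <= N).
#' @param config A [ShiftFlipConfig].
#' @param hyper A [Hyperparameters].
#' @param seed Integer seed; identical seeds give identical initializations.
#' @return List with elements \code{model} (a [MixtureModel]) and
#'   \code{responsibilities}.
#' @export
initializeDMM <- function(dataset, K, config = ShiftFlipConfig(),
                          hyper = Hyperparameters(), seed = 1L) {
  N <- nLoci(dataset)
  L <- nBins(dataset)
  if (K < 1L || K > N) stop("K must be between 1 and the number of loci")
  set.seed(seed)
  countsList <- counts(dataset)
  prop <- lapply(countsList, function(X) {
    n <- rowSums(X)
    P <- X / ifelse(n > 0, n, 1)
    P[n == 0, ] <- 1 / ncol(X)
    P
  })
  concat <- do.call(cbind, prop)
  if (K == 1L) {
    r <- matrix(1, nrow = N, ncol = 1L)
  } else {
    km <- stats::kmeans(concat, centers = K, nstart = 3L, iter.max = 100L)
    d2 <- vapply(seq_len(K), function(k) {
      rowSums(sweep(concat, 2L, km$centers[k, ])^2)
    }, numeric(N))
    temp <- mean(apply(d2, 1L, min)) + 1e-12
    lw <- -d2 / (2 * temp)
    r <- exp(lw - apply(lw, 1L, max))
    r <- r / rowSums(r)
  }
  S <- nShiftStates(config)
  xi <- shiftPriorVector(config)
  zeta <- flipPriorVector(config)
  resp <- array(0, dim = c(N, K, S, 2L))
  for (k in seq_len(K)) {
    resp[, k, , ] <- r[, k] %o% xi %o% zeta
  }
  Lext <- L + S - 1L
  M <- nFeatures(dataset)
  alpha <- array(NA_real_, dim = c(Lext, M, K),
                 dimnames = list(NULL, featureNames(dataset), NULL))
  for (k in seq_len(K)) {
    for (m in seq_len(M)) {
      alpha[, m, k] <- initialAlphaBlock(countsList[[m]], r[, k], L, Lext)
    }
  }
  model <- MixtureModel(alpha = alpha, pi = colMeans(r), config = config,
                        L = L, xi = xi, zeta = zeta,
                        featureNames = featureNames(dataset))
  model@alpha <- mStepAlpha(dataset, resp, model, hyper, maxit = 50L)
  list(model = model, responsibilities = resp)
}

## One EM run from a given seed.
singleFit <- function(dataset, K, config, hyper, maxIter, tol, seed,
                      mStepMaxit = 40L, verbose = FALSE) {
  init <- initializeDMM(dataset, K, config, hyper, seed)
  model <- init$model
  countsList <- counts(dataset)
  logCoef <- Reduce(`+`, lapply(countsList, multinomialLogCoef))
  trace <- numeric(0)
  converged <- FALSE
  es <- NULL
  iter <- 0L
  repeat {
    es <- eStepCore(countsList, model, logCoef)
    # objective in the lambda = log(alpha) parameterization the M-step
    # maximizes: prior change of variables contributes the log-Jacobian
    q <- es$logLik + logPriorLambda(log(model@alpha), hyper)
    trace <- c(trace, q)
    iter <- iter + 1L
    if (verbose) message(sprintf("  iter %d: Q = %.6f", iter, q))
    if (iter > 1L) {
      rel <- abs(q - trace[iter - 1L]) / max(abs(q), 1e-12)
      if (is.finite(rel) && rel < tol) {
        converged <- TRUE
        break
      }
    }
    if (iter >= maxIter) break
    model@alpha <- mStepAlpha(dataset, es$resp, model, hyper,
                              maxit = mStepMaxit)
    model@pi <- mStepWeights(es$resp)
  }
  list(model = model, resp = es$resp, trace = trace, converged = converged,
       logLik = es$logLik, logPost = trace[length(trace)], seed = seed)
}

#' Fit the product Dirichlet-multinomial mixture by MAP-EM
#'
#' Runs \code{nRestarts} independent EM fits (restart r uses seed
#' \code{seed + r - 1}) and returns the one with the highest final
#' observed-data log-posterior. Each EM iteration performs an exact E-step
#' over the (cluster, shift, flip) tensor and a generalized M-step
#' (closed-form mixture weights; per-block BFGS updates of log(alpha)), and
#' stops when the relative change of the objective falls below \code{tol}.
#'
#' @param dataset A [ChromatinExperiment].
#' @param K Number of mixture components.
#' @param config A [ShiftFlipConfig].
#' @param hyper A [Hyperparameters].
#' @param nRestarts Number of independent restarts.
#' @param maxIter Maximum EM iterations per restart.
#' @param tol Relative objective-change convergence tolerance.
#' @param seed Master integer seed.
#' @param verbose Print the objective per iteration.
#' @return A [DMMFit].
#' @examples
#' sim <- simulateDMM(alphaTrue = twoClusterAlpha(L = 20, M = 1),
#'                    piTrue = c(0.5, 0.5), coverages = 100, N = 60,
#'                    seed = 1)
#' fit <- fitDMM(sim$dataset, K = 2, nRestarts = 1, seed = 1)
#' mixtureWeights(fit)
#' @export
fitDMM <- function(dataset, K, config = ShiftFlipConfig(),
                   hyper = Hyperparameters(), nRestarts = 2L,
                   maxIter = 200L, tol = 1e-6, seed = 1L, verbose = FALSE) {
  if (maxIter < 1L || tol <= 0) stop("maxIter and tol must be positive")
  zeroLoci <- sum(Reduce(`+`, lapply(counts(dataset), rowSums)) == 0)
  if (zeroLoci > 0) {
    warning(zeroLoci, " locus/loci have all-zero counts in every feature; ",
            "they carry no signal (DM mass of an empty profile is 1)",
            call. = FALSE)
  }
  best <- NULL
  failures <- character(0)
  for (r in seq_len(nRestarts)) {
    res <- tryCatch(
      singleFit(dataset, K, config, hyper, maxIter, tol,
                seed = seed + r - 1L, verbose = verbose),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, conditionMessage(res))
      warning(sprintf("restart %d failed: %s", r, conditionMessage(res)),
              call. = FALSE)
      next
    }
    if (is.null(best) || res$logPost > best$logPost) best <- res
  }
  if (is.null(best)) {
    stop("all EM restarts failed: ", paste(failures, collapse = "; "))
  }
  assignments <- computeHardAssignments(best$resp, best$model@config)
  new("DMMFit", model = best$model, responsibilities = best$resp,
      lowerBoundTrace = best$trace, nIterations = length(best$trace),
      converged = best$converged, logPosterior = best$logPost,
      logLik = best$logLik, assignments = assignments, hyper = hyper,
      seed = as.integer(best$seed))
}

#' @describeIn DMMFit Fitted mixture model.
#' @param x,object A \code{DMMFit}.
#' @export
setMethod("responsibilities", "DMMFit", function(x) x@responsibilities)

#' @describeIn DMMFit Hard assignments data.frame.
#' @export
setMethod("hardAssignments", "DMMFit", function(x) x@assignments)

#' @describeIn DMMFit EM objective trace.
#' @export
setMethod("lowerBoundTrace", "DMMFit", function(x) x@lowerBoundTrace)

#' @describeIn DMMFit Number of components of the fitted model.
#' @export
setMethod("nComponents", "DMMFit", function(x) nComponents(x@model))

#' @describeIn DMMFit Mixture weights of the fitted model.
#' @export
setMethod("mixtureWeights", "DMMFit", function(x) mixtureWeights(x@model))

#' @describeIn DMMFit Dirichlet parameters of the fitted model.
#' @export
setMethod("componentAlpha", "DMMFit", function(x) componentAlpha(x@model))

setMethod("show", "DMMFit", function(object) {
  cat(sprintf(
    "DMMFit: K=%d, %s after %d iterations (seed %d)\n",
    nComponents(object), if (object@converged) "converged" else "NOT converged",
    object@nIterations, object@seed))
  cat(sprintf("log-posterior %.4f, log-likelihood %.4f\n",
              object@logPosterior, object@logLik))
  print(table(cluster = object@assignments$cluster))
})
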