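## M-step machinery for one (component, feature) block.
##
## Given responsibilities, the expected complete-data log-posterior separates
## over (k, m) blocks; each block objective is a weighted sum of DM log-masses
## over the (shift, flip) windows of one extended parameter vector, plus the
## block's prior. Because counts are small integers, the weighted likelihood
## collapses onto value-grouped tables: per data column j and window w,
## sum_i W_iw * lgamma(x_ij + a) = sum_v Tab[v+1, j, w] * lgamma(v + a),
## built once per M-step with rowsum(). Objective and gradient then only
## touch a (V+1) x L_ext lgamma/digamma lookup of the current alpha.

## Precompute the weight tables for one block.
## X: N x L counts; W: N x (S*nF) responsibilities (columns ordered s fast,
## f slow, matching windowOrder()).
mStepTables <- function(X, W) {
  N <- nrow(X)
  L <- ncol(X)
  V <- max(X)
  nW <- ncol(W)
  TabM <- matrix(0, nrow = (V + 1L) * L, ncol = nW)
  for (j in seq_len(L)) {
    g <- rowsum(W, group = X[, j], reorder = TRUE)
    vals <- as.integer(rownames(g))
    TabM[(j - 1L) * (V + 1L) + vals + 1L, ] <- g
  }
  n <- rowSums(X)
  nTab <- rowsum(W, group = n, reorder = TRUE)
  list(TabM = TabM, nVals = as.numeric(rownames(nTab)), nTab = nTab,
       wSum = colSums(W), V = V, L = L)
}

## (s, f) pairs in the column order used for W / tables
windowOrder <- function(S, nF) {
  cbind(s = rep(seq_len(S), nF), f = rep(seq_len(nF), each = S))
}

## L x (S*nF) matrix of extended-vector positions: column w holds the
## positions addressed by window w, in data-column order
windowIndexMatrix <- function(S, nF, L) {
  wo <- windowOrder(S, nF)
  vapply(seq_len(nrow(wo)), function(w) {
    windowIndices(wo[w, 1L], wo[w, 2L], L)
  }, integer(L))
}

## Weighted DM log-likelihood (no multinomial coefficient) and its gradient
## in alpha, over all windows of one block; fully vectorized over windows.
blockLikValueGrad <- function(alphaExt, tab, S, nF, grad = TRUE) {
  L <- tab$L
  V <- tab$V
  idxVec <- as.vector(tab$IDX)              # length L * nW
  nW <- ncol(tab$IDX)
  LG <- lgamma(outer(0:V, alphaExt, "+"))   # (V+1) x L_ext lookup
  csum <- c(0, cumsum(alphaExt))
  wo <- windowOrder(S, nF)
  As <- (csum[wo[, 1L] + L] - csum[wo[, 1L]])   # per-window alpha totals
  wtRep <- rep(tab$wSum, each = L)

  bigLG <- LG[, idxVec, drop = FALSE]
  dim(bigLG) <- c((V + 1L) * L, nW)
  val <- sum(tab$TabM * bigLG) -
    sum(wtRep * LG[1L, idxVec]) +
    sum(tab$wSum * lgamma(As)) -
    sum(tab$nTab * lgamma(outer(tab$nVals, As, "+")))

  gvec <- NULL
  if (grad) {
    DG <- digamma(outer(0:V, alphaExt, "+"))
    bigDG <- DG[, idxVec, drop = FALSE]
    dim(bigDG) <- c((V + 1L) * L, nW)
    P <- tab$TabM * bigDG
    dim(P) <- c(V + 1L, L * nW)
    gjw <- colSums(P) - wtRep * DG[1L, idxVec]
    cA <- tab$wSum * digamma(As) -
      colSums(tab$nTab * digamma(outer(tab$nVals, As, "+")))
    gjw <- gjw + rep(cA, each = L)
    gvec <- as.vector(rowsum(gjw, group = idxVec))
  }
  list(value = val, grad = gvec)
}

## Maximize the block objective in lambda = log(alpha) by BFGS.
## Returns the updated alphaExt; falls back to the previous value (with a
## warning) if the optimizer fails or degrades the objective.
mStepAlphaBlock <- function(X, W, alphaExt0, hyper, S, nF,
                            maxit = 50L, reltol = 1e-10) {
  tab <- mStepTables(X, W)
  tab$IDX <- windowIndexMatrix(S, nF, tab$L)
  lam0 <- log(alphaExt0)
  negObj <- function(lam) {
    if (any(!is.finite(lam)) || any(lam > 60) || any(lam < -60)) return(1e12)
    a <- exp(lam)
    lik <- blockLikValueGrad(a, tab, S, nF, grad = FALSE)$value
    pri <- logPriorAlphaBlock(a, hyper) + sum(lam)
    v <- lik + pri
    if (!is.finite(v)) return(1e12)
    -v
  }
  negGrad <- function(lam) {
    a <- exp(lam)
    gl <- blockLikValueGrad(a, tab, S, nF, grad = TRUE)$grad
    -(a * (gl + gradLogPriorAlphaBlock(a, hyper)) + 1)
  }
  f0 <- negObj(lam0)
  opt <- tryCatch(
    stats::optim(lam0, fn = negObj, gr = negGrad, method = "BFGS",
                 control = list(maxit = maxit, reltol = reltol)),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value) || opt$value > f0 + 1e-9) {
    if (is.null(opt)) {
      warning("BFGS update failed for a component block; keeping previous ",
              "parameters", call. = FALSE)
    }
    return(alphaExt0)
  }
  exp(opt$par)
}

## Expected complete-data log-posterior contribution of one block, used by
## tests to verify the generalized-EM (non-decreasing) contract directly.
blockObjective <- function(X, W, alphaExt, hyper, S, nF) {
  tab <- mStepTables(X, W)
  tab$IDX <- windowIndexMatrix(S, nF, ncol(X))
  blockLikValueGrad(alphaExt, tab, S, nF, grad = FALSE)$value +
    logPriorAlphaBlock(alphaExt, hyper)
}
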