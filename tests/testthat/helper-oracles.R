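# Independent reference implementations used as oracles. These deliberately
# avoid the package's log-gamma/lookup-table code paths: small-number
# products, explicit loops, numerically differentiated optimization.

# Dirichlet-multinomial pmf via rising factorials (Pochhammer products);
# exact for small counts.
oracleDM <- function(x, alpha) {
  poch <- function(a, n) if (n == 0) 1 else prod(a + 0:(n - 1))
  n <- sum(x)
  coef <- factorial(n) / prod(factorial(x))
  coef * prod(mapply(poch, alpha, x)) / poch(sum(alpha), n)
}

# log-space variant (sums of logs of rising-factorial terms), safe for
# large alpha or counts
logOracleDM <- function(x, alpha) {
  logPoch <- function(a, n) if (n == 0) 0 else sum(log(a + 0:(n - 1)))
  n <- sum(x)
  sum(log(seq_len(n))) - sum(unlist(lapply(x, function(xi)
    sum(log(seq_len(xi)))))) +
    sum(mapply(logPoch, alpha, x)) - logPoch(sum(alpha), n)
}

# all count vectors of length L summing to n
allCompositions <- function(n, L) {
  if (L == 1) return(matrix(n, ncol = 1))
  out <- NULL
  for (k in 0:n) {
    sub <- allCompositions(n - k, L - 1)
    out <- rbind(out, cbind(k, sub))
  }
  unname(out)
}

# brute-force responsibilities by explicit summation over (k, s, f)
oracleResponsibilities <- function(countsList, alpha, piK, xi, zeta, L) {
  N <- nrow(countsList[[1]])
  K <- dim(alpha)[3]
  S <- length(xi)
  resp <- array(0, dim = c(N, K, S, 2))
  for (i in seq_len(N)) {
    for (k in seq_len(K)) {
      for (s in seq_len(S)) {
        for (f in 1:2) {
          lik <- 1
          for (m in seq_along(countsList)) {
            w <- alpha[s:(s + L - 1), m, k]
            if (f == 2) w <- rev(w)
            lik <- lik * oracleDM(countsList[[m]][i, ], w)
          }
          resp[i, k, s, f] <- piK[k] * xi[s] * zeta[f] * lik
        }
      }
    }
  }
  for (i in seq_len(N)) resp[i, , , ] <- resp[i, , , ] / sum(resp[i, , , ])
  resp
}

# observed-data log-likelihood by explicit summation (proper pmf)
oracleLogLik <- function(countsList, alpha, piK, xi, zeta, L) {
  N <- nrow(countsList[[1]])
  K <- dim(alpha)[3]
  S <- length(xi)
  total <- 0
  for (i in seq_len(N)) {
    acc <- 0
    for (k in seq_len(K)) {
      for (s in seq_len(S)) {
        for (f in 1:2) {
          lik <- 1
          for (m in seq_along(countsList)) {
            w <- alpha[s:(s + L - 1), m, k]
            if (f == 2) w <- rev(w)
            lik <- lik * oracleDM(countsList[[m]][i, ], w)
          }
          acc <- acc + piK[k] * xi[s] * zeta[f] * lik
        }
      }
    }
    total <- total + log(acc)
  }
  total
}

# independent single-feature DMM EM (no shift/flip, near-flat prior):
# naive E-step plus numerically differentiated BFGS M-step on log(alpha)
oracleEM <- function(X, alpha0, pi0, nIter = 200, tol = 1e-12,
                     eta = 1, nu = 1e-8) {
  N <- nrow(X)
  K <- ncol(alpha0)  # alpha0: L x K
  L <- ncol(X)
  alpha <- alpha0
  piK <- pi0
  ll <- function(a, w) {
    # weighted DM log-lik of all loci under one component, weights w
    s <- 0
    for (i in seq_len(N)) {
      s <- s + w[i] * logOracleDM(X[i, ], a)
    }
    s
  }
  prevQ <- -Inf
  resp <- NULL
  for (it in seq_len(nIter)) {
    # E-step
    lik <- sapply(seq_len(K), function(k) {
      vapply(seq_len(N), function(i) exp(logOracleDM(X[i, ], alpha[, k])),
             numeric(1))
    })
    num <- sweep(lik, 2, piK, `*`)
    resp <- num / rowSums(num)
    q <- sum(log(rowSums(num)))
    if (is.finite(prevQ) && abs(q - prevQ) / abs(q) < tol) break
    prevQ <- q
    # M-step
    piK <- colMeans(resp)
    for (k in seq_len(K)) {
      obj <- function(lam) {
        a <- exp(lam)
        -(ll(a, resp[, k]) +
            sum((eta - 1) * log(a) - nu * a) + sum(lam))
      }
      opt <- optim(log(alpha[, k]), obj, method = "BFGS",
                   control = list(maxit = 200, reltol = 1e-12))
      alpha[, k] <- exp(opt$par)
    }
  }
  list(resp = resp, alpha = alpha, pi = piK)
}

# small simulated two-cluster dataset used across tests
makeTestData <- function(N = 80, L = 20, M = 1, coverages = 100, seed = 1) {
  simulateDMM(twoClusterAlpha(L = L, M = M), c(0.5, 0.5),
              coverages = coverages, N = N, seed = seed)
}
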