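test_that("E-step reduces to Bayes rule verified by explicit summation", {
  set.seed(13)
  # degenerate single component: all responsibilities exactly 1
  sim1 <- makeTestData(N = 10, L = 8, seed = 2)
  m1 <- MixtureModel(array(runif(8, 0.5, 2), c(8, 1, 1)), pi = 1,
                     config = ShiftFlipConfig(binSize = 40L))
  r1 <- eStep(sim1$dataset, m1)
  expect_equal(as.vector(r1[, 1, 1, 1]), rep(1, 10))
  # two identical components split every locus exactly 0.5/0.5
  aSame <- array(rep(runif(8, 0.5, 2), 2), c(8, 1, 2))
  m2 <- MixtureModel(aSame, pi = c(0.5, 0.5),
                     config = ShiftFlipConfig(binSize = 40L))
  r2 <- eStep(sim1$dataset, m2)
  expect_equal(as.vector(r2[, 1, 1, 1]), rep(0.5, 10))
  # 3-locus, 2-component, S=3, flip on: brute-force oracle
  L <- 5
  cfg <- ShiftFlipConfig(shift = TRUE, flip = TRUE, maxShiftBp = 40,
                         binSize = 40)
  S <- nShiftStates(cfg)
  alpha <- array(runif((L + S - 1) * 1 * 2, 0.3, 3), c(L + S - 1, 1, 2))
  X <- matrix(rpois(3 * L, 2), nrow = 3)
  ds <- ChromatinExperiment(list(f1 = X), binSize = 40)
  piK <- c(0.3, 0.7)
  xi <- pyramidShiftPrior(S)
  model <- MixtureModel(alpha, piK, cfg, L = L, xi = xi)
  got <- eStep(ds, model)
  want <- oracleResponsibilities(list(X), alpha, piK, xi, c(0.5, 0.5), L)
  expect_equal(got, want, tolerance = 1e-10)
  # normalization invariant
  expect_equal(apply(got, 1, sum), rep(1, 3), tolerance = 1e-8)
})

test_that("weight update is the responsibility column mean", {
  r <- array(0, c(4, 2, 1, 2))
  r[, 1, 1, 1] <- 1
  expect_equal(mStepWeights(r), c(1, 0))
  rU <- array(1 / 4, c(5, 2, 1, 2))
  expect_equal(mStepWeights(rU), c(0.5, 0.5))
  set.seed(4)
  rR <- array(runif(6 * 3 * 2 * 2), c(6, 3, 2, 2))
  for (i in 1:6) rR[i, , , ] <- rR[i, , , ] / sum(rR[i, , , ])
  byHand <- numeric(3)
  for (k in 1:3) for (i in 1:6) byHand[k] <- byHand[k] + sum(rR[i, k, , ])
  expect_equal(mStepWeights(rR), byHand / 6, tolerance = 1e-12)
})

test_that("alpha update tracks empirical proportions and its gradient vanishes", {
  # strongly-weighted smooth profile, weak priors: DM mean ~ proportions
  L <- 10
  prof <- c(1, 2, 5, 9, 12, 12, 9, 5, 2, 1)
  X <- matrix(rep(prof * 10, 6), nrow = 6, byrow = TRUE)
  ds <- ChromatinExperiment(list(f1 = X), binSize = 40)
  hyperWeak <- Hyperparameters(eta = 1, nu = 1e-6, regularize = FALSE)
  resp <- array(1, c(6, 1, 1, 2)) * rep(c(1, 0), each = 6)
  dim(resp) <- c(6, 1, 1, 2)
  m <- MixtureModel(array(rep(1, L) + 0.01 * seq_len(L), c(L, 1, 1)),
                    pi = 1, config = ShiftFlipConfig(binSize = 40L))
  aNew <- mStepAlpha(ds, resp, m, hyperWeak, maxit = 400)
  expect_equal(as.vector(aNew[, 1, 1] / sum(aNew[, 1, 1])),
               prof / sum(prof), tolerance = 0.05)
  # first-order condition at the optimum
  W <- matrix(resp[, 1, , 1], nrow = 6)
  tab <- ProfileDMM:::mStepTables(X, W)
  tab$IDX <- ProfileDMM:::windowIndexMatrix(1L, 1L, L)
  gLik <- ProfileDMM:::blockLikValueGrad(aNew[, 1, 1], tab, 1L, 1L)$grad
  gPri <- ProfileDMM:::gradLogPriorAlphaBlock(aNew[, 1, 1], hyperWeak)
  gLam <- aNew[, 1, 1] * (gLik + gPri) + 1
  expect_lt(max(abs(gLam)), 1e-3)
})

test_that("stronger smoothness prior flattens the fitted profile", {
  set.seed(17)
  L <- 12
  X <- matrix(rpois(8 * L, c(1, 1, 2, 6, 14, 20, 20, 14, 6, 2, 1, 1)),
              nrow = 8, byrow = TRUE)
  ds <- ChromatinExperiment(list(f1 = X), binSize = 40)
  resp <- array(1, c(8, 1, 1, 2)) * rep(c(1, 0), each = 8)
  dim(resp) <- c(8, 1, 1, 2)
  m <- MixtureModel(array(1 + 0.01 * seq_len(L), c(L, 1, 1)), pi = 1,
                    config = ShiftFlipConfig(binSize = 40L))
  rough <- function(a) max(a) - min(a)
  hW <- Hyperparameters(etaH = 10, nuH = 10)         # h prior mean 1
  hS <- Hyperparameters(etaH = 10, nuH = 1e4)        # h prior mean 1e-3
  aW <- mStepAlpha(ds, resp, m, hW, maxit = 300)[, 1, 1]
  aS <- mStepAlpha(ds, resp, m, hS, maxit = 300)[, 1, 1]
  expect_lt(smoothnessTerm(aS), smoothnessTerm(aW))
  expect_lt(rough(aS), rough(aW))
})

test_that("initialization separates clear clusters and is deterministic", {
  sim <- makeTestData(N = 120, L = 20, M = 2, coverages = 100, seed = 6)
  init <- initializeDMM(sim$dataset, K = 2, seed = 3)
  memb <- apply(init$responsibilities, c(1, 2), sum)
  hard <- max.col(memb)
  agree <- alignClusterLabels(sim$truth$labels, hard)$agreement
  expect_gte(agree, 0.9)
  # identical seed: bit-identical; K = 1: all mass on the single cluster
  init2 <- initializeDMM(sim$dataset, K = 2, seed = 3)
  expect_identical(init$responsibilities, init2$responsibilities)
  expect_identical(init$model@alpha, init2$model@alpha)
  init1 <- initializeDMM(sim$dataset, K = 1, seed = 3)
  expect_equal(apply(init1$responsibilities, c(1, 2), sum),
               matrix(1, 120, 1))
  expect_error(initializeDMM(sim$dataset, K = 200, seed = 1), "between")
})

test_that("EM fit is deterministic, monotone and degenerate-safe", {
  sim <- makeTestData(N = 60, L = 12, seed = 10)
  fit1 <- fitDMM(sim$dataset, K = 1, nRestarts = 1, seed = 5)
  expect_equal(mixtureWeights(fit1), 1)
  expect_true(fit1@converged)
  fit2a <- fitDMM(sim$dataset, K = 2, nRestarts = 2, seed = 5)
  fit2b <- fitDMM(sim$dataset, K = 2, nRestarts = 2, seed = 5)
  expect_identical(lowerBoundTrace(fit2a), lowerBoundTrace(fit2b))
  tr <- lowerBoundTrace(fit2a)
  expect_true(all(diff(tr) >= -1e-6 * abs(tr[-1])))
  expect_equal(apply(responsibilities(fit2a), 1, sum), rep(1, 60),
               tolerance = 1e-8)
})

test_that("package EM agrees with an independent brute-force DMM EM", {
  # single feature, no shift/flip, near-flat prior; both EMs run from the
  # same starting point to tight convergence
  set.seed(31)
  L <- 5
  N <- 16
  aTrue <- cbind(c(6, 3, 1, 0.5, 0.5), c(0.5, 0.5, 1, 3, 6))
  X <- matrix(0, N, L)
  lab <- rep(1:2, each = N / 2)
  for (i in 1:N) {
    p <- aTrue[, lab[i]] / sum(aTrue[, lab[i]])
    X[i, ] <- rmultinom(1, 40, p)
  }
  ds <- ChromatinExperiment(list(f1 = X), binSize = 40)
  hyperFlat <- Hyperparameters(eta = 1, nu = 1e-8, regularize = FALSE)
  cfg <- ShiftFlipConfig(binSize = 40L)
  alpha0 <- cbind(1 + 0.2 * (1:L), 2 - 0.2 * (1:L))
  pi0 <- c(0.5, 0.5)
  # package path via the exported EM operations
  model <- MixtureModel(array(alpha0, c(L, 1, 2)), pi0, cfg)
  for (it in 1:60) {
    r <- eStep(ds, model)
    model@alpha <- mStepAlpha(ds, r, model, hyperFlat, maxit = 300)
    model@pi <- mStepWeights(r)
  }
  rPkg <- apply(eStep(ds, model), c(1, 2), sum)
  # oracle path
  or <- oracleEM(X, alpha0, pi0, nIter = 60, eta = 1, nu = 1e-8)
  expect_equal(rPkg, or$resp, tolerance = 1e-6, ignore_attr = TRUE)
})
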