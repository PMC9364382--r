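respFromScore <- function(score) {
  # N x 2 x 1 x 2 tensor whose cluster-1 marginal equals `score`
  N <- length(score)
  r <- array(0, c(N, 2, 1, 2))
  r[, 1, 1, 1] <- score
  r[, 2, 1, 1] <- 1 - score
  r
}

test_that("clustering AUC matches the rank-based oracle and is invariant", {
  labels <- c(1, 1, 1, 2, 2, 2)
  # one-hot posteriors: perfect separation
  expect_equal(clusteringAUC(labels, respFromScore(c(1, 1, 1, 0, 0, 0))), 1)
  # uninformative posteriors
  expect_equal(clusteringAUC(labels, respFromScore(rep(0.5, 6))), 0.5)
  # hand-set posteriors vs brute-force Mann-Whitney over all pairs
  score <- c(0.9, 0.62, 0.55, 0.6, 0.3, 0.21)
  pairs <- expand.grid(i = which(labels == 1), j = which(labels == 2))
  mw <- mean(ifelse(score[pairs$i] > score[pairs$j], 1,
                    ifelse(score[pairs$i] == score[pairs$j], 0.5, 0)))
  expect_equal(clusteringAUC(labels, respFromScore(score)), max(mw, 1 - mw))
  # invariance: relabelling and monotone transform of scores
  expect_equal(clusteringAUC(labels, respFromScore(1 - score)),
               clusteringAUC(labels, respFromScore(score)))
  expect_equal(clusteringAUC(labels, respFromScore(score^3)),
               clusteringAUC(labels, respFromScore(score)))
  expect_error(clusteringAUC(rep(1, 6), respFromScore(score)), "two")
})

test_that("shift error averages absolute bp differences with mirroring", {
  truth <- list(shiftBp = c(0, 40, -40, 80), flipStates = c(1, 1, 1, 1))
  asgPerfect <- data.frame(cluster = 1L, shiftBp = truth$shiftBp,
                           flipState = 1L)
  expect_equal(shiftError(truth, asgPerfect), 0)
  asgOff <- data.frame(cluster = 1L, shiftBp = truth$shiftBp + 40,
                       flipState = 1L)
  expect_equal(shiftError(truth, asgOff), 40)
  # mixed errors equal the hand-summed average
  asgMix <- data.frame(cluster = 1L, shiftBp = c(0, -40, -40, 200),
                       flipState = 1L)
  expect_equal(shiftError(truth, asgMix), mean(c(0, 80, 0, 120)))
  # a flip-inverted cluster mirrors its inferred shifts before differencing
  truthF <- list(shiftBp = c(40, 80), flipStates = c(1, 2))
  asgInv <- data.frame(cluster = 1L, shiftBp = c(-40, -80),
                       flipState = c(2L, 1L))
  fi <- flipError(truthF, asgInv)
  expect_equal(fi$error, 0)  # inversion-corrected
  expect_equal(shiftError(truthF, asgInv, flipInversion = fi), 0)
})

test_that("flip error is inversion-corrected per cluster", {
  truth <- list(flipStates = c(1, 2, 1, 2, 1, 2))
  all_right <- data.frame(cluster = rep(1L, 6),
                          flipState = truth$flipStates)
  expect_equal(flipError(truth, all_right)$error, 0)
  inverted <- data.frame(cluster = rep(1L, 6),
                         flipState = 3L - truth$flipStates)
  fe <- flipError(truth, inverted)
  expect_equal(fe$error, 0)
  expect_true(fe$inverted[["1"]])
  # worst case: an inversion-symmetric half-mismatch stays at 0.5
  truthH <- list(flipStates = c(1L, 2L, 1L, 2L))
  half <- data.frame(cluster = rep(1L, 4),
                     flipState = c(1L, 1L, 2L, 2L))
  expect_equal(flipError(truthH, half)$error, 0.5)
  # two clusters, each corrected independently, weighted by size
  truth2 <- list(flipStates = rep(1L, 10))
  asg2 <- data.frame(cluster = rep(c(1L, 2L), c(8, 2)),
                     flipState = c(rep(1L, 8), 2L, 2L))
  expect_equal(flipError(truth2, asg2)$error, 0)  # cluster 2 inverts
})

test_that("label alignment finds the best permutation", {
  truthLab <- c(1, 1, 2, 2, 3, 3)
  inf <- c(3, 3, 1, 1, 2, 2)  # cyclic relabelling, perfect clustering
  al <- alignClusterLabels(truthLab, inf)
  expect_equal(al$agreement, 1)
  expect_equal(al$aligned, truthLab)
})

test_that("aggregate profiles average realigned members and correlate", {
  X <- rbind(c(5, 0, 0, 0), c(0, 0, 0, 7), c(2, 4, 0, 0), c(0, 4, 2, 0))
  ds <- ChromatinExperiment(list(f1 = X), binSize = 40)
  asg <- data.frame(locus = 1:4, cluster = c(1L, 1L, 2L, 2L),
                    clusterPosterior = 1, shiftState = 1L,
                    shiftBp = 0L, flipState = 1L)
  out <- aggregateProfiles(ds, asg)
  expect_equal(out$aggregates[, 1, 1], colMeans(X[1:2, ]))
  expect_equal(out$aggregates[, 1, 2], colMeans(X[3:4, ]))
  # correlation of a profile with itself is 1 after label alignment
  tr <- array(0, c(4, 1, 2))
  tr[, 1, 1] <- colMeans(X[3:4, ])  # true labels swapped vs inferred
  tr[, 1, 2] <- colMeans(X[1:2, ])
  out2 <- aggregateProfiles(ds, asg, trueAggregates = tr,
                            truthLabels = c(2, 2, 1, 1))
  expect_equal(as.vector(out2$correlations), c(1, 1), tolerance = 1e-12)
  # single-locus clusters return that locus's (realigned) profile
  asg1 <- asg
  asg1$cluster <- c(1L, 2L, 3L, 4L)
  out3 <- aggregateProfiles(ds, asg1)
  for (i in 1:4) expect_equal(out3$aggregates[, 1, i], X[i, ])
  # empty cluster warns and yields zeros
  expect_warning(aggregateProfiles(ds, asg, K = 3), "empty")
})

test_that("metrics are pure functions of their inputs", {
  set.seed(30)
  truth <- list(labels = rep(1:2, each = 10),
                shiftBp = sample(seq(-80, 80, 40), 20, TRUE),
                flipStates = sample(1:2, 20, TRUE))
  asg <- data.frame(cluster = sample(1:2, 20, TRUE),
                    shiftBp = sample(seq(-80, 80, 40), 20, TRUE),
                    flipState = sample(1:2, 20, TRUE))
  fe1 <- flipError(truth, asg)
  fe2 <- flipError(truth, asg)
  expect_identical(fe1, fe2)
  expect_identical(shiftError(truth, asg, flipInversion = fe1),
                   shiftError(truth, asg, flipInversion = fe2))
})
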