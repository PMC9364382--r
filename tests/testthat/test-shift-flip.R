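test_that("window extraction slices and reverses the extended parameters", {
  a <- c(1, 2, 3, 4, 5)
  expect_equal(extractWindow(a, s = 1, f = 1, L = 5), a)
  expect_equal(extractWindow(a, s = 2, f = 1, L = 3), c(2, 3, 4))
  expect_equal(extractWindow(a, s = 2, f = 2, L = 3), c(4, 3, 2))
  expect_error(extractWindow(a, s = 4, f = 1, L = 3), "out of range")
  expect_error(extractWindow(a, s = 1, f = 3, L = 3), "flip")
  # flip is exactly reversal, for every shift state
  for (s in 1:3) {
    expect_equal(extractWindow(a, s, 2, 3), rev(extractWindow(a, s, 1, 3)))
  }
})

test_that("shift-state arithmetic and the pyramid prior behave as defined", {
  cfg <- ShiftFlipConfig(shift = TRUE, maxShiftBp = 400, binSize = 40)
  expect_identical(nShiftStates(cfg), 21L)
  expect_identical(ProfileDMM:::noShiftState(21L), 11L)
  expect_equal(pyramidShiftPrior(1), 1)
  expect_equal(pyramidShiftPrior(3), c(0.25, 0.5, 0.25))
  p21 <- pyramidShiftPrior(21)
  expect_equal(which.max(p21), 11)
  expect_equal(sum(p21), 1)
  expect_equal(p21, rev(p21))
  expect_error(pyramidShiftPrior(4), "odd")
  expect_error(ShiftFlipConfig(shift = TRUE, maxShiftBp = 90, binSize = 40),
               "multiple")
})

test_that("hard assignment marginalizes cluster, then flip, then shift", {
  cfgPlain <- ShiftFlipConfig(binSize = 40L)
  # degenerate
  r <- array(1, c(3, 1, 1, 2)) * rep(c(1, 0), each = 3)
  dim(r) <- c(3, 1, 1, 2)
  asg <- computeHardAssignments(r, cfgPlain)
  expect_equal(asg$cluster, rep(1L, 3))
  expect_equal(asg$shiftState, rep(1L, 3))
  expect_equal(asg$flipState, rep(1L, 3))
  # point mass at (k=2, s=1, f=2)
  cfgFlip <- ShiftFlipConfig(flip = TRUE, binSize = 40L)
  r2 <- array(0, c(1, 2, 1, 2))
  r2[1, 2, 1, 2] <- 1
  asg2 <- computeHardAssignments(r2, cfgFlip)
  expect_equal(asg2$cluster, 2L)
  expect_equal(asg2$flipState, 2L)
  expect_equal(asg2$shiftState, 1L)
  # dense random tensor vs explicit summation of the marginalization rules
  set.seed(5)
  cfgSF <- ShiftFlipConfig(shift = TRUE, flip = TRUE, maxShiftBp = 80,
                           binSize = 40)
  S <- nShiftStates(cfgSF)
  r3 <- array(runif(4 * 3 * S * 2), c(4, 3, S, 2))
  for (i in 1:4) r3[i, , , ] <- r3[i, , , ] / sum(r3[i, , , ])
  asg3 <- computeHardAssignments(r3, cfgSF)
  for (i in 1:4) {
    margK <- numeric(3)
    for (k in 1:3) margK[k] <- sum(r3[i, k, , ])
    k <- which.max(margK)
    margF <- c(sum(r3[i, k, , 1]), sum(r3[i, k, , 2]))
    f <- which.max(margF)
    margS <- vapply(seq_len(S), function(s) sum(r3[i, k, s, ]), numeric(1))
    s <- which.max(margS)
    expect_equal(asg3$cluster[i], k)
    expect_equal(asg3$flipState[i], f)
    expect_equal(asg3$shiftState[i], s)
    expect_equal(asg3$shiftBp[i],
                 (ProfileDMM:::noShiftState(S) - s) * 40)
  }
  expect_error(computeHardAssignments(r3 * 2, cfgSF), "sum to 1")
})

test_that("realignment is the identity at no-shift and inverts known states", {
  X <- rbind(c(0, 0, 5, 0, 0), c(1, 2, 3, 4, 5))
  ds <- ChromatinExperiment(list(f1 = X), binSize = 40)
  asgId <- data.frame(locus = 1:2, cluster = 1L, clusterPosterior = 1,
                      shiftState = 1L, shiftBp = 0L, flipState = 1L)
  expect_equal(counts(realignProfiles(ds, asgId))[[1]], X,
               ignore_attr = TRUE)
  # pattern displaced one bin downstream (shiftBp = +40): realignment
  # translates it back upstream
  asgShift <- asgId
  asgShift$shiftBp <- c(40L, 0L)
  out <- counts(realignProfiles(ds, asgShift))[[1]]
  expect_equal(out[1, ], c(0, 5, 0, 0, 0))
  expect_equal(out[2, ], X[2, ])
  # flip state 2: reversal happens before the translation
  asgFlip <- asgId
  asgFlip$flipState <- c(2L, 1L)
  expect_equal(counts(realignProfiles(ds, asgFlip))[[1]][1, ],
               rev(X[1, ]))
})

test_that("corrupting with known states then realigning restores profiles", {
  # interior-supported profiles: translation cannot push counts off-window
  L <- 30
  a <- makeSmoothAlpha(L, list(c(15, 2, 8)), baseline = 1e-4)
  sim <- simulateDMM(array(a, c(L, 1, 1)), 1, coverages = 200, N = 12,
                     seed = 8)
  cs <- corruptShiftFlip(sim$dataset, sim$truth, maxShiftBp = 120,
                         binSize = 40, seed = 9)
  S <- 2 * 3 + 1
  asg <- data.frame(locus = 1:12, cluster = 1L, clusterPosterior = 1,
                    shiftState = cs$truth$shiftStates,
                    shiftBp = cs$truth$shiftBp,
                    flipState = cs$truth$flipStates)
  restored <- counts(realignProfiles(cs$dataset, asg))[[1]]
  orig <- counts(sim$dataset)[[1]]
  # compare away from the edges (zero-fill region)
  inner <- 5:(L - 4)
  expect_equal(restored[, inner], orig[, inner], ignore_attr = TRUE)
})

test_that("translated data is likelihood-equivalent to the mirrored window", {
  # data displaced by t bins, evaluated under window s0 - t, pairs every
  # count with the same parameter as the original data under the centre
  # window (exactly, when no count is pushed off the window)
  L <- 6
  S <- 3
  s0 <- ProfileDMM:::noShiftState(S)
  # wrap the extension so every window has the same parameter total;
  # otherwise the DM normalization term differs at the extension edges
  base <- makeSmoothAlpha(L, list(c(4, 1.5, 5)), baseline = 0.3)
  aExt <- c(base, base[1:2])
  x <- c(0, 0, 4, 9, 2, 0)  # interior support: |t| <= 1 drops nothing
  llOrig <- logDirichletMultinomial(x, extractWindow(aExt, s0, 1, L))
  for (t in -1:1) {
    xShift <- ProfileDMM:::translateProfile(x, t)
    llMirror <- logDirichletMultinomial(xShift,
                                        extractWindow(aExt, s0 - t, 1, L))
    expect_equal(llMirror, llOrig, tolerance = 1e-9)
  }
  # the flipped frame: reversed data under the reversed window, with the
  # shift state mirrored about the centre
  xFlip <- rev(ProfileDMM:::translateProfile(x, 1))
  expect_equal(logDirichletMultinomial(xFlip,
                                       extractWindow(aExt, s0 - 1, 2, L)),
               llOrig, tolerance = 1e-9)
})
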