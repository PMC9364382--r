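#' Smooth synthetic Dirichlet parameter profile
#'
#' Sum of Gaussian bumps on a strictly positive baseline; deterministic.
#' Used to build ground-truth component parameters whose mean profiles
#' resemble chromatin coverage motifs (peaks, flanked valleys).
#'
#' @param L Profile length in bins.
#' @param peaks List of \code{c(center, width, height)} triples (bins /
#'   bins / alpha units); may be empty.
#' @param baseline Positive baseline alpha value.
#' @return Positive numeric vector of length L.
#' @examples
#' a <- makeSmoothAlpha(50, list(c(25, 5, 3)), baseline = 0.2)
#' which.max(a)  # 25
#' @export
makeSmoothAlpha <- function(L, peaks = list(), baseline = 0.2) {
  if (baseline <= 0) stop("'baseline' must be > 0")
  a <- rep(baseline, L)
  j <- seq_len(L)
  for (p in peaks) {
    a <- a + p[3] * exp(-(j - p[1])^2 / (2 * p[2]^2))
  }
  a
}

#' Two-cluster ground-truth parameters
#'
#' A deterministic fixture of smooth Dirichlet parameters for K = 2
#' components and M features: component 1 has a central valley flanked by
#' two peaks of unequal height (nucleosome-phased histone-modification-like
#' motif, asymmetric as expected around directional elements), component 2
#' a single asymmetric off-centre peak (directional
#' polymerase-occupancy-like motif). The asymmetry makes strand
#' orientation identifiable. Feature copies are slightly rescaled so
#' features are not identical.
#'
#' @param L Profile length in bins.
#' @param M Number of features.
#' @return L x M x 2 array of positive Dirichlet parameters.
#' @export
twoClusterAlpha <- function(L = 50, M = 2) {
  a1 <- makeSmoothAlpha(L, list(c(0.32 * L, 0.07 * L, 3.2),
                                c(0.68 * L, 0.07 * L, 1.6)), baseline = 0.15)
  a2 <- makeSmoothAlpha(L, list(c(0.40 * L, 0.08 * L, 4),
                                c(0.58 * L, 0.16 * L, 1.2)),
                        baseline = 0.15)
  out <- array(NA_real_, dim = c(L, M, 2L))
  for (m in seq_len(M)) {
    sc <- 1 + 0.15 * (m - 1)
    out[, m, 1L] <- a1 * sc
    out[, m, 2L] <- a2 * sc
  }
  out
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) <= 0) {
    # extremely small shapes can underflow to all zeros; fall back to the
    # normalized shapes (the Dirichlet mean)
    return(alpha / sum(alpha))
  }
  g / sum(g)
}

#' Simulate counts from the product Dirichlet-multinomial mixture
#'
#' Ancestral sampling of the generative model: each locus draws a cluster
#' from \code{piTrue}, then for each feature a probability vector from
#' Dirichlet(alpha) and counts from Multinomial(coverage, p). Every
#' locus/feature profile sums exactly to the feature's coverage, so no
#' all-zero loci occur.
#'
#' @param alphaTrue L x M x K array of positive Dirichlet parameters (an
#'   L x M matrix is promoted to K = 1).
#' @param piTrue Mixture weight simplex of length K.
#' @param coverages Integer vector of per-feature sequencing coverages
#'   (total reads per locus); recycled to M.
#' @param N Number of loci.
#' @param binSize Bin width in bp for the returned dataset.
#' @param featureNames Optional character vector of length M.
#' @param seed Integer seed.
#' @return List with \code{dataset} (a [ChromatinExperiment]) and
#'   \code{truth} (list: \code{labels}, \code{shiftBins},
#'   \code{flipStates}, \code{alphaTrue}, \code{coverages}); shifts are 0
#'   and flips 1 until [corruptShiftFlip()] is applied.
#' @export
simulateDMM <- function(alphaTrue, piTrue, coverages, N, binSize = 40L,
                        featureNames = NULL, seed = 1L) {
  if (length(dim(alphaTrue)) == 2L) {
    alphaTrue <- array(alphaTrue, dim = c(dim(alphaTrue), 1L))
  }
  L <- dim(alphaTrue)[1]
  M <- dim(alphaTrue)[2]
  K <- dim(alphaTrue)[3]
  if (length(piTrue) != K || any(piTrue < 0) ||
      abs(sum(piTrue) - 1) > 1e-8) {
    stop("'piTrue' must be a length-K probability vector")
  }
  coverages <- as.integer(rep_len(coverages, M))
  if (any(coverages < 1L)) stop("coverages must be >= 1")
  if (is.null(featureNames)) featureNames <- paste0("feature", seq_len(M))
  set.seed(seed)
  labels <- sample.int(K, N, replace = TRUE, prob = piTrue)
  countsList <- lapply(seq_len(M), function(m) {
    X <- matrix(0, nrow = N, ncol = L)
    for (i in seq_len(N)) {
      p <- rdirichlet1(alphaTrue[, m, labels[i]])
      X[i, ] <- stats::rmultinom(1L, size = coverages[m], prob = p)
    }
    X
  })
  names(countsList) <- featureNames
  dataset <- ChromatinExperiment(countsList, binSize = binSize)
  list(dataset = dataset,
       truth = list(labels = labels, shiftBins = rep(0L, N),
                    flipStates = rep(1L, N), alphaTrue = alphaTrue,
                    coverages = coverages))
}

#' Simulate low-coverage Gaussian-profile clusters
#'
#' Two-or-more-cluster generator for sparse single-feature data: each
#' cluster has a Gaussian-shaped expected profile (unit-normalized shape
#' times \code{scale} expected total reads, times the coverage factor
#' \code{f}), and bin counts are independent Poisson draws. Profiles are
#' oversampled and all-zero draws rejected until \code{NPerCluster} non-zero
#' profiles per cluster are collected, so the returned dataset contains no
#' zero vectors.
#'
#' @param NPerCluster Non-zero profiles to collect per cluster.
#' @param f Coverage factor (e.g. 0.5 or 1) scaling all expected counts.
#' @param L Profile length in bins.
#' @param clusterSpecs List of per-cluster lists with elements \code{mean}
#'   (mode bin), \code{sd} (bins) and \code{scale} (expected total reads at
#'   f = 1). Default: two overlapping clusters with differing means and
#'   spreads.
#' @param binSize Bin width in bp.
#' @param seed Integer seed.
#' @param maxDraws Error if a cluster needs more than this many draws.
#' @return List with \code{dataset} (single-feature
#'   [ChromatinExperiment]) and \code{truth} as in [simulateDMM()].
#' @export
simulateGaussianLowCoverage <- function(NPerCluster = 1000L, f = 1,
                                        L = 50L,
                                        clusterSpecs = list(
                                          list(mean = 0.45 * L, sd = 0.08 * L,
                                               scale = 2),
                                          list(mean = 0.55 * L, sd = 0.14 * L,
                                               scale = 2)),
                                        binSize = 40L, seed = 1L,
                                        maxDraws = 1e6) {
  if (f <= 0) stop("'f' must be > 0")
  set.seed(seed)
  j <- seq_len(L)
  rows <- list()
  labels <- integer(0)
  for (k in seq_along(clusterSpecs)) {
    sp <- clusterSpecs[[k]]
    shape <- exp(-(j - sp$mean)^2 / (2 * sp$sd^2))
    rate <- f * sp$scale * shape / sum(shape)
    if (sum(rate) < 1e-8) {
      stop("expected profile is numerically zero; rejection would not ",
           "terminate")
    }
    got <- 0L
    drawn <- 0L
    keep <- matrix(0, nrow = NPerCluster, ncol = L)
    while (got < NPerCluster) {
      batch <- min(4L * NPerCluster, 1e5)
      drawn <- drawn + batch
      if (drawn > maxDraws) {
        stop(sprintf("cluster %d: exceeded %g draws while rejecting ",
                     k, maxDraws), "all-zero profiles")
      }
      X <- matrix(stats::rpois(batch * L, lambda = rep(rate, each = batch)),
                  nrow = batch)
      nz <- which(rowSums(X) > 0)
      take <- utils::head(nz, NPerCluster - got)
      if (length(take)) {
        keep[(got + 1L):(got + length(take)), ] <- X[take, , drop = FALSE]
        got <- got + length(take)
      }
    }
    rows[[k]] <- keep
    labels <- c(labels, rep(k, NPerCluster))
  }
  X <- do.call(rbind, rows)
  dataset <- ChromatinExperiment(list(signal = X), binSize = binSize)
  list(dataset = dataset,
       truth = list(labels = labels, shiftBins = rep(0L, nrow(X)),
                    flipStates = rep(1L, nrow(X)), alphaTrue = NULL,
                    coverages = NA_integer_))
}

#' Skellam random deviates
#'
#' Difference of two independent Poisson(mu) draws: symmetric around 0 with
#' variance 2 * mu.
#'
#' @param n Number of deviates.
#' @param mu Common rate of the two Poisson components.
#' @return Integer vector of length n.
#' @export
rskellam <- function(n, mu) {
  stats::rpois(n, mu) - stats::rpois(n, mu)
}

#' Corrupt a dataset with random shifts and flips
#'
#' Per locus, a shift in bins is drawn from a mean-zero Skellam
#' distribution truncated (by resampling) to |shift| <= maxShiftBp /
#' binSize, and a flip state uniformly from \{1, 2\}. Each profile is then
#' translated by the shift (zero-fill at vacated bins, counts shifted out
#' of the window are dropped) and reversed when flipped; the same states
#' apply to all features of a locus. True states are recorded in the truth
#' list using the package's sign convention: positive shift = pattern
#' displaced towards higher bin indices, i.e. downstream.
#'
#' @param dataset A [ChromatinExperiment].
#' @param truth Truth list from a simulator (labels are carried through).
#' @param maxShiftBp Maximum shift in bp (exact multiple of binSize).
#' @param binSize Bin width in bp; defaults to the dataset's.
#' @param mu Skellam rate; default chooses variance 2*mu so that about 99%
#'   of draws fall within the maximum shift (sd = maxShiftBins / 2.576),
#'   honouring the bounded-support constraint by resampling the rest.
#' @param flip Draw flip states (TRUE) or leave all profiles unflipped.
#' @param seed Integer seed.
#' @return List with the corrupted \code{dataset} and updated \code{truth}
#'   (fields \code{shiftBins}, \code{shiftBp}, \code{shiftStates},
#'   \code{flipStates} filled in).
#' @export
corruptShiftFlip <- function(dataset, truth, maxShiftBp = 400L,
                             binSize = NULL, mu = NULL, flip = TRUE,
                             seed = 1L) {
  if (is.null(binSize)) binSize <- binSize(dataset)
  if (maxShiftBp %% binSize != 0L) {
    stop("maxShiftBp must be an exact multiple of binSize")
  }
  maxBins <- maxShiftBp %/% binSize
  if (is.null(mu)) {
    mu <- if (maxBins > 0) (maxBins / 2.576)^2 / 2 else 0
  }
  set.seed(seed)
  N <- nLoci(dataset)
  shifts <- integer(N)
  if (maxBins > 0 && mu > 0) {
    todo <- seq_len(N)
    while (length(todo)) {
      draw <- rskellam(length(todo), mu)
      ok <- abs(draw) <= maxBins
      shifts[todo[ok]] <- draw[ok]
      todo <- todo[!ok]
    }
  }
  flips <- if (flip) sample(c(1L, 2L), N, replace = TRUE) else rep(1L, N)
  corrupted <- lapply(counts(dataset), function(X) {
    Y <- X
    for (i in seq_len(N)) {
      xi <- translateProfile(X[i, ], shifts[i])
      if (flips[i] == 2L) xi <- rev(xi)
      Y[i, ] <- xi
    }
    Y
  })
  S <- 2L * maxBins + 1L
  truth$shiftBins <- shifts
  truth$shiftBp <- shifts * binSize
  truth$shiftStates <- noShiftState(S) - shifts
  truth$flipStates <- flips
  ds <- ChromatinExperiment(corrupted, binSize = binSize(dataset),
                            windowSize = windowSize(dataset),
                            lociIds = rownames(dataset))
  list(dataset = ds, truth = truth)
}

#' Prior predictive (ancestral) sampling of a dataset
#'
#' Draws component parameters elementwise from the Gamma(eta, nu) part of
#' the prior (the smoothness factor is ignored here: the joint prior is
#' known only up to a constant, and this sampler serves prior predictive
#' checks of count variation, not of smoothness), then simulates counts
#' with [simulateDMM()].
#'
#' @param hyper A [Hyperparameters].
#' @param K,M Number of components and features.
#' @param L Profile length in bins (parameters are drawn at this length).
#' @param coverages Per-feature coverages.
#' @param N Number of loci.
#' @param seed Integer seed.
#' @return As [simulateDMM()], with the drawn alpha in the truth.
#' @export
sampleFromPrior <- function(hyper, K = 2L, M = 1L, L = 50L,
                            coverages = 100L, N = 100L, seed = 1L) {
  set.seed(seed)
  alpha <- array(stats::rgamma(L * M * K, shape = hyper@eta,
                               rate = hyper@nu),
                 dim = c(L, M, K))
  alpha <- pmax(alpha, 1e-8)
  simulateDMM(alpha, rep(1 / K, K), coverages, N,
              seed = seed + 1L)
}
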