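#' Hard cluster/shift/flip assignments from responsibilities
#'
#' For each locus the cluster is chosen by marginalizing shift and flip
#' states, then the flip state by marginalizing shifts within that cluster,
#' then the shift state by marginalizing flips:
#' \deqn{\tilde k_i = \arg\max_k \sum_{s,f} E[z_{iksf}], \quad
#'   \tilde f_i = \arg\max_f \sum_s E[z_{i\tilde k s f}], \quad
#'   \tilde s_i = \arg\max_s \sum_f E[z_{i\tilde k s f}].}
#' Ties are broken deterministically by the lowest index.
#'
#' \code{shiftBp} is the inferred physical displacement of the locus's data
#' pattern relative to the window anchor, \code{((S+1)/2 - s) * binSize} bp:
#' positive values mean the pattern sits downstream of the anchor, and
#' realignment translates the profile by \code{-shiftBp / binSize} bins (see
#' [realignProfiles()]).
#'
#' @param responsibilities N x K x S x 2 array; every locus slice must sum
#'   to 1 (within 1e-6).
#' @param config The [ShiftFlipConfig] the model was fitted with.
#' @return data.frame with columns \code{locus}, \code{cluster},
#'   \code{clusterPosterior}, \code{shiftState}, \code{shiftBp},
#'   \code{flipState}.
#' @export
computeHardAssignments <- function(responsibilities, config) {
  d <- dim(responsibilities)
  if (length(d) != 4L) stop("responsibilities must be N x K x S x 2")
  N <- d[1]
  S <- d[3]
  tot <- apply(responsibilities, 1L, sum)
  if (any(abs(tot - 1) > 1e-6)) {
    stop("responsibilities do not sum to 1 per locus")
  }
  s0 <- noShiftState(S)
  B <- config@binSize
  out <- data.frame(locus = seq_len(N), cluster = NA_integer_,
                    clusterPosterior = NA_real_, shiftState = NA_integer_,
                    shiftBp = NA_integer_, flipState = NA_integer_)
  for (i in seq_len(N)) {
    ri <- responsibilities[i, , , , drop = FALSE]
    dim(ri) <- d[2:4]
    margK <- apply(ri, 1L, sum)
    k <- which.max(margK)
    margF <- apply(ri[k, , , drop = FALSE], 3L, sum)
    f <- which.max(margF)
    margS <- apply(ri[k, , , drop = FALSE], 2L, sum)
    s <- which.max(margS)
    out$cluster[i] <- k
    out$clusterPosterior[i] <- margK[k]
    out$shiftState[i] <- s
    out$shiftBp[i] <- (s0 - s) * B
    out$flipState[i] <- f
  }
  if (!config@flip && any(out$flipState != 1L)) out$flipState <- 1L
  out
}

## Translate a single profile by t bins (t > 0 moves the pattern towards
## higher bin indices); vacated bins are zero-filled, shifted-out counts drop.
translateProfile <- function(x, t) {
  L <- length(x)
  out <- numeric(L)
  if (t >= 0) {
    if (t < L) out[(1L + t):L] <- x[1L:(L - t)]
  } else {
    if (-t < L) out[1L:(L + t)] <- x[(1L - t):L]
  }
  out
}

#' Realign profiles by inferred shift and flip states
#'
#' Undoes the inferred displacement and strand-orientation of every locus,
#' e.g. for visualization of refined aggregate patterns: a profile with flip
#' state 2 is reversed first, then translated by \code{-shiftBp / binSize}
#' bins. Bins shifted out of the window are dropped and vacated bins are
#' zero-filled, so realignment is exact except at the window edges.
#'
#' @param dataset A [ChromatinExperiment].
#' @param assignments data.frame as returned by [computeHardAssignments()]
#'   (or [hardAssignments()]), one row per locus.
#' @return A [ChromatinExperiment] of the same shape with realigned counts.
#' @export
realignProfiles <- function(dataset, assignments) {
  if (nrow(assignments) != nLoci(dataset)) {
    stop("need exactly one assignment per locus")
  }
  B <- binSize(dataset)
  tBins <- -assignments$shiftBp %/% B
  flip <- assignments$flipState == 2L
  aligned <- lapply(counts(dataset), function(X) {
    Y <- X
    for (i in seq_len(nrow(X))) {
      xi <- X[i, ]
      if (flip[i]) xi <- rev(xi)
      Y[i, ] <- translateProfile(xi, tBins[i])
    }
    Y
  })
  dropped <- sum(vapply(counts(dataset), sum, numeric(1))) -
    sum(vapply(aligned, sum, numeric(1)))
  if (dropped > 0) {
    message(sprintf("realignment dropped %g read(s) at window edges",
                    dropped))
  }
  ChromatinExperiment(aligned, binSize = B, windowSize = windowSize(dataset),
                      lociIds = rownames(dataset))
}
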