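#' Align inferred cluster labels to ground truth
#'
#' Exhaustively searches the permutations of the K inferred labels (K <= 7)
#' for the one maximizing agreement with the true labels, the standard
#' correction for label-switching unidentifiability.
#'
#' @param truthLabels Integer vector of true cluster labels (1..K).
#' @param inferred Integer vector of inferred cluster labels (1..K).
#' @param K Number of clusters; defaults to the larger label range.
#' @return List with \code{mapping} (mapping[j] = truth label assigned to
#'   inferred label j), \code{aligned} (remapped inferred labels) and
#'   \code{agreement} (fraction of matching loci).
#' @export
alignClusterLabels <- function(truthLabels, inferred,
                               K = max(truthLabels, inferred)) {
  if (K > 7L) stop("exhaustive label alignment supports K <= 7")
  perms <- allPermutations(K)
  best <- NULL
  bestAgree <- -1
  for (p in perms) {
    agree <- mean(p[inferred] == truthLabels)
    if (agree > bestAgree) {
      bestAgree <- agree
      best <- p
    }
  }
  list(mapping = best, aligned = best[inferred], agreement = bestAgree)
}

#' Clustering AUC for two true clusters
#'
#' Area under the ROC curve of the marginal posterior probability of one
#' cluster, \eqn{\sum_{s,f} E[z_{i1sf}]}, against the binary true labels.
#' Label switching is corrected by taking max(AUC, 1 - AUC), so the value
#' lies in [0.5, 1] and is invariant to relabelling and to strictly
#' monotone transforms of the scores.
#'
#' @param truthLabels Integer vector with exactly two distinct true labels.
#' @param responsibilities N x K x S x 2 responsibility array (or a
#'   [DMMFit]).
#' @return AUC in [0.5, 1].
#' @export
clusteringAUC <- function(truthLabels, responsibilities) {
  if (is(responsibilities, "DMMFit")) {
    responsibilities <- responsibilities@responsibilities
  }
  lv <- sort(unique(truthLabels))
  if (length(lv) != 2L) {
    stop("clusteringAUC requires exactly two true clusters")
  }
  score <- apply(responsibilities[, 1L, , , drop = FALSE], 1L, sum)
  r <- pROC::roc(response = truthLabels, predictor = score, levels = lv,
                 direction = "<", quiet = TRUE)
  a <- as.numeric(pROC::auc(r))
  max(a, 1 - a)
}

#' Flip-state error with inversion correction
#'
#' Proportion of incorrectly inferred flip states. Because flip indices can
#' be globally reversed within a cluster without changing the likelihood,
#' the error of each inferred cluster is computed for both labellings of
#' that cluster's flip states and the smaller is taken; the overall error
#' is the locus-weighted mean, hence always <= 0.5.
#'
#' @param truth Truth list (uses \code{flipStates}).
#' @param assignments Hard-assignment data.frame (columns \code{cluster},
#'   \code{flipState}).
#' @return List with \code{error}, per-cluster \code{byCluster} errors and
#'   \code{inverted} flags (TRUE when the reversed labelling was the better
#'   one), used by [shiftError()] to mirror shifts consistently.
#' @export
flipError <- function(truth, assignments) {
  cl <- assignments$cluster
  fHat <- assignments$flipState
  fTrue <- truth$flipStates
  clusters <- sort(unique(cl))
  byCluster <- numeric(length(clusters))
  inverted <- logical(length(clusters))
  nByCluster <- integer(length(clusters))
  for (j in seq_along(clusters)) {
    idx <- cl == clusters[j]
    errAsIs <- mean(fHat[idx] != fTrue[idx])
    errInv <- mean((3L - fHat[idx]) != fTrue[idx])
    inverted[j] <- errInv < errAsIs
    byCluster[j] <- min(errAsIs, errInv)
    nByCluster[j] <- sum(idx)
  }
  names(byCluster) <- names(inverted) <- clusters
  list(error = sum(byCluster * nByCluster) / sum(nByCluster),
       byCluster = byCluster, inverted = inverted)
}

#' Mean absolute shift error in nucleotides
#'
#' Mean over loci of |true shift - inferred shift| in bp. When a cluster's
#' flip labelling was inversion-corrected (see [flipError()]), the inferred
#' displacements of its loci are mirrored (sign-negated) before
#' differencing, since a flipped frame mirrors shifts.
#'
#' @param truth Truth list (uses \code{shiftBp} or \code{shiftBins}).
#' @param assignments Hard-assignment data.frame (columns \code{cluster},
#'   \code{shiftBp}).
#' @param binSize Bin width in bp (used if the truth stores bins only).
#' @param flipInversion Optional result of [flipError()]; its
#'   \code{inverted} flags trigger the mirroring.
#' @return Mean absolute error in bp.
#' @export
shiftError <- function(truth, assignments, binSize = 40L,
                       flipInversion = NULL) {
  trueBp <- truth$shiftBp
  if (is.null(trueBp)) trueBp <- truth$shiftBins * binSize
  infBp <- assignments$shiftBp
  if (!is.null(flipInversion)) {
    invClusters <- as.integer(names(flipInversion$inverted)[
      flipInversion$inverted])
    mirror <- assignments$cluster %in% invClusters
    infBp[mirror] <- -infBp[mirror]
  }
  mean(abs(trueBp - infBp))
}

#' Cluster-wise aggregate profiles after realignment
#'
#' Realigns every locus by its inferred shift/flip state, then averages the
#' profiles within each inferred cluster, per feature — the aggregate
#' patterns drawn above heatmaps. If true aggregates and labels are
#' supplied, Pearson correlations between true and inferred aggregates are
#' returned after label alignment.
#'
#' @param dataset A [ChromatinExperiment].
#' @param assignments Hard-assignment data.frame.
#' @param K Number of clusters (defaults to max assigned label).
#' @param trueAggregates Optional L x M x K array of true cluster
#'   aggregates.
#' @param truthLabels Optional true labels, needed for label alignment of
#'   the correlations.
#' @return List with \code{aggregates} (L x M x K array; empty clusters
#'   give zero profiles with a warning) and, when truth is supplied,
#'   \code{correlations} (M x K matrix of Pearson r) and \code{mapping}.
#' @export
aggregateProfiles <- function(dataset, assignments,
                              K = max(assignments$cluster),
                              trueAggregates = NULL, truthLabels = NULL) {
  aligned <- suppressMessages(realignProfiles(dataset, assignments))
  countsList <- counts(aligned)
  L <- nBins(dataset)
  M <- nFeatures(dataset)
  agg <- array(0, dim = c(L, M, K),
               dimnames = list(NULL, featureNames(dataset), NULL))
  for (k in seq_len(K)) {
    idx <- assignments$cluster == k
    if (!any(idx)) {
      warning("cluster ", k, " is empty; returning a zero profile",
              call. = FALSE)
      next
    }
    for (m in seq_len(M)) {
      agg[, m, k] <- colMeans(countsList[[m]][idx, , drop = FALSE])
    }
  }
  out <- list(aggregates = agg)
  if (!is.null(trueAggregates) && !is.null(truthLabels)) {
    al <- alignClusterLabels(truthLabels, assignments$cluster, K)
    cors <- matrix(NA_real_, nrow = M, ncol = K,
                   dimnames = list(featureNames(dataset), NULL))
    for (k in seq_len(K)) {
      kTrue <- al$mapping[k]
      for (m in seq_len(M)) {
        cors[m, k] <- stats::cor(agg[, m, k], trueAggregates[, m, kTrue])
      }
    }
    out$correlations <- cors
    out$mapping <- al$mapping
  }
  out
}

#' Full evaluation report against simulation truth
#'
#' Convenience wrapper computing the clustering AUC (two true clusters),
#' label alignment, flip error with inversion correction, shift error in
#' bp, and aggregate-profile correlations.
#'
#' @param fit A [DMMFit].
#' @param truth Truth list from the simulators.
#' @param dataset The [ChromatinExperiment] the fit was computed on.
#' @return List: \code{clusteringAUC}, \code{labelAgreement},
#'   \code{shiftErrorBp}, \code{flipError}, \code{flipInverted},
#'   \code{mapping}.
#' @export
evaluateFit <- function(fit, truth, dataset) {
  asg <- hardAssignments(fit)
  al <- alignClusterLabels(truth$labels, asg$cluster,
                           max(truth$labels, asg$cluster))
  fe <- flipError(truth, asg)
  se <- shiftError(truth, asg, binSize = binSize(dataset),
                   flipInversion = fe)
  aucVal <- if (length(unique(truth$labels)) == 2L) {
    clusteringAUC(truth$labels, fit@responsibilities)
  } else {
    NA_real_
  }
  list(clusteringAUC = aucVal, labelAgreement = al$agreement,
       shiftErrorBp = se, flipError = fe$error,
       flipInverted = fe$inverted, mapping = al$mapping)
}
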