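#' Construct a shift/flip configuration
#'
#' @param shift Enable latent shift states.
#' @param flip Enable latent flip (strand-orientation) states.
#' @param maxShiftBp Maximum shift in bp, an exact multiple of
#'   \code{binSize}; forced to 0 when \code{shift = FALSE}. The default
#'   400 bp with 40 bp bins yields S = 21 shift states.
#' @param binSize Bin width in bp.
#' @param shiftPrior \code{"uniform"} or \code{"pyramid"} prior over shift
#'   states; the pyramid prior peaks at the no-shift state and decreases
#'   linearly to zero beyond the maximum shift.
#' @return A [ShiftFlipConfig].
#' @examples
#' cfg <- ShiftFlipConfig(shift = TRUE, flip = TRUE,
#'                        maxShiftBp = 400, binSize = 40)
#' nShiftStates(cfg)  # 21
#' @export
ShiftFlipConfig <- function(shift = FALSE, flip = FALSE,
                            maxShiftBp = if (shift) 400L else 0L,
                            binSize = 40L, shiftPrior = c("uniform", "pyramid")) {
  shiftPrior <- match.arg(shiftPrior)
  if (!shift) maxShiftBp <- 0L
  new("ShiftFlipConfig", shift = isTRUE(shift), flip = isTRUE(flip),
      maxShiftBp = as.integer(maxShiftBp), binSize = as.integer(binSize),
      shiftPrior = shiftPrior)
}

#' @describeIn ShiftFlipConfig Number of shift states S (odd; 1 when
#'   shifting is disabled).
#' @param x,object A \code{ShiftFlipConfig}.
#' @export
setMethod("nShiftStates", "ShiftFlipConfig", function(x) {
  2L * (x@maxShiftBp %/% x@binSize) + 1L
})

#' @describeIn ShiftFlipConfig Bin width in bp.
#' @export
setMethod("binSize", "ShiftFlipConfig", function(x) x@binSize)

setMethod("show", "ShiftFlipConfig", function(object) {
  S <- nShiftStates(object)
  cat(sprintf(
    "ShiftFlipConfig: shift=%s (maxShiftBp=%d, S=%d, prior=%s), flip=%s\n",
    object@shift, object@maxShiftBp, S, object@shiftPrior, object@flip))
})

#' Index of the no-shift state
#'
#' @param S Odd number of shift states.
#' @return Integer (S + 1) / 2.
#' @keywords internal
noShiftState <- function(S) (S + 1L) %/% 2L

#' Pyramid-shaped shift-state prior
#'
#' Probability vector over S shift states with weights proportional to
#' (S+1)/2 - |s - (S+1)/2|: maximal at the no-shift state, symmetric, and
#' linearly decreasing to zero beyond the maximum shift state.
#'
#' @param S Odd positive number of shift states.
#' @return Numeric simplex vector of length S.
#' @examples
#' pyramidShiftPrior(3)  # 0.25 0.50 0.25
#' @export
pyramidShiftPrior <- function(S) {
  S <- as.integer(S)
  if (length(S) != 1L || is.na(S) || S < 1L || S %% 2L == 0L) {
    stop("'S' must be a single odd positive integer")
  }
  c0 <- (S + 1L) / 2
  w <- c0 - abs(seq_len(S) - c0)
  w / sum(w)
}

#' Shift-state prior vector for a configuration
#'
#' @param config A [ShiftFlipConfig].
#' @return Simplex vector of length S: uniform or pyramid per the config.
#' @keywords internal
shiftPriorVector <- function(config) {
  S <- nShiftStates(config)
  if (config@shiftPrior == "pyramid") pyramidShiftPrior(S) else rep(1 / S, S)
}

#' Flip-state prior vector for a configuration
#'
#' @param config A [ShiftFlipConfig].
#' @return Length-2 simplex; (1, 0) when flipping is disabled.
#' @keywords internal
flipPriorVector <- function(config) {
  if (config@flip) c(0.5, 0.5) else c(1, 0)
}

#' Extract the profile-length parameter window for a shift/flip state
#'
#' Given extended Dirichlet parameters of length L + S - 1, shift state s
#' selects the subvector of length L starting at position s; flip state 2
#' additionally reverses its order. The input is never modified.
#'
#' @param alphaExt Positive numeric vector of length L + S - 1.
#' @param s Shift state in 1..S.
#' @param f Flip state, 1 (as is) or 2 (reversed).
#' @param L Window length in bins.
#' @return Numeric vector of length L.
#' @examples
#' extractWindow(1:5, s = 2, f = 1, L = 3)  # 2 3 4
#' extractWindow(1:5, s = 2, f = 2, L = 3)  # 4 3 2
#' @export
extractWindow <- function(alphaExt, s, f = 1L, L = length(alphaExt)) {
  S <- length(alphaExt) - L + 1L
  if (s < 1L || s > S) {
    stop(sprintf("shift state s=%d out of range 1..%d", s, S))
  }
  if (!f %in% c(1L, 2L)) stop("flip state f must be 1 or 2")
  w <- alphaExt[s:(s + L - 1L)]
  if (f == 2L) rev(w) else w
}

#' Extended-vector positions addressed by a shift/flip window
#'
#' Window slot j pairs data bin j with extended position idx[j]; for f = 2
#' the positions run backwards. Shared by the likelihood and the M-step
#' gradient so the two cannot disagree.
#'
#' @keywords internal
windowIndices <- function(s, f, L) {
  if (f == 2L) (s + L - 1L):s else s:(s + L - 1L)
}
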