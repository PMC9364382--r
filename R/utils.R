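#' Numerically stable log(sum(exp(x))) over matrix rows
#'
#' @param x Numeric matrix; -Inf entries are allowed.
#' @return Numeric vector of row-wise log-sum-exp values.
#' @keywords internal
rowLogSumExp <- function(x) {
  m <- apply(x, 1L, max)
  bad <- !is.finite(m)
  m[bad] <- 0
  out <- m + log(rowSums(exp(x - m)))
  out[bad] <- -Inf
  out
}

#' All permutations of 1..n (n <= 7)
#'
#' Used for exhaustive label alignment of clusterings.
#' @keywords internal
allPermutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- allPermutations(n - 1L)
    for (p in rest) {
      q <- seq_len(n)[-i]
      out[[length(out) + 1L]] <- c(i, q[p])
    }
  }
  out
}

#' Validate a count vector/matrix
#' @keywords internal
checkCounts <- function(x, what = "x") {
  if (anyNA(x) || any(x < 0) || any(x != round(x))) {
    stop(sprintf("'%s' must contain non-negative integral counts", what))
  }
  invisible(TRUE)
}
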