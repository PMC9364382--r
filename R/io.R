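#' Read a binned count matrix from tab-delimited text
#'
#' Expects one locus per row; an optional first column of non-numeric row
#' labels is used as locus ids. A header line is detected automatically.
#' All cells must be non-negative integers; violations are reported with
#' the offending file and line.
#'
#' @param path Path to the file.
#' @return Numeric N x L matrix (rownames = locus ids when present).
#' @export
readCountMatrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  tok <- strsplit(first, "\t", fixed = TRUE)[[1]]
  hasHeader <- length(tok) > 0 &&
    any(is.na(suppressWarnings(as.numeric(tok[-1]))))
  df <- utils::read.table(path, header = hasHeader, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  rn <- NULL
  if (ncol(df) > 1L && !is.numeric(df[[1L]])) {
    rn <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
  }
  if (length(unique(vapply(seq_len(nrow(df)), function(i)
    sum(!is.na(df[i, ])), integer(1)))) > 1L) {
    stop("ragged rows in ", path)
  }
  X <- as.matrix(df)
  if (!is.numeric(X)) {
    bad <- which(is.na(suppressWarnings(apply(df, 1L,
                                              function(r) sum(as.numeric(r))))))
    stop(sprintf("non-numeric cell in %s (data line %d)", path, bad[1]))
  }
  if (anyNA(X)) {
    stop(sprintf("missing/ragged value in %s (data line %d)", path,
                 which(rowSums(is.na(X)) > 0)[1]))
  }
  bad <- which(rowSums(X < 0 | X != round(X)) > 0)
  if (length(bad)) {
    stop(sprintf("negative or non-integral count in %s (data line %d)",
                 path, bad[1]))
  }
  rownames(X) <- rn
  colnames(X) <- NULL
  X
}

#' Write a count matrix as tab-delimited text
#'
#' Inverse of [readCountMatrix()]: no header, optional leading locus-id
#' column taken from the rownames.
#'
#' @param X Numeric matrix.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeCountMatrix <- function(X, path) {
  df <- as.data.frame(X)
  if (!is.null(rownames(X))) df <- cbind(locus = rownames(X), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read locus coordinates from a BED file
#'
#' Standard 0-based half-open BED via \pkg{rtracklayer}; used only to label
#' loci and annotate outputs (count extraction from alignments is outside
#' this package's scope). Records without a strand column get strand
#' \code{*} (unknown).
#'
#' @param path Path to the BED file.
#' @return A [GenomicRanges::GRanges] with locus names where present.
#' @export
readBedLoci <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) == 0L) stop("no records in ", path)
  gr
}

## serialize a MixtureModel (plus fit metadata) to a JSON-ready list
modelToList <- function(fit) {
  model <- fit@model
  cfg <- model@config
  list(
    alpha = model@alpha,
    pi = model@pi,
    xi = model@xi,
    zeta = model@zeta,
    L = model@L,
    featureNames = model@featureNames,
    config = list(shift = cfg@shift, flip = cfg@flip,
                  maxShiftBp = cfg@maxShiftBp, binSize = cfg@binSize,
                  shiftPrior = cfg@shiftPrior),
    hyper = list(eta = fit@hyper@eta, nu = fit@hyper@nu,
                 etaH = fit@hyper@etaH, nuH = fit@hyper@nuH,
                 regularize = fit@hyper@regularize),
    seed = fit@seed,
    converged = fit@converged,
    nIterations = fit@nIterations,
    logPosterior = fit@logPosterior,
    logLik = fit@logLik,
    conventions = list(
      shiftBp = "positive = data pattern displaced downstream; realign by -shiftBp/binSize bins",
      binIndexing = "1-based, j = 1..L",
      nParameters = "K*M*(L+S-1) + (K-1): shift-extended alpha plus free weights"
    )
  )
}

#' Write a fitted model to JSON
#'
#' @param fit A [DMMFit].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @seealso [readModelJSON()]
#' @export
writeModelJSON <- function(fit, path) {
  jsonlite::write_json(modelToList(fit), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Reload a mixture model written by [writeModelJSON()]
#'
#' @param path JSON path.
#' @return List with \code{model} (a [MixtureModel]), \code{hyper} and the
#'   stored metadata fields.
#' @export
readModelJSON <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- ShiftFlipConfig(shift = x$config$shift, flip = x$config$flip,
                         maxShiftBp = x$config$maxShiftBp,
                         binSize = x$config$binSize,
                         shiftPrior = x$config$shiftPrior)
  alpha <- x$alpha
  if (length(dim(alpha)) != 3L) {
    alpha <- array(unlist(alpha), dim = c(x$L + nShiftStates(cfg) - 1L,
                                          length(x$featureNames),
                                          length(x$pi)))
  }
  xi <- x$xi
  if (is.null(dim(xi))) xi <- matrix(xi, nrow = 1L)
  zeta <- x$zeta
  if (is.null(dim(zeta))) zeta <- matrix(zeta, nrow = 1L)
  model <- MixtureModel(alpha = alpha, pi = x$pi, config = cfg, L = x$L,
                        xi = xi, zeta = zeta,
                        featureNames = x$featureNames)
  hyper <- Hyperparameters(eta = x$hyper$eta, nu = x$hyper$nu,
                           etaH = x$hyper$etaH, nuH = x$hyper$nuH,
                           regularize = x$hyper$regularize)
  c(list(model = model, hyper = hyper),
    x[c("seed", "converged", "nIterations", "logPosterior", "logLik")])
}

#' Write all results of a fit to a directory
#'
#' Emits, under \code{outdir}: \code{assignments.tsv} (locus, cluster,
#' posterior, shift in bp, flip), \code{model.json} (parameters, priors,
#' run metadata and the file conventions), \code{selection.tsv} (when a
#' selection table is given), \code{realigned_<feature>.tsv} matrices and
#' \code{aggregates.tsv} (long format: cluster, feature, bin, mean). The
#' directory is created and checked to be writable before anything is
#' computed.
#'
#' @param fit A [DMMFit].
#' @param dataset The [ChromatinExperiment] that was fitted.
#' @param outdir Output directory.
#' @param selectionTable Optional data.frame from [selectK()].
#' @return Invisibly, the vector of files written.
#' @export
writeResults <- function(fit, dataset, outdir, selectionTable = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  probe <- file.path(outdir, ".write-test")
  ok <- tryCatch({
    writeLines("", probe)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("output directory not writable: ", outdir)
  unlink(probe)
  files <- character(0)

  asg <- hardAssignments(fit)
  ids <- rownames(dataset)
  if (!is.null(ids)) asg$locus <- ids
  f <- file.path(outdir, "assignments.tsv")
  utils::write.table(asg, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)

  f <- file.path(outdir, "model.json")
  writeModelJSON(fit, f)
  files <- c(files, f)

  if (!is.null(selectionTable)) {
    f <- file.path(outdir, "selection.tsv")
    utils::write.table(selectionTable, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
  }

  aligned <- suppressMessages(realignProfiles(dataset, hardAssignments(fit)))
  for (m in featureNames(dataset)) {
    f <- file.path(outdir, paste0("realigned_", gsub("[^A-Za-z0-9._-]", "_", m),
                                  ".tsv"))
    writeCountMatrix(counts(aligned)[[m]], f)
    files <- c(files, f)
  }

  agg <- aggregateProfiles(dataset, hardAssignments(fit),
                           K = nComponents(fit))$aggregates
  long <- do.call(rbind, lapply(seq_len(dim(agg)[3]), function(k) {
    do.call(rbind, lapply(seq_len(dim(agg)[2]), function(m) {
      data.frame(cluster = k, feature = dimnames(agg)[[2]][m],
                 bin = seq_len(dim(agg)[1]), mean = agg[, m, k])
    }))
  }))
  f <- file.path(outdir, "aggregates.tsv")
  utils::write.table(long, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)

  invisible(files)
}
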