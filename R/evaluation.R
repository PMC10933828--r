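#' Subject-by-subject correlation matrix
#'
#' Pearson correlation across voxels between every predicted and actual map:
#' entry (i, j) is the correlation between subject i's predicted map and
#' subject j's actual map.
#'
#' @param pred,actual n x V matrices, same subject order.
#' @return n x n correlation matrix (rows = predicted subjects).
#' @export
correlationMatrix <- function(pred, actual) {
  stopifnot(all(dim(pred) == dim(actual)))
  sdP <- apply(pred, 1, stats::sd)
  sdA <- apply(actual, 1, stats::sd)
  if (any(sdP == 0))
    stop("constant predicted map for subject ", which(sdP == 0)[1L])
  if (any(sdA == 0))
    stop("constant actual map for subject ", which(sdA == 0)[1L])
  stats::cor(t(pred), t(actual))
}

#' Prediction accuracy
#'
#' Mean of the diagonal of the subject-by-subject correlation matrix: the
#' average over subjects of the correlation between each subject's predicted
#' and own actual map.
#'
#' @param corrmat square correlation matrix from [correlationMatrix()].
#' @return numeric scalar.
#' @export
accuracy <- function(corrmat) {
  stopifnot(nrow(corrmat) == ncol(corrmat))
  mean(diag(corrmat))
}

#' Prediction discriminability
#'
#' After Fisher z-transformation of the correlation matrix (entries clipped
#' to +/- (1 - 1e-12) first), each subject's discriminability is the
#' difference between (i) the z of the correlation between their predicted
#' and own actual map and (ii) the mean z of the correlations between their
#' predicted map and the other subjects' actual maps (row convention:
#' predicted subject i against all actual maps).
#'
#' @param corrmat square correlation matrix.
#' @return list with `perSubject` (numeric n) and `mean`.
#' @export
discriminability <- function(corrmat) {
  n <- nrow(corrmat)
  stopifnot(n == ncol(corrmat), n >= 2)
  bound <- 1 - 1e-12
  clipped <- pmin(pmax(corrmat, -bound), bound)
  nClip <- sum(clipped != corrmat)
  if (nClip > 0)
    message(nClip, " correlation(s) clipped before Fisher transform")
  z <- atanh(clipped)
  perSubject <- vapply(seq_len(n), function(i)
    z[i, i] - mean(z[i, -i]), numeric(1))
  list(perSubject = perSubject, mean = mean(perSubject))
}

#' Subject identification rate
#'
#' Fraction of subjects whose predicted map correlates most strongly (strict
#' row maximum) with their own actual map. Ties count as failures and are
#' reported in the `"ties"` attribute.
#'
#' @param corrmat square correlation matrix.
#' @return numeric in \[0, 1\] with attribute `ties` (tie count).
#' @export
identification <- function(corrmat) {
  n <- nrow(corrmat)
  stopifnot(n == ncol(corrmat), n >= 2)
  hit <- logical(n)
  ties <- 0L
  for (i in seq_len(n)) {
    others <- max(corrmat[i, -i])
    if (corrmat[i, i] > others) hit[i] <- TRUE
    else if (corrmat[i, i] == others) ties <- ties + 1L
  }
  structure(mean(hit), ties = ties)
}

#' Correlation of inter-individual variability maps
#'
#' Correlates the per-voxel between-subject standard-deviation map
#' (denominator n - 1) of the predictions with that of the actual maps.
#'
#' @param pred,actual n x V matrices.
#' @return numeric scalar.
#' @export
variabilityMapCorrelation <- function(pred, actual) {
  stopifnot(all(dim(pred) == dim(actual)), nrow(pred) >= 2)
  sdP <- apply(pred, 2, stats::sd)
  sdA <- apply(actual, 2, stats::sd)
  if (stats::sd(sdP) == 0 || stats::sd(sdA) == 0)
    stop("constant standard-deviation map; variability correlation undefined")
  stats::cor(sdP, sdA)
}

#' Test-retest reliability
#'
#' Per-subject spatial correlation between first-visit and repeat-session
#' maps. Applied to residualised maps this estimates the noise ceiling
#' `sigma_b^2 / (sigma_b^2 + sigma_eps^2)` bounding attainable prediction
#' accuracy.
#'
#' @param session1,session2 n x V matrices, same subject order.
#' @return numeric n of per-subject correlations.
#' @export
testRetest <- function(session1, session2) {
  stopifnot(all(dim(session1) == dim(session2)))
  vapply(seq_len(nrow(session1)), function(i) {
    if (stats::sd(session1[i, ]) == 0 || stats::sd(session2[i, ]) == 0)
      stop("constant map for subject ", i)
    stats::cor(session1[i, ], session2[i, ])
  }, numeric(1))
}

#' Full evaluation report
#'
#' Computes the correlation matrix and all summary measures for one set of
#' predictions, optionally with repeat-session maps for the reliability
#' benchmark.
#'
#' @param pred,actual n x V matrices.
#' @param session2 optional n x V repeat-session maps (same space as
#'   `actual`).
#' @return an [EvaluationReport-class].
#' @export
evaluatePredictions <- function(pred, actual, session2 = NULL) {
  cm <- correlationMatrix(pred, actual)
  rel <- if (is.null(session2)) numeric(0) else testRetest(actual, session2)
  new("EvaluationReport", corrmat = cm, accuracy = accuracy(cm),
      discriminability = discriminability(cm),
      identificationRate = as.numeric(identification(cm)),
      variabilityCorr = variabilityMapCorrelation(pred, actual),
      reliability = rel)
}
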