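#' Fit the per-voxel ensemble stacker
#'
#' For every voxel, regresses the true training task residuals on the
#' baseline-fitted and sparse-fitted values at that voxel (optionally plus q
#' rest-amplitude principal-component scores), with no intercept. Collinear
#' designs are solved by the minimum-norm pseudoinverse; the number of such
#' voxels is reported in a single warning.
#'
#' @param Y N x V matrix of training task residuals.
#' @param fittedBaseline,fittedSparse N x V matrices of constituent-model
#'   fitted values on the training subjects.
#' @param ampPcs optional N x q matrix of amplitude PC scores.
#' @param contrast label stored in the fit.
#' @return an [EnsembleFit-class] with theta of dimension (2 + q) x V.
#' @export
fitEnsemble <- function(Y, fittedBaseline, fittedSparse, ampPcs = NULL,
                        contrast = "") {
  stopifnot(all(dim(Y) == dim(fittedBaseline)),
            all(dim(Y) == dim(fittedSparse)))
  N <- nrow(Y)
  V <- ncol(Y)
  q <- if (is.null(ampPcs)) 0L else ncol(ampPcs)
  if (q > 0L) stopifnot(nrow(ampPcs) == N)
  m <- 2L + q
  if (N <= m) stop("need more training subjects (", N,
                   ") than ensemble predictors (", m, ")")
  theta <- matrix(0, m, V)
  nSingular <- 0L
  if (q == 0L) {
    # batched closed-form 2x2 normal equations across voxels
    a11 <- colSums(fittedBaseline^2)
    a12 <- colSums(fittedBaseline * fittedSparse)
    a22 <- colSums(fittedSparse^2)
    r1 <- colSums(fittedBaseline * Y)
    r2 <- colSums(fittedSparse * Y)
    det <- a11 * a22 - a12^2
    scale2 <- pmax(a11, a22)
    ok <- det > (scale2^2) * 1e-12 & scale2 > 0
    theta[1L, ok] <- (a22[ok] * r1[ok] - a12[ok] * r2[ok]) / det[ok]
    theta[2L, ok] <- (a11[ok] * r2[ok] - a12[ok] * r1[ok]) / det[ok]
    for (i in which(!ok)) {
      nSingular <- nSingular + 1L
      D <- cbind(fittedBaseline[, i], fittedSparse[, i])
      theta[, i] <- drop(pinvMatrix(D) %*% Y[, i])
    }
  } else {
    for (i in seq_len(V)) {
      D <- cbind(fittedBaseline[, i], fittedSparse[, i], ampPcs)
      qrD <- qr(D)
      if (qrD$rank < m) {
        nSingular <- nSingular + 1L
        theta[, i] <- drop(pinvMatrix(D) %*% Y[, i])
      } else {
        theta[, i] <- qr.coef(qrD, Y[, i])
      }
    }
  }
  if (nSingular > 0L)
    warning("minimum-norm solution used at ", nSingular, " collinear voxel(s)")
  new("EnsembleFit", theta = theta, q = as.integer(q), contrast = contrast)
}

#' Ensemble predictions
#'
#' Combines constituent-model predictions voxelwise with the trained theta.
#'
#' @param fit an [EnsembleFit-class].
#' @param predBaseline,predSparse n x V matrices of constituent predictions.
#' @param ampPcs optional n x q matrix of amplitude PC scores (must match the
#'   q used in training).
#' @return n x V matrix of ensemble predictions.
#' @export
predictEnsemble <- function(fit, predBaseline, predSparse, ampPcs = NULL) {
  q <- if (is.null(ampPcs)) 0L else ncol(ampPcs)
  if (q != fit@q)
    stop("amplitude PC count (", q, ") does not match training (", fit@q, ")")
  stopifnot(all(dim(predBaseline) == dim(predSparse)))
  out <- predBaseline * rep(fit@theta[1L, ], each = nrow(predBaseline)) +
    predSparse * rep(fit@theta[2L, ], each = nrow(predSparse))
  if (q > 0L)
    out <- out + ampPcs %*% fit@theta[3:(2 + q), , drop = FALSE]
  out
}
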