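#' Fit the amplitude model
#'
#' Multiple linear regression (with intercept; rest amplitudes are centred
#' near 1, not 0) of each subject's task activation amplitude on their k
#' rest-mode amplitudes.
#'
#' @param restAmps N x k matrix of rest-mode amplitudes.
#' @param taskAmps numeric N task amplitudes for one contrast.
#' @param contrast label stored in the fit.
#' @return an [AmplitudeFit-class] (training R-squared recorded).
#' @export
fitAmplitude <- function(restAmps, taskAmps, contrast = "") {
  restAmps <- as.matrix(restAmps)
  N <- nrow(restAmps)
  k <- ncol(restAmps)
  stopifnot(length(taskAmps) == N)
  if (N <= k + 1L)
    stop("need more subjects (", N, ") than predictors plus intercept (",
         k + 1L, ")")
  D <- cbind(1, restAmps)
  qrD <- qr(D)
  if (qrD$rank < k + 1L) {
    warning("rank-deficient amplitude design; using minimum-norm solution")
    coefs <- drop(pinvMatrix(D) %*% taskAmps)
  } else {
    coefs <- drop(qr.coef(qrD, taskAmps))
  }
  fitted <- drop(D %*% coefs)
  ss <- sum((taskAmps - mean(taskAmps))^2)
  r2 <- if (ss > 0) 1 - sum((taskAmps - fitted)^2) / ss else NA_real_
  new("AmplitudeFit", weights = coefs[-1L], intercept = coefs[1L],
      contrast = contrast, r2 = r2)
}

#' Predict task amplitudes for unseen subjects
#'
#' @param fit an [AmplitudeFit-class].
#' @param restAmps n x k matrix of rest-mode amplitudes.
#' @return numeric n of predicted (surrogate) task amplitudes, to be used by
#'   [recompose()] when adding the group-average map back in.
#' @export
predictAmplitude <- function(fit, restAmps) {
  restAmps <- as.matrix(restAmps)
  if (ncol(restAmps) != length(fit@weights))
    stop("amplitude count (", ncol(restAmps), ") does not match model (",
         length(fit@weights), ")")
  drop(fit@intercept + restAmps %*% fit@weights)
}

#' Principal components of the rest-mode amplitudes
#'
#' Column-centred PCA of the N x k amplitude matrix. Scores are ordered by
#' variance; the sign of each component is fixed so its largest-magnitude
#' loading is positive.
#'
#' @param restAmps N x k matrix of rest-mode amplitudes.
#' @param q number of components (`q <= min(N, k)`).
#' @return list with `scores` (N x q), `loadings` (k x q), `center`
#'   (numeric k), `sdev` (component standard deviations). Test subjects are
#'   projected as `(A - center) %*% loadings`.
#' @export
amplitudePcs <- function(restAmps, q) {
  restAmps <- as.matrix(restAmps)
  if (q > min(dim(restAmps)))
    stop("q (", q, ") exceeds min(N, k) = ", min(dim(restAmps)))
  ctr <- colMeans(restAmps)
  Xc <- sweep(restAmps, 2, ctr)
  sv <- svd(Xc, nu = q, nv = q)
  loadings <- sv$v[, seq_len(q), drop = FALSE]
  for (i in seq_len(q)) {
    peak <- which.max(abs(loadings[, i]))
    if (loadings[peak, i] < 0) loadings[, i] <- -loadings[, i]
  }
  scores <- Xc %*% loadings
  list(scores = scores, loadings = loadings, center = ctr,
       sdev = sv$d[seq_len(q)] / sqrt(max(1, nrow(restAmps) - 1)))
}
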