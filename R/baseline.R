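#' Per-subject reconstruction coefficients
#'
#' Ordinary least squares of one subject's task variation map on their k
#' rest-mode variation maps (no intercept; the inputs are residualised).
#' Rank-deficient designs fall back to the minimum-norm pseudoinverse
#' solution with a warning.
#'
#' @param X V x k matrix of rest-mode residual maps for one subject.
#' @param y numeric V task residual map.
#' @return numeric k coefficient vector.
#' @export
fitBaselineSubject <- function(X, y) {
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("non-finite values in baseline regression inputs")
  if (nrow(X) != length(y)) stop("dimension mismatch")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("rank-deficient rest basis (rank ", qrX$rank, " < ", ncol(X),
            "); using minimum-norm solution")
    return(drop(pinvMatrix(X) %*% y))
  }
  drop(qr.coef(qrX, y))
}

#' Fit the baseline model over a training cohort
#'
#' Computes per-subject reconstruction coefficients and averages them across
#' training subjects to give the final baseline estimate, independently per
#' contrast.
#'
#' @param restStacks list of k N x V matrices (or [CohortStack-class]) of
#'   rest-mode residuals, in mode order; rows are subjects.
#' @param Y N x V matrix of task residual maps (same subject order).
#' @return list with `beta` (numeric k, the averaged coefficients) and
#'   `perSubject` (N x k matrix of individual coefficients).
#' @export
fitBaseline <- function(restStacks, Y) {
  stacks <- lapply(restStacks, function(s)
    if (is(s, "CohortStack")) s@data else s)
  k <- length(stacks)
  N <- nrow(Y)
  V <- ncol(Y)
  if (!all(vapply(stacks, function(s) all(dim(s) == c(N, V)), logical(1))))
    stop("inconsistent dimensions across mode stacks")
  if (N < 1) stop("need at least one training subject")
  perSubject <- matrix(0, N, k)
  for (j in seq_len(N)) {
    Xj <- vapply(stacks, function(s) s[j, ], numeric(V))
    perSubject[j, ] <- fitBaselineSubject(Xj, Y[j, ])
  }
  list(beta = colMeans(perSubject), perSubject = perSubject)
}

#' Baseline-model predictions
#'
#' Applies the averaged reconstruction coefficients to each subject's own
#' rest-mode residual maps: `y_hat = X_l beta`.
#'
#' @param beta numeric k coefficients (or the list from [fitBaseline()]).
#' @param restStacks list of k n x V matrices (or [CohortStack-class]) for
#'   the subjects to predict.
#' @return n x V matrix of predicted task residual maps.
#' @export
predictBaseline <- function(beta, restStacks) {
  if (is.list(beta) && !is.null(beta$beta)) beta <- beta$beta
  stacks <- lapply(restStacks, function(s)
    if (is(s, "CohortStack")) s@data else s)
  if (length(beta) != length(stacks))
    stop("coefficient count (", length(beta), ") does not match mode count (",
         length(stacks), ")")
  out <- matrix(0, nrow(stacks[[1L]]), ncol(stacks[[1L]]))
  for (i in seq_along(stacks)) out <- out + beta[i] * stacks[[i]]
  out
}
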