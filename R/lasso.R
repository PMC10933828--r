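#' Lasso solution for one target column
#'
#' Minimises the unscaled objective `||y - X w||^2 + lambda * ||w||_1` by
#' cyclic coordinate descent (tolerance 1e-8 on the maximum coefficient
#' change). With this convention the all-zero solution is optimal exactly
#' when `lambda >= 2 * max |X' y|`.
#'
#' @param X N x q predictor matrix.
#' @param y numeric N target.
#' @param lambda non-negative penalty.
#' @param tol,maxit coordinate-descent controls.
#' @param wInit optional warm start.
#' @return numeric q coefficient vector.
#' @export
solveLasso <- function(X, y, lambda, tol = 1e-8, maxit = 100000L,
                       wInit = NULL) {
  stopifnot(lambda >= 0, nrow(X) == length(y))
  .lassoSolveC(X, as.numeric(y), lambda, tol, as.integer(maxit), wInit)
}

#' Warm-started Lasso path
#'
#' Solves [solveLasso()] along a decreasing `lambdas` sequence, warm-starting
#' each solution from the previous one.
#'
#' @inheritParams solveLasso
#' @param lambdas decreasing penalty sequence.
#' @return q x length(lambdas) coefficient matrix.
#' @export
lassoPath <- function(X, y, lambdas, tol = 1e-8, maxit = 100000L) {
  stopifnot(all(lambdas >= 0), nrow(X) == length(y))
  .lassoPathC(X, as.numeric(y), as.numeric(lambdas), tol, as.integer(maxit))
}

#' Deterministic cross-validation folds
#'
#' Subjects are sorted by identifier, shuffled once under the seed, and
#' assigned to folds round-robin, so the fold structure is reproducible from
#' the seed alone.
#'
#' @param ids character subject identifiers (or an integer count).
#' @param nFolds number of folds.
#' @param seed integer seed.
#' @return integer fold assignment, one entry per element of `ids` (in the
#'   original order of `ids`).
#' @export
makeFolds <- function(ids, nFolds, seed = 1) {
  if (length(ids) == 1L && is.numeric(ids)) ids <- as.character(seq_len(ids))
  n <- length(ids)
  stopifnot(nFolds >= 2, n >= nFolds)
  ord <- order(ids)
  shuffled <- withSeed(seed, sample(ord))
  fold <- integer(n)
  fold[shuffled] <- rep_len(seq_len(nFolds), n)
  fold
}

#' Fit the sparse model by per-column Lasso with nested cross-validation
#'
#' Each target column gets its own penalty, chosen on a 30-point log grid
#' from `lambda_max` (the smallest penalty with an all-zero solution) down to
#' `lambdaMinRatio * lambda_max` by nested K-fold cross-validation on the
#' training rows, minimising held-out squared error; the final coefficients
#' are refit on all rows at the chosen penalty. Predictors are internally
#' scaled to unit Euclidean norm (no centering, keeping the no-intercept
#' objective exact), and each target column is solved at unit norm (the
#' objective is scale-equivariant); coefficients and penalties are returned
#' on the original scale. Columns are solved independently.
#'
#' @param A N x (d*k) reduced rest variation matrix (training subjects).
#' @param targets N x p (or N x V) matrix of Lasso targets: the task ICA
#'   mixing matrix, or the raw task residual matrix in identity mode.
#' @param nFolds nested CV folds (default 3).
#' @param nLambda grid size (default 30).
#' @param lambdaMinRatio grid lower end relative to `lambda_max`.
#' @param seed seed for the deterministic fold assignment.
#' @param ids optional subject identifiers (length N); folds are assigned by
#'   identifier so the fit is equivariant to row permutations.
#' @return a [SparseFit-class].
#' @export
fitSparse <- function(A, targets, nFolds = 3L, nLambda = 30L,
                      lambdaMinRatio = 1e-3, seed = 1, ids = NULL) {
  A <- as.matrix(A)
  targets <- as.matrix(targets)
  N <- nrow(A)
  q <- ncol(A)
  p <- ncol(targets)
  stopifnot(nrow(targets) == N, N >= nFolds, nFolds >= 2)
  if (is.null(ids)) ids <- sprintf("sub%06d", seq_len(N))
  colNorms <- sqrt(colSums(A^2))
  scale <- ifelse(colNorms > 0, colNorms, 1)
  Xs <- sweep(A, 2, scale, "/")
  fold <- makeFolds(ids, nFolds, seed = seed)
  W <- matrix(0, q, p)
  lambda <- numeric(p)
  nConstant <- 0L
  for (col in seq_len(p)) {
    y <- targets[, col]
    # the objective is scale-equivariant: solve at unit target norm so the
    # absolute coordinate-descent tolerance is meaningful, then rescale
    yScale <- sqrt(sum(y^2))
    if (yScale == 0 || stats::sd(y) == 0) {
      nConstant <- nConstant + 1L
      lambda[col] <- 0
      next
    }
    ys <- y / yScale
    lmax <- 2 * max(abs(crossprod(Xs, ys)))
    if (lmax == 0) {
      nConstant <- nConstant + 1L
      lambda[col] <- 0
      next
    }
    grid <- exp(seq(log(lmax), log(lmax * lambdaMinRatio),
                    length.out = nLambda))
    cvErr <- numeric(nLambda)
    for (f in seq_len(nFolds)) {
      tr <- fold != f
      # looser tolerance for the CV scoring paths; the final refit is tight
      path <- .lassoPathC(Xs[tr, , drop = FALSE], ys[tr], grid, 1e-5, 100000L)
      pred <- Xs[!tr, , drop = FALSE] %*% path
      cvErr <- cvErr + colSums((ys[!tr] - pred)^2)
    }
    best <- which.min(cvErr)   # ties resolve to the larger (sparser) penalty
    lambda[col] <- grid[best] * yScale
    W[, col] <- yScale * .lassoSolveC(Xs, ys, grid[best], 1e-8, 100000L, NULL)
  }
  if (nConstant > 0L)
    message(nConstant, " constant target column(s) received zero coefficients")
  W <- W / scale
  new("SparseFit", W = W, lambda = lambda, cvFolds = as.integer(nFolds),
      sparsity = mean(W == 0))
}

#' Sparse-model predictions
#'
#' Applies the sparse coefficients to the subjects' reduced rest coordinates:
#' `A W S_task` in ICA task mode, `A W` in identity mode.
#'
#' @param fit a [SparseFit-class] (or bare coefficient matrix `W`).
#' @param A n x (d*k) matrix of reduced rest coordinates (from
#'   [projectSubjects()] for unseen subjects, or the training mixing matrix).
#' @param taskReduction a [TaskReduction-class].
#' @return n x V matrix of predicted task residual maps.
#' @export
predictSparse <- function(fit, A, taskReduction) {
  W <- if (is(fit, "SparseFit")) fit@W else fit
  if (ncol(A) != nrow(W))
    stop("coordinate count (", ncol(A), ") does not match coefficients (",
         nrow(W), ")")
  P <- A %*% W
  if (taskReduction@mode == "ica") P <- P %*% taskReduction@sources
  P
}
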