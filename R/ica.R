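# Fixed-point (FastICA-style) estimation of an orthogonal unmixing rotation.
#
# Z: d x V whitened data (rows approximately unit-variance, uncorrelated).
# Deflation scheme with the tanh contrast; returns list(W = d x d rotation,
# converged = logical). Seeded initial vectors make the result deterministic.
fixedPointICA <- function(Z, seed = 1, maxit = 500L, tol = 1e-6) {
  d <- nrow(Z)
  V <- ncol(Z)
  W <- matrix(0, d, d)
  converged <- TRUE
  withSeed(seed, {
    for (comp in seq_len(d)) {
      w <- stats::rnorm(d)
      # orthogonalise against previously extracted components
      if (comp > 1L) {
        prev <- W[seq_len(comp - 1L), , drop = FALSE]
        w <- w - drop(t(prev) %*% (prev %*% w))
      }
      w <- w / sqrt(sum(w^2))
      ok <- FALSE
      for (it in seq_len(maxit)) {
        wz <- drop(w %*% Z)
        g <- tanh(wz)
        gp <- 1 - g^2
        wNew <- drop(Z %*% g) / V - mean(gp) * w
        if (comp > 1L) {
          prev <- W[seq_len(comp - 1L), , drop = FALSE]
          wNew <- wNew - drop(t(prev) %*% (prev %*% wNew))
        }
        nrm <- sqrt(sum(wNew^2))
        if (nrm < .Machine$double.eps) break
        wNew <- wNew / nrm
        delta <- abs(1 - abs(sum(wNew * w)))
        w <- wNew
        if (delta < tol) { ok <- TRUE; break }
      }
      if (!ok) converged <- FALSE
      W[comp, ] <- w
    }
  })
  list(W = W, converged = converged)
}

# Factorise one N x V stack as A (N x d) times S (d x V) via rank-d SVD
# whitening followed by fixed-point ICA. Sources have unit variance over
# voxels, sign fixed so each source's largest-magnitude value is positive,
# and components are ordered by explained variance. On ICA non-convergence
# the PCA basis is used for this stack (with a warning).
icaFactorise <- function(X, d, seed = 1, maxit = 500L, tol = 1e-6,
                         label = "stack") {
  N <- nrow(X)
  V <- ncol(X)
  if (d > min(N, V))
    stop("d (", d, ") exceeds min(N, V) = ", min(N, V))
  sv <- svd(X, nu = d, nv = d)
  K <- t(sv$v)                       # d x V, orthonormal rows
  Z <- K * sqrt(V)                   # whitened: rows ~ unit variance
  fp <- fixedPointICA(Z, seed = seed, maxit = maxit, tol = tol)
  if (!fp$converged) {
    warning("ICA did not converge for ", label, "; using the PCA basis")
    S <- Z
  } else {
    S <- fp$W %*% Z
  }
  # exact unit variance (population) over voxels
  mu <- rowMeans(S)
  sdS <- sqrt(rowMeans(S^2) - mu^2)
  sdS[sdS == 0] <- 1
  S <- S / sdS
  # mixing so that A %*% S equals the rank-d approximation of X
  A <- X %*% t(S) %*% solve(S %*% t(S))
  # deterministic sign: largest-magnitude source value positive
  for (i in seq_len(nrow(S))) {
    peak <- which.max(abs(S[i, ]))
    if (S[i, peak] < 0) { S[i, ] <- -S[i, ]; A[, i] <- -A[, i] }
  }
  # order by explained variance (sources unit-variance => column norms of A)
  ord <- order(colSums(A^2), decreasing = TRUE)
  list(A = A[, ord, drop = FALSE], S = S[ord, , drop = FALSE],
       converged = fp$converged)
}

#' Cross-subject ICA reduction of the rest variation matrices
#'
#' For each of the k rest modes, the subjects-by-voxels residual stack is
#' whitened by SVD to rank d and factorised by fixed-point ICA (deflation,
#' tanh contrast, at most 500 iterations, tolerance 1e-6, seeded) into d
#' spatial sources and an N x d mixing matrix of subject "coordinates". The
#' k mixing matrices are concatenated into the N x (d*k) reduced variation
#' matrix used as sparse-model predictors. A mode whose ICA fails to
#' converge falls back to its PCA basis with a warning.
#'
#' @param restStacks list of k N x V matrices (or [CohortStack-class]) of
#'   rest residuals (training subjects).
#' @param d components per mode (`d <= min(N, V)`).
#' @param seed integer seed for the ICA initial vectors.
#' @return a [RestReduction-class].
#' @export
reduceModes <- function(restStacks, d, seed = 1) {
  stacks <- lapply(restStacks, function(s)
    if (is(s, "CohortStack")) s@data else s)
  k <- length(stacks)
  res <- vector("list", k)
  for (i in seq_len(k)) {
    res[[i]] <- icaFactorise(stacks[[i]], d, seed = seed + i,
                             label = sprintf("mode %d", i))
  }
  new("RestReduction",
      sources = lapply(res, `[[`, "S"),
      mixing = lapply(res, `[[`, "A"),
      mixingConcat = do.call(cbind, lapply(res, `[[`, "A")),
      d = as.integer(d),
      converged = vapply(res, `[[`, logical(1), "converged"))
}

#' Reduction of the task variation matrix
#'
#' Either factorises the concatenated task residual matrix into p independent
#' components (same ICA contract as [reduceModes()]), or passes the raw
#' voxelwise matrix through (`identity` mode, i.e. no ICA on the task
#' matrix).
#'
#' @param Y N x V matrix (or [CohortStack-class]) of task residuals.
#' @param p component count, or `NULL` / `"identity"` for identity mode.
#' @param seed integer seed.
#' @return a [TaskReduction-class].
#' @export
reduceTask <- function(Y, p = NULL, seed = 1) {
  Ym <- if (is(Y, "CohortStack")) Y@data else Y
  if (is.null(p) || identical(p, "identity")) {
    return(new("TaskReduction", mode = "identity",
               sources = matrix(0, 0, 0), mixing = matrix(0, 0, 0),
               p = ncol(Ym)))
  }
  f <- icaFactorise(Ym, p, seed = seed, label = "task matrix")
  new("TaskReduction", mode = "ica", sources = f$S, mixing = f$A,
      p = as.integer(p))
}

#' Project unseen subjects into the training reduction space
#'
#' For each mode, regresses the test subjects' residual stack onto the
#' training sources, `A_hat = argmin || X - A S ||_F`, and concatenates the
#' per-mode coordinates. Rank-deficient sources fall back to the
#' pseudoinverse with a warning.
#'
#' @param restStacks list of k n x V matrices (or [CohortStack-class]) of
#'   test-subject rest residuals.
#' @param reduction a [RestReduction-class] from the training subjects.
#' @return n x (d*k) matrix of projected coordinates.
#' @export
projectSubjects <- function(restStacks, reduction) {
  stacks <- lapply(restStacks, function(s)
    if (is(s, "CohortStack")) s@data else s)
  if (length(stacks) != length(reduction@sources))
    stop("mode count mismatch")
  parts <- vector("list", length(stacks))
  for (i in seq_along(stacks)) {
    S <- reduction@sources[[i]]
    if (ncol(stacks[[i]]) != ncol(S)) stop("voxel count mismatch in mode ", i)
    G <- S %*% t(S)
    cp <- stacks[[i]] %*% t(S)
    A <- tryCatch(t(solve(G, t(cp))), error = function(e) {
      warning("rank-deficient sources in mode ", i, "; using pseudoinverse")
      cp %*% pinvMatrix(G)
    })
    parts[[i]] <- A
  }
  do.call(cbind, parts)
}
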