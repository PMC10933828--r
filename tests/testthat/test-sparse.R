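test_that("ICA reduction reconstructs exact low-rank stacks", {
  d <- 3; N <- 12; V <- 400
  A0 <- rmat(N, d, seed = 1)
  S0 <- rmat(d, V, seed = 2)
  X <- A0 %*% S0
  red <- reduceModes(list(X), d, seed = 5)
  recon <- red@mixing[[1]] %*% red@sources[[1]]
  expect_lt(norm(recon - X, "F") / norm(X, "F"), 1e-6)
  expect_equal(dim(red@mixingConcat), c(N, d))

  # sign convention: each source's largest-magnitude value is positive,
  # and stays satisfied when the input is negated
  for (M in list(X, -X)) {
    r <- reduceModes(list(M), d, seed = 5)
    peaks <- apply(r@sources[[1]], 1, function(s) s[which.max(abs(s))])
    expect_true(all(peaks > 0))
  }
  expect_error(reduceModes(list(X), 50, seed = 1), "exceeds")
})

test_that("planted non-Gaussian sources are recovered up to permutation", {
  d <- 3; N <- 40; V <- 1500
  S0 <- withr::with_seed(3, {
    s <- matrix(sign(rnorm(d * V)) * rexp(d * V), d, V)
    s / sqrt(rowMeans(s^2))
  })
  A0 <- rmat(N, d, seed = 4)
  red <- reduceTask(A0 %*% S0, p = d, seed = 6)
  cmat <- abs(cor(t(red@sources), t(S0)))
  # best match per true source
  expect_true(all(apply(cmat, 2, max) >= 0.95))
})

test_that("identity task mode passes targets through", {
  Y <- rmat(10, 50, seed = 7)
  red <- reduceTask(Y, p = NULL)
  expect_identical(red@mode, "identity")
  expect_identical(red@p, 50L)
  W <- rmat(6, 50, seed = 8)
  A <- rmat(4, 6, seed = 9)
  expect_equal(predictSparse(W, A, red), A %*% W, tolerance = 1e-12)
})

test_that("projection reproduces training coordinates and the OLS oracle", {
  d <- 4; N <- 15; V <- 600
  X <- rmat(N, V, seed = 10)
  red <- reduceModes(list(X), d, seed = 11)
  S <- red@sources[[1]]

  # random test rows match the explicit normal-equations solution
  Xtest <- rmat(5, V, seed = 12)
  A <- projectSubjects(list(Xtest), red)
  Ao <- t(solve(S %*% t(S), S %*% t(Xtest)))
  expect_equal(A, Ao, tolerance = 1e-8)

  # a test subject identical to training subject j lands on j's mixing row
  Adup <- projectSubjects(list(X[3, , drop = FALSE]), red)
  # training mixing reproduces the rank-d approximation, so projecting the
  # raw row recovers the mixing row up to the truncation residual
  Aself <- projectSubjects(list(X), red)
  expect_equal(Adup[1, ], Aself[3, ], tolerance = 1e-8)
})

test_that("lasso solutions satisfy their optimality conditions", {
  X <- rmat(40, 12, seed = 13)
  y <- rmat(40, 1, seed = 14)[, 1]

  # lambda = 0 reduces to least squares
  expect_equal(solveLasso(X, y, 0), normalEquationsSolve(X, y),
               tolerance = 1e-6)

  # beyond the KKT bound the solution is identically zero
  lmax <- 2 * max(abs(crossprod(X, y)))
  expect_equal(solveLasso(X, y, lmax * 1.0000001), rep(0, 12))
  expect_gt(max(abs(solveLasso(X, y, lmax * 0.9))), 0)

  # single standardised predictor: closed-form soft threshold
  x1 <- rmat(30, 1, seed = 15)[, 1]
  x1 <- x1 / sqrt(sum(x1^2))
  y1 <- rmat(30, 1, seed = 16)[, 1]
  for (lam in c(0.01, 0.1, 0.5)) {
    z <- sum(x1 * y1)
    expected <- sign(z) * max(abs(z) - lam / 2, 0)
    expect_equal(solveLasso(matrix(x1), y1, lam), expected,
                 tolerance = 1e-10)
  }

  # monotone shrinkage of the l1 norm along the path
  lams <- exp(seq(log(lmax), log(lmax * 1e-3), length.out = 25))
  path <- lassoPath(X, y, lams)
  l1 <- colSums(abs(path))
  expect_true(all(diff(l1) >= -1e-10))     # lambda decreasing => l1 growing
})

test_that("lasso agrees with glmnet under the matching convention", {
  skip_if_not_installed("glmnet")
  N <- 50
  X <- rmat(N, 8, seed = 17)
  y <- rmat(N, 1, seed = 18)[, 1]
  for (lam in c(0.5, 2, 10)) {
    mine <- solveLasso(X, y, lam)
    gl <- glmnet::glmnet(X, y, alpha = 1, lambda = lam / (2 * N),
                         standardize = FALSE, intercept = FALSE,
                         thresh = 1e-14)
    expect_equal(mine, as.numeric(gl$beta), tolerance = 1e-4)
  }
})

test_that("nested-CV lasso recovers planted sparse couplings", {
  N <- 60; q <- 20; p <- 15
  A <- rmat(N, q, seed = 19)
  Wtrue <- matrix(0, q, p)
  withr::with_seed(20, {
    for (j in 1:p) Wtrue[sample(q, 3), j] <- rnorm(3) + sign(rnorm(3)) * 0.5
  })
  targets <- A %*% Wtrue
  fit <- fitSparse(A, targets, seed = 21)
  supportOK <- vapply(1:p, function(j)
    identical(which(fit@W[, j] != 0), which(Wtrue[, j] != 0)), logical(1))
  expect_gte(mean(supportOK), 0.9)
  expect_gt(fit@sparsity, 0.5)

  # all-zero targets give an all-zero W (reported via message)
  expect_message(z <- fitSparse(A, matrix(0, N, 3), seed = 21), "constant")
  expect_equal(z@W, matrix(0, q, 3))

  # row-permutation equivariance when identifiers travel with the rows
  ids <- sprintf("s%02d", 1:N)
  perm <- withr::with_seed(22, sample(N))
  fitP <- fitSparse(A[perm, ], targets[perm, ], seed = 21, ids = ids[perm])
  fitO <- fitSparse(A, targets, seed = 21, ids = ids)
  expect_equal(fitP@W, fitO@W, tolerance = 1e-10)
})

test_that("CV-chosen penalties beat the grid ends on noisy planted data", {
  # in expectation over repeats, held-out error at the CV lambda is no worse
  # than at lambda = 0 or lambda_max
  N <- 40; q <- 30
  wins0 <- winsMax <- 0
  nrep <- 20
  for (r in 1:nrep) {
    A <- rmat(N, q, seed = 100 + r)
    w <- rep(0, q); w[1:3] <- 2
    y <- drop(A %*% w) + rmat(N, 1, seed = 200 + r)[, 1] * 3
    Anew <- rmat(N, q, seed = 300 + r)
    ynew <- drop(Anew %*% w) + rmat(N, 1, seed = 400 + r)[, 1] * 3
    fit <- fitSparse(A, matrix(y), seed = r)
    scale <- sqrt(colSums(A^2))
    errCV <- sum((ynew - Anew %*% fit@W)^2)
    err0 <- sum((ynew - Anew %*% MASS::ginv(A) %*% y)^2)
    wzero <- sum(ynew^2)
    wins0 <- wins0 + (errCV <= err0)
    winsMax <- winsMax + (errCV <= wzero)
  }
  expect_gt(wins0 / nrep, 0.5)
  expect_gt(winsMax / nrep, 0.5)
})
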