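test_that("per-subject coefficients solve the least-squares problem", {
  # orthonormal basis: coefficients read off directly
  X <- withr::with_seed(1, qr.Q(qr(matrix(rnorm(100 * 4), 100, 4))))
  cvec <- c(2, -1, 0.5, 3)
  expect_equal(fitBaselineSubject(X, drop(X %*% cvec)), cvec,
               tolerance = 1e-10)

  # target orthogonal to all columns gives zero coefficients
  y <- withr::with_seed(2, rnorm(100))
  yperp <- y - X %*% crossprod(X, y)
  expect_equal(fitBaselineSubject(X, drop(yperp)), rep(0, 4),
               tolerance = 1e-10)

  # random instance against the explicit normal-equations oracle
  Xr <- rmat(300, 7, seed = 3)
  yr <- rmat(300, 1, seed = 4)[, 1]
  expect_equal(fitBaselineSubject(Xr, yr), normalEquationsSolve(Xr, yr),
               tolerance = 1e-8)
  # fit residual orthogonal to every column
  res <- yr - Xr %*% fitBaselineSubject(Xr, yr)
  expect_lt(max(abs(crossprod(Xr, res))), 1e-8)
})

test_that("rank-deficient bases fall back to the minimum-norm solution", {
  X <- rmat(50, 3, seed = 5)
  Xdef <- cbind(X, X[, 1])
  y <- rmat(50, 1, seed = 6)[, 1]
  expect_warning(w <- fitBaselineSubject(Xdef, y), "rank-deficient")
  # minimum-norm solution: matches svd pseudoinverse
  sv <- svd(Xdef)
  wmn <- sv$v %*% ((t(sv$u) %*% y) / sv$d * (sv$d > 1e-10))
  expect_equal(w, drop(wmn), tolerance = 1e-8)
  expect_error(fitBaselineSubject(matrix(NA_real_, 5, 2), rnorm(5)),
               "non-finite")
})

test_that("cohort fit averages per-subject coefficients", {
  V <- 120; k <- 3
  stacks <- lapply(1:k, function(i) rmat(4, V, seed = 10 + i))
  Y <- rmat(4, V, seed = 20)
  fit <- fitBaseline(stacks, Y)
  expect_equal(fit$beta, colMeans(fit$perSubject), tolerance = 1e-12)

  # single subject equals the subject-level solve
  one <- fitBaseline(lapply(stacks, function(s) s[1, , drop = FALSE]),
                     Y[1, , drop = FALSE])
  Xj <- vapply(stacks, function(s) s[1, ], numeric(V))
  expect_equal(one$beta, fitBaselineSubject(Xj, Y[1, ]), tolerance = 1e-10)

  # antisymmetric pair cancels
  X1 <- vapply(stacks, function(s) s[2, ], numeric(V))
  b1 <- fitBaselineSubject(X1, Y[2, ])
  Ypair <- rbind(Y[2, ], -Y[2, ])
  pairStacks <- lapply(stacks, function(s) rbind(s[2, ], s[2, ]))
  expect_equal(fitBaseline(pairStacks, Ypair)$beta, rep(0, k),
               tolerance = 1e-10)
})

test_that("baseline predictions are linear and recover in-span cohorts", {
  stacks <- lapply(1:3, function(i) rmat(5, 60, seed = 30 + i))
  beta <- c(0.5, -1, 2)
  pred <- predictBaseline(beta, stacks)
  expect_equal(predictBaseline(beta, lapply(stacks, function(s) 2 * s)),
               2 * pred, tolerance = 1e-12)
  expect_equal(predictBaseline(c(0, 1, 0), stacks), stacks[[2]])
  expect_equal(predictBaseline(rep(0, 3), stacks), matrix(0, 5, 60))

  # noiseless synthetic cohort with common coupling: recovered coefficients
  # predict the true residuals nearly perfectly
  co <- simulateCohort(tinySpec(N = 30, sigma_eps = 0, sigma_c = 0,
                                sessions = 1, seed = 99))
  rr <- lapply(1:3, function(i) co@truth$restResiduals[[i]])
  fit <- fitBaseline(rr, co@truth$taskResiduals[[1]])
  pred <- predictBaseline(fit$beta, rr)
  cm <- correlationMatrix(pred, co@truth$taskResiduals[[1]])
  expect_gte(accuracy(cm), 0.99)
})
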