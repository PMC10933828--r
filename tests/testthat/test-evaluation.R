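test_that("correlation matrix follows the row = predicted convention", {
  pred <- rmat(5, 20, seed = 1)
  act <- rmat(5, 20, seed = 2)
  cm <- correlationMatrix(pred, act)
  # direct covariance-formula oracle
  for (i in 1:5) for (j in 1:5) {
    p <- pred[i, ]; a <- act[j, ]
    oracle <- sum((p - mean(p)) * (a - mean(a))) /
      sqrt(sum((p - mean(p))^2) * sum((a - mean(a))^2))
    expect_equal(cm[i, j], oracle, tolerance = 1e-12)
  }
  expect_equal(diag(correlationMatrix(pred, pred)), rep(1, 5),
               tolerance = 1e-12)
  pred2 <- pred
  pred2[3, ] <- 0
  expect_error(correlationMatrix(pred2, act), "subject 3")
})

test_that("accuracy is the diagonal mean", {
  cm <- diag(c(0.2, 0.4))
  expect_equal(accuracy(cm), 0.3)
  r <- rmat(4, 4, seed = 3)
  expect_equal(accuracy(r), mean(diag(r)))
})

test_that("discriminability matches its step-by-step definition", {
  # constant matrix: zero for every subject
  cm <- matrix(0.4, 3, 3)
  d <- discriminability(cm)
  expect_equal(d$perSubject, rep(0, 3))

  # closed-form 2x2 case
  cm2 <- matrix(c(0.5, 0, 0, 0.5), 2, 2)
  d2 <- discriminability(cm2)
  expect_equal(d2$perSubject, rep(atanh(0.5), 2), tolerance = 1e-12)

  # random matrix against a brute-force reimplementation
  r <- rmat(6, 6, seed = 4) / 3
  dr <- discriminability(r)
  z <- atanh(pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12))
  brute <- vapply(1:6, function(i) z[i, i] - mean(z[i, setdiff(1:6, i)]),
                  numeric(1))
  expect_equal(dr$perSubject, brute, tolerance = 1e-12)
  expect_equal(dr$mean, mean(brute), tolerance = 1e-12)

  # clipping keeps |r| = 1 finite (and is reported)
  cm3 <- diag(2) * 1
  cm3[1, 2] <- 0.2; cm3[2, 1] <- -0.3
  expect_message(d3 <- discriminability(cm3), "clipped")
  expect_true(all(is.finite(d3$perSubject)))
})

test_that("identification demands a strict row maximum", {
  cm <- matrix(0.1, 4, 4); diag(cm) <- 0.9
  expect_equal(as.numeric(identification(cm)), 1.0)

  cmTie <- matrix(0.5, 3, 3)
  idT <- identification(cmTie)
  expect_equal(as.numeric(idT), 0.0)
  expect_equal(attr(idT, "ties"), 3L)

  r <- rmat(7, 7, seed = 5)
  oracle <- mean(vapply(1:7, function(i)
    r[i, i] > max(r[i, -i]), logical(1)))
  expect_equal(as.numeric(identification(r)), oracle)
})

test_that("variability-map correlation is scale invariant and exact", {
  pred <- rmat(6, 40, seed = 6)
  act <- rmat(6, 40, seed = 7)
  v <- variabilityMapCorrelation(pred, act)
  oracle <- cor(apply(pred, 2, sd), apply(act, 2, sd))
  expect_equal(v, oracle, tolerance = 1e-12)
  expect_equal(variabilityMapCorrelation(act, act), 1, tolerance = 1e-12)
  expect_equal(variabilityMapCorrelation(3 * act, act), 1, tolerance = 1e-12)
})

test_that("test-retest behaves at the identical and independent extremes", {
  s1 <- rmat(5, 2000, seed = 8)
  expect_equal(testRetest(s1, s1), rep(1, 5), tolerance = 1e-12)
  s2 <- rmat(5, 2000, seed = 9)
  expect_lt(abs(mean(testRetest(s1, s2))), 0.05)
})

test_that("all measures are invariant to a joint subject permutation", {
  pred <- rmat(8, 60, seed = 10)
  act <- rmat(8, 60, seed = 11)
  perm <- withr::with_seed(12, sample(8))
  r1 <- evaluatePredictions(pred, act)
  r2 <- evaluatePredictions(pred[perm, ], act[perm, ])
  expect_equal(r2@accuracy, r1@accuracy, tolerance = 1e-12)
  expect_equal(r2@discriminability$mean, r1@discriminability$mean,
               tolerance = 1e-12)
  expect_equal(r2@identificationRate, r1@identificationRate)
  expect_equal(r2@variabilityCorr, r1@variabilityCorr, tolerance = 1e-12)
  expect_equal(sort(r2@discriminability$perSubject),
               sort(r1@discriminability$perSubject), tolerance = 1e-12)
})

test_that("residualised evaluation has near-zero off-diagonals", {
  co <- tinyCohort()
  tmpl <- co@templates@taskMaps[1, ]
  r1 <- residualiseCohort(stackData(co@taskMaps[[1]][[1]]), tmpl)$residuals
  cm <- correlationMatrix(co@truth$taskResiduals[[1]], r1)
  offdiag <- cm[row(cm) != col(cm)]
  expect_lt(abs(mean(offdiag)), 0.02)
})
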