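test_that("cohort generation is deterministic and templates are unit norm", {
  co1 <- tinyCohort()
  co2 <- simulateCohort(tinySpec())
  expect_identical(stackData(co1@restModes[[2]]), stackData(co2@restModes[[2]]))
  expect_identical(stackData(co1@taskMaps[[1]][[2]]),
                   stackData(co2@taskMaps[[1]][[2]]))
  expect_identical(co1@truth$restAmps, co2@truth$restAmps)

  tmpl <- co1@templates
  expect_equal(sqrt(rowSums(tmpl@restMaps^2)), rep(1, 3), tolerance = 1e-12)
  expect_equal(sqrt(rowSums(tmpl@taskMaps^2)), rep(1, 1), tolerance = 1e-12)
})

test_that("spatial autocorrelation increases with the smoothing length", {
  lag1 <- function(smooth_len) {
    tm <- makeGroupTemplates(tinySpec(V = 4096, smooth_len = smooth_len))
    v <- tm@restMaps[1, ]
    cor(v[-1], v[-length(v)])
  }
  acs <- vapply(c(0, 2, 8), lag1, numeric(1))
  expect_lt(abs(acs[1]), 0.15)          # white noise: no autocorrelation
  expect_true(all(diff(acs) > 0))
})

test_that("constructional identities hold exactly", {
  co <- tinyCohort()
  spec <- co@spec
  V <- spec$V
  G <- co@templates@restMaps
  Tm <- co@templates@taskMaps
  tr <- co@truth

  # rest maps decompose as a * G + R with R template-orthogonal, norm sigma_b*sqrt(V)
  for (i in 1:spec$k) {
    R <- tr$restResiduals[[i]]
    recon <- outer(tr$restAmps[, i], G[i, ]) + R
    expect_equal(recon, stackData(co@restModes[[i]]), tolerance = 1e-12)
    expect_lt(max(abs(R %*% G[i, ])) / sqrt(sum(G[i, ]^2)), 1e-10)
    expect_equal(sqrt(rowSums(R^2)), rep(spec$sigma_b * sqrt(V), spec$N),
                 tolerance = 1e-10)
  }

  # task maps: y - c*T - b has exactly the session-noise norm, b orthogonal to T
  b <- tr$taskResiduals[[1]]
  expect_lt(max(abs(b %*% Tm[1, ])), 1e-10)
  for (s in 1:2) {
    eps <- stackData(co@taskMaps[[1]][[s]]) -
      outer(tr$taskAmps[, 1], Tm[1, ]) - b
    expect_equal(sqrt(rowSums(eps^2)), rep(spec$sigma_eps * sqrt(V), spec$N),
                 tolerance = 1e-10)
  }
})

test_that("degenerate noise settings collapse as they should", {
  co0 <- simulateCohort(tinySpec(N = 6, sigma_b = 0, sigma_eps = 0,
                                 sigma_c = 0, sessions = 1))
  Tm <- co0@templates@taskMaps[1, ]
  y <- stackData(co0@taskMaps[[1]][[1]])
  # every task map is an exact scalar multiple of the group task map
  for (j in 1:6)
    expect_equal(y[j, ], co0@truth$taskAmps[j, 1] * Tm, tolerance = 1e-12)

  coA <- simulateCohort(tinySpec(N = 5, sigma_a = 0, sessions = 1))
  expect_equal(coA@truth$restAmps, matrix(1, 5, 3))
})

test_that("test-retest reliability of residuals follows sb^2/(sb^2+se^2)", {
  grid <- list(c(0.01, 0.01), c(0.01, 0.005), c(0.008, 0.016))
  for (g in grid) {
    spec <- tinySpec(N = 80, V = 1331, sigma_b = g[1], sigma_eps = g[2],
                     sessions = 2, seed = 7)
    co <- simulateCohort(spec)
    tmpl <- co@templates@taskMaps[1, ]
    r1 <- residualiseCohort(stackData(co@taskMaps[[1]][[1]]), tmpl)$residuals
    r2 <- residualiseCohort(stackData(co@taskMaps[[1]][[2]]), tmpl)$residuals
    tr <- testRetest(r1, r2)
    expected <- g[1]^2 / (g[1]^2 + g[2]^2)
    se <- sd(tr) / sqrt(length(tr))
    expect_lt(abs(mean(tr) - expected), 3 * se + 0.02)
  }
})

test_that("simulated time series live in the mode span and reproduce", {
  co <- tinyCohort()
  ts1 <- simulateTimeseries(co, 3, T_len = 30)
  ts2 <- simulateTimeseries(co, 3, T_len = 30)
  expect_identical(ts1$series, ts2$series)

  M <- t(vapply(co@restModes, function(s) s@data[3, ], numeric(co@spec$V)))
  # noiseless series rows are combinations of the subject's mode maps
  recon <- ts1$timecourses %*% M
  expect_equal(ts1$series, recon, tolerance = 1e-12)
  expect_error(simulateTimeseries(co, 3, T_len = 3), "exceed")
})
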