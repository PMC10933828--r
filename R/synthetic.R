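# Run expr with a fixed RNG seed, restoring the caller's RNG state after.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647L))
  expr
}

#' Gaussian smoothing of a 3-D array (circular boundary)
#'
#' Separable Gaussian convolution computed via FFT with periodic boundary
#' conditions, used to give synthetic fields a controllable spatial
#' correlation length on the virtual grid backing the mask.
#'
#' @param arr 3-D numeric array.
#' @param sigma kernel standard deviation in voxels; `sigma <= 0` returns
#'   `arr` unchanged.
#' @return smoothed array of the same dimension.
#' @export
gaussianSmooth3D <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  dims <- dim(arr)
  k1d <- function(n) {
    x <- seq_len(n) - 1L
    d <- pmin(x, n - x)
    g <- exp(-d^2 / (2 * sigma^2))
    g / sum(g)
  }
  kern <- outer(outer(k1d(dims[1]), k1d(dims[2])), k1d(dims[3]))
  dim(kern) <- dims
  out <- Re(fft(fft(arr) * fft(kern), inverse = TRUE)) / prod(dims)
  out
}

# internal: one smooth standard field over the mask (unnormalised)
smoothField <- function(mask, smooth_len) {
  vol <- array(stats::rnorm(prod(mask@dim)), dim = mask@dim)
  vol <- gaussianSmooth3D(vol, smooth_len)
  applyMask(vol, mask)@values
}

# internal: remove the component of x along t (no intercept)
orthogonalise <- function(x, t) {
  x - (sum(x * t) / sum(t * t)) * t
}

# internal: rescale vector to target Euclidean norm (zero vector stays zero)
rescaleNorm <- function(x, target) {
  nx <- sqrt(sum(x^2))
  if (nx == 0 || target == 0) return(x * 0)
  x * (target / nx)
}

#' Specification of a synthetic cohort
#'
#' Defines the generative conditions for [simulateCohort()]: per subject j
#' and mode i the observed rest map is `a_ji * G_i + R_ji` with amplitude
#' `a ~ N(1, sigma_a^2)` and a smooth individual residual `R` orthogonal to
#' the template and of norm `sigma_b * sqrt(V)`; the task residual is the
#' coupling-weighted combination of the rest residuals, the task amplitude is
#' `1 + sum_i w_ci (a_ji - 1)` plus `N(0, sigma_c^2)` noise, and each session
#' adds fresh smooth noise of norm `sigma_eps * sqrt(V)`.
#'
#' @param N subjects.
#' @param V in-mask voxels (a compact 3-D grid is built behind the mask).
#' @param k rest modes.
#' @param C task contrasts.
#' @param sigma_a std of rest-mode amplitudes about 1.
#' @param sigma_b scale of individual spatial residuals (per-voxel RMS; the
#'   residual has Euclidean norm `sigma_b * sqrt(V)` against unit-norm group
#'   templates, so the default keeps the group-average component dominant,
#'   as in real task contrast maps).
#' @param sigma_eps scale of per-session spatial noise (per-voxel RMS).
#' @param sigma_c std of noise on the task amplitude about its rest-coupled
#'   value.
#' @param smooth_len spatial correlation length (Gaussian sigma, voxels) of
#'   all smooth fields, noise included.
#' @param coupling k x C matrix mapping rest residuals to task residuals;
#'   default is a seeded random matrix with unit-norm columns (so the task
#'   residual has expected norm `sigma_b * sqrt(V)` and the
#'   `sigma_b^2 / (sigma_b^2 + sigma_eps^2)` test-retest law holds).
#' @param sessions 1 or 2 task sessions.
#' @param seed integer; fixed seed gives bit-identical cohorts.
#' @return a validated spec list of class `syntheticSpec`.
#' @export
syntheticSpec <- function(N = 200, V = 2000, k = 8, C = 2,
                          sigma_a = 0.1, sigma_b = 0.01, sigma_eps = 0.01,
                          sigma_c = 0.05, smooth_len = 1.5,
                          coupling = NULL, sessions = 2, seed = 1) {
  stopifnot(N >= 1, V >= 1, k >= 1, C >= 1, sessions %in% c(1, 2),
            sigma_a >= 0, sigma_b >= 0, sigma_eps >= 0, sigma_c >= 0,
            smooth_len >= 0)
  if (is.null(coupling)) {
    coupling <- withSeed(seed + 101L, {
      m <- matrix(stats::rnorm(k * C), k, C)
      sweep(m, 2, sqrt(colSums(m^2)), "/")
    })
  }
  if (!is.matrix(coupling) || nrow(coupling) != k || ncol(coupling) != C)
    stop("coupling must be a k x C matrix")
  structure(list(N = N, V = V, k = k, C = C, sigma_a = sigma_a,
                 sigma_b = sigma_b, sigma_eps = sigma_eps, sigma_c = sigma_c,
                 smooth_len = smooth_len, coupling = coupling,
                 sessions = sessions, seed = as.integer(seed)),
            class = "syntheticSpec")
}

#' Generate group templates for a synthetic cohort
#'
#' Builds k smooth unit-norm rest-mode templates (Gaussian-filtered white
#' noise) and C group task maps as fixed linear combinations of the rest
#' templates plus an independent smooth field, all deterministic under the
#' spec seed.
#'
#' @param spec a [syntheticSpec()].
#' @param mask optional [BrainMask-class]; defaults to `gridMask(spec$V)`.
#' @return a [GroupTemplates-class].
#' @export
makeGroupTemplates <- function(spec, mask = gridMask(spec$V)) {
  if (spec$V < spec$k)
    stop("V (", spec$V, ") must be at least k (", spec$k, ")")
  withSeed(spec$seed + 11L, {
    rest <- matrix(0, spec$k, spec$V)
    for (i in seq_len(spec$k)) {
      g <- smoothField(mask, spec$smooth_len)
      rest[i, ] <- g / sqrt(sum(g^2))
    }
    task <- matrix(0, spec$C, spec$V)
    for (cc in seq_len(spec$C)) {
      mix <- stats::rnorm(spec$k)
      mix <- mix / sqrt(sum(mix^2))
      extra <- smoothField(mask, spec$smooth_len)
      extra <- extra / sqrt(sum(extra^2))
      t0 <- drop(mix %*% rest) + 0.5 * extra
      task[cc, ] <- t0 / sqrt(sum(t0^2))
    }
    new("GroupTemplates", restMaps = rest, taskMaps = task,
        restLabels = sprintf("mode%02d", seq_len(spec$k)),
        taskLabels = sprintf("contrast%d", seq_len(spec$C)),
        mask = mask)
  })
}

#' Simulate a cohort with known ground truth
#'
#' Draws a full synthetic cohort under the generative model described in
#' [syntheticSpec()], recording all latent quantities (amplitudes, residuals,
#' couplings) in the `truth` slot.
#'
#' @param spec a [syntheticSpec()].
#' @return a [SyntheticCohort-class].
#' @export
simulateCohort <- function(spec) {
  stopifnot(inherits(spec, "syntheticSpec"))
  templates <- makeGroupTemplates(spec)
  mask <- templates@mask
  N <- spec$N; V <- spec$V; k <- spec$k; C <- spec$C
  G <- templates@restMaps
  Tm <- templates@taskMaps
  ids <- sprintf("sub%04d", seq_len(N))

  withSeed(spec$seed + 23L, {
    # fixed amplitude-coupling weights: first k entries of a seeded random
    # unit vector, one per contrast
    ampW <- matrix(stats::rnorm(C * k), C, k)
    ampW <- ampW / sqrt(rowSums(ampW^2))

    restAmps <- matrix(stats::rnorm(N * k, mean = 1, sd = spec$sigma_a), N, k)
    restRes <- lapply(seq_len(k), function(i) matrix(0, N, V))
    restObs <- lapply(seq_len(k), function(i) matrix(0, N, V))
    for (j in seq_len(N)) {
      for (i in seq_len(k)) {
        r <- smoothField(mask, spec$smooth_len)
        r <- orthogonalise(r, G[i, ])
        r <- rescaleNorm(r, spec$sigma_b * sqrt(V))
        restRes[[i]][j, ] <- r
        restObs[[i]][j, ] <- restAmps[j, i] * G[i, ] + r
      }
    }

    taskAmps <- matrix(0, N, C)
    taskRes <- lapply(seq_len(C), function(cc) matrix(0, N, V))
    taskObs <- lapply(seq_len(C), function(cc)
      lapply(seq_len(spec$sessions), function(s) matrix(0, N, V)))
    for (j in seq_len(N)) {
      for (cc in seq_len(C)) {
        b <- rep(0, V)
        for (i in seq_len(k)) b <- b + spec$coupling[i, cc] * restRes[[i]][j, ]
        b <- orthogonalise(b, Tm[cc, ])
        taskRes[[cc]][j, ] <- b
        a_c <- 1 + sum(ampW[cc, ] * (restAmps[j, ] - 1)) +
          stats::rnorm(1, 0, spec$sigma_c)
        taskAmps[j, cc] <- a_c
        for (s in seq_len(spec$sessions)) {
          eps <- rescaleNorm(smoothField(mask, spec$smooth_len),
                             spec$sigma_eps * sqrt(V))
          taskObs[[cc]][[s]][j, ] <- a_c * Tm[cc, ] + b + eps
        }
      }
    }

    restStacks <- lapply(seq_len(k), function(i)
      cohortStack(restObs[[i]], mask, ids))
    taskStacks <- lapply(seq_len(C), function(cc)
      lapply(seq_len(spec$sessions), function(s)
        cohortStack(taskObs[[cc]][[s]], mask, ids)))
    names(taskStacks) <- templates@taskLabels

    new("SyntheticCohort", spec = unclass(spec), templates = templates,
        restModes = restStacks, taskMaps = taskStacks,
        truth = list(restAmps = restAmps, taskAmps = taskAmps,
                     restResiduals = restRes, taskResiduals = taskRes,
                     coupling = spec$coupling, amplitudeWeights = ampW))
  })
}

#' Simulate a resting-state time series for one subject
#'
#' Returns `Y = TC %*% M + noise`, where `M` stacks the subject's true mode
#' maps (k x V) and `TC` is a T x k random time-course matrix with
#' unit-variance columns.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param subject subject index or id.
#' @param T_len number of time points (must exceed k).
#' @param noise_sd per-entry std of additive white noise (default 0).
#' @return list with `series` (T x V) and `timecourses` (T x k).
#' @export
simulateTimeseries <- function(cohort, subject, T_len, noise_sd = 0) {
  spec <- cohort@spec
  if (is.character(subject)) subject <- match(subject, subjectIds(cohort))
  stopifnot(!is.na(subject), subject >= 1, subject <= spec$N)
  if (T_len <= spec$k)
    stop("T_len (", T_len, ") must exceed the mode count k (", spec$k, ")")
  M <- t(vapply(cohort@restModes,
                function(s) s@data[subject, ], numeric(spec$V)))
  withSeed(spec$seed + 1000L + subject, {
    TC <- matrix(stats::rnorm(T_len * spec$k), T_len, spec$k)
    TC <- sweep(TC, 2, apply(TC, 2, stats::sd), "/")
    series <- TC %*% M
    if (noise_sd > 0)
      series <- series + matrix(stats::rnorm(T_len * spec$V, 0, noise_sd),
                                T_len, spec$V)
    list(series = series, timecourses = TC)
  })
}
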