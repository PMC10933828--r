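# internal: normalise cohort input to a plain list of matrices
cohortPieces <- function(cohort) {
  if (is(cohort, "SyntheticCohort")) {
    rest <- lapply(cohort@restModes, stackData)
    task <- lapply(cohort@taskMaps, function(ct) lapply(ct, stackData))
    list(rest = rest, task = task, ids = subjectIds(cohort),
         mask = maskOf(cohort))
  } else {
    stopifnot(is.list(cohort), !is.null(cohort$rest), !is.null(cohort$task))
    rest <- lapply(cohort$rest, function(s)
      if (is(s, "CohortStack")) s@data else s)
    task <- lapply(cohort$task, function(ct)
      lapply(ct, function(s) if (is(s, "CohortStack")) s@data else s))
    ids <- cohort$ids
    if (is.null(ids)) ids <- sprintf("sub%04d", seq_len(nrow(rest[[1L]])))
    list(rest = rest, task = task, ids = ids, mask = cohort$mask)
  }
}

# internal: select the stacker configuration by inner CV on the training
# rows, using the constituent-model fitted values. Candidates are the
# per-voxel OLS stacker with each q in qGrid, plus the two constituent-only
# configurations (the per-voxel stacker adds estimation variance that can
# hurt held-out performance at small N). Selection maximises the held-out
# mean spatial correlation, the framework's primary performance measure.
# Returns list(mode, q).
chooseStacker <- function(Y, Fb, Fs, restAmps, qGrid, fold) {
  qGrid <- sort(unique(pmin(qGrid, ncol(restAmps))))
  nFolds <- max(fold)
  cand <- c(lapply(qGrid, function(q) list(mode = "stack", q = q)),
            list(list(mode = "baseline", q = 0L), list(mode = "sparse", q = 0L)))
  scoreOf <- function(pred, act) {
    mean(vapply(seq_len(nrow(act)), function(i) {
      if (stats::sd(pred[i, ]) == 0 || stats::sd(act[i, ]) == 0) return(0)
      stats::cor(pred[i, ], act[i, ])
    }, numeric(1)))
  }
  err <- rep(Inf, length(cand))
  for (ci in seq_along(cand)) {
    q <- cand[[ci]]$q
    mode <- cand[[ci]]$mode
    score <- 0
    ok <- TRUE
    for (f in seq_len(nFolds)) {
      tr <- fold != f
      if (mode == "stack") {
        if (sum(tr) <= 2L + q + 1L) { ok <- FALSE; break }
        if (q > 0L) {
          pcs <- amplitudePcs(restAmps[tr, , drop = FALSE], q)
          scTr <- pcs$scores
          scTe <- sweep(restAmps[!tr, , drop = FALSE], 2, pcs$center) %*%
            pcs$loadings
        } else {
          scTr <- NULL; scTe <- NULL
        }
        fit <- suppressWarnings(fitEnsemble(Y[tr, , drop = FALSE],
                                            Fb[tr, , drop = FALSE],
                                            Fs[tr, , drop = FALSE], scTr))
        pred <- predictEnsemble(fit, Fb[!tr, , drop = FALSE],
                                Fs[!tr, , drop = FALSE], scTe)
      } else if (mode == "baseline") {
        pred <- Fb[!tr, , drop = FALSE]
      } else {
        pred <- Fs[!tr, , drop = FALSE]
      }
      score <- score + scoreOf(pred, Y[!tr, , drop = FALSE])
    }
    if (ok) err[ci] <- -score
  }
  cand[[which.min(err)]]
}

# internal: EnsembleFit pinned to a single constituent
constituentFit <- function(which, V, contrast) {
  theta <- matrix(0, 2L, V)
  theta[if (which == "baseline") 1L else 2L, ] <- 1
  new("EnsembleFit", theta = theta, q = 0L, contrast = contrast)
}

#' Cross-validated rest-to-task prediction pipeline
#'
#' Runs the full framework under outer K-fold cross-validation: per fold,
#' group templates are computed from the training subjects only, rest and
#' task maps are residualised against them, the baseline, sparse, amplitude
#' and ensemble models are fitted on the training fold, and the held-out
#' subjects are projected and predicted. Test predictions are pooled across
#' folds and evaluated both in residual space and with the amplitude-scaled
#' group map added back in. Every random draw derives from `seed`.
#'
#' @param cohort a [SyntheticCohort-class], or a list with elements `rest`
#'   (list of k N x V matrices), `task` (list per contrast of lists per
#'   session of N x V matrices), optional `ids`.
#' @param folds outer cross-validation folds (default 3).
#' @param d ICA components per rest mode.
#' @param p task ICA components, or `NULL` for identity (no task ICA).
#' @param qGrid candidate numbers of amplitude PCs for the ensemble. The
#'   stacker configuration (per-voxel OLS with each q, or one of the single
#'   constituents) is chosen by inner cross-validation on training rows.
#' @param nestedFolds nested folds for the Lasso penalty (and q selection).
#' @param nLambda,lambdaMinRatio Lasso grid controls (see [fitSparse()]).
#' @param seed integer master seed.
#' @param verbose log per-stage timing messages.
#' @return list with one element per contrast, each containing
#'   `residual` (list of [EvaluationReport-class] for baseline, sparse,
#'   ensemble), `recomposed` (report for the ensemble predictions with the
#'   group map added back), `predictions` (pooled matrices), `amplitude`
#'   (observed and predicted task amplitudes); plus `folds` (assignment),
#'   `models` (per-fold fitted parameters) and `config`.
#' @export
runCrossval <- function(cohort, folds = 3L, d = 10L, p = NULL,
                        qGrid = c(0L, 1L, 2L, 3L, 5L), nestedFolds = 3L,
                        nLambda = 30L, lambdaMinRatio = 1e-3, seed = 1,
                        verbose = FALSE) {
  pieces <- cohortPieces(cohort)
  rest <- pieces$rest
  task <- pieces$task
  ids <- pieces$ids
  k <- length(rest)
  N <- nrow(rest[[1L]])
  V <- ncol(rest[[1L]])
  contrasts <- names(task)
  if (is.null(contrasts)) contrasts <- sprintf("contrast%d", seq_along(task))
  nSessions <- length(task[[1L]])
  say <- function(...) if (verbose) message(sprintf(...))

  foldId <- makeFolds(ids, folds, seed = seed)
  out <- stats::setNames(vector("list", length(task)), contrasts)
  for (cc in seq_along(task)) {
    out[[cc]] <- list(
      predBaseline = matrix(NA_real_, N, V),
      predSparse = matrix(NA_real_, N, V),
      predEnsemble = matrix(NA_real_, N, V),
      predRecomposed = matrix(NA_real_, N, V),
      actualResid1 = matrix(NA_real_, N, V),
      actualResid2 = if (nSessions > 1L) matrix(NA_real_, N, V) else NULL,
      taskAmps = rep(NA_real_, N),
      predAmps = rep(NA_real_, N))
  }
  models <- vector("list", folds)

  for (f in seq_len(folds)) {
    t0 <- proc.time()[["elapsed"]]
    S <- foldId != f
    Tt <- foldId == f
    restTemplates <- t(vapply(rest, function(s)
      colMeans(s[S, , drop = FALSE]), numeric(V)))
    restResid <- vector("list", k)
    restAmps <- matrix(0, N, k)
    for (i in seq_len(k)) {
      rr <- residualiseCohort(rest[[i]], restTemplates[i, ])
      restResid[[i]] <- rr$residuals
      restAmps[, i] <- rr$amplitudes
    }
    say("fold %d: residualised rest modes (%.1fs)",
        f, proc.time()[["elapsed"]] - t0)

    reduction <- reduceModes(lapply(restResid, function(s)
      s[S, , drop = FALSE]), d, seed = seed + 1000L + f)
    A_S <- reduction@mixingConcat
    A_T <- projectSubjects(lapply(restResid, function(s)
      s[Tt, , drop = FALSE]), reduction)
    say("fold %d: rest ICA reduction d=%d (%.1fs)",
        f, d, proc.time()[["elapsed"]] - t0)

    # inner-fold rest reductions for honest (cross-fitted) constituent
    # predictions used in stacker selection
    Sidx <- which(S)
    innerId <- makeFolds(ids[Sidx], nestedFolds, seed = seed + 5000L + f)
    innerRest <- lapply(seq_len(nestedFolds), function(g) {
      trIn <- Sidx[innerId != g]
      teIn <- Sidx[innerId == g]
      redg <- reduceModes(lapply(restResid, function(s)
        s[trIn, , drop = FALSE]), d, seed = seed + 1000L + f)
      list(trIn = trIn, teIn = teIn, red = redg,
           A_te = projectSubjects(lapply(restResid, function(s)
             s[teIn, , drop = FALSE]), redg))
    })

    models[[f]] <- list(restTemplates = restTemplates, reduction = reduction,
                        contrasts = stats::setNames(
                          vector("list", length(task)), contrasts))

    for (cc in seq_along(task)) {
      s1 <- task[[cc]][[1L]]
      taskTemplate <- colMeans(s1[S, , drop = FALSE])
      rc1 <- residualiseCohort(s1, taskTemplate)
      Yres <- rc1$residuals
      out[[cc]]$actualResid1[Tt, ] <- Yres[Tt, , drop = FALSE]
      out[[cc]]$taskAmps[Tt] <- rc1$amplitudes[Tt]
      if (nSessions > 1L) {
        rc2 <- residualiseCohort(task[[cc]][[2L]], taskTemplate)
        out[[cc]]$actualResid2[Tt, ] <- rc2$residuals[Tt, , drop = FALSE]
      }

      # predicted variation maps are kept orthogonal to the training-fold
      # group map, as the training targets are by construction
      orth <- function(M) residualiseCohort(M, taskTemplate)$residuals
      trainResid <- lapply(restResid, function(s) s[S, , drop = FALSE])
      testResid <- lapply(restResid, function(s) s[Tt, , drop = FALSE])
      bl <- fitBaseline(trainResid, Yres[S, , drop = FALSE])
      Fb_S <- orth(predictBaseline(bl$beta, trainResid))
      Fb_T <- orth(predictBaseline(bl$beta, testResid))

      taskRed <- reduceTask(Yres[S, , drop = FALSE], p,
                            seed = seed + 2000L + f)
      targets <- if (taskRed@mode == "ica") taskRed@mixing
                 else Yres[S, , drop = FALSE]
      sp <- fitSparse(A_S, targets, nFolds = nestedFolds, nLambda = nLambda,
                      lambdaMinRatio = lambdaMinRatio,
                      seed = seed + 3000L + f, ids = ids[S])
      Fs_S <- orth(predictSparse(sp, A_S, taskRed))
      Fs_T <- orth(predictSparse(sp, A_T, taskRed))
      say("fold %d, %s: sparse model fitted (%.1fs)",
          f, contrasts[cc], proc.time()[["elapsed"]] - t0)

      ampFit <- fitAmplitude(restAmps[S, , drop = FALSE],
                             rc1$amplitudes[S], contrast = contrasts[cc])
      out[[cc]]$predAmps[Tt] <- predictAmplitude(
        ampFit, restAmps[Tt, , drop = FALSE])

      # cross-fitted constituent predictions on the training rows: each
      # inner fold is predicted by constituents trained without it, so the
      # stacker comparison is not flattered by in-sample fitted values
      nS <- length(Sidx)
      Fb_cv <- matrix(0, nS, V)
      Fs_cv <- matrix(0, nS, V)
      for (g in seq_len(nestedFolds)) {
        ir <- innerRest[[g]]
        blg <- fitBaseline(lapply(restResid, function(s)
          s[ir$trIn, , drop = FALSE]), Yres[ir$trIn, , drop = FALSE])
        Fb_cv[innerId == g, ] <- predictBaseline(
          blg$beta, lapply(restResid, function(s) s[ir$teIn, , drop = FALSE]))
        tredg <- reduceTask(Yres[ir$trIn, , drop = FALSE], p,
                            seed = seed + 2000L + f)
        targg <- if (tredg@mode == "ica") tredg@mixing
                 else Yres[ir$trIn, , drop = FALSE]
        spg <- fitSparse(ir$red@mixingConcat, targg, nFolds = nestedFolds,
                         nLambda = nLambda, lambdaMinRatio = lambdaMinRatio,
                         seed = seed + 3000L + f, ids = ids[ir$trIn])
        Fs_cv[innerId == g, ] <- predictSparse(spg, ir$A_te, tredg)
      }
      Fb_cv <- orth(Fb_cv)
      Fs_cv <- orth(Fs_cv)
      stk <- chooseStacker(Yres[S, , drop = FALSE], Fb_cv, Fs_cv,
                           restAmps[S, , drop = FALSE], qGrid, innerId)
      q <- stk$q
      if (stk$mode == "stack") {
        if (q > 0L) {
          pcs <- amplitudePcs(restAmps[S, , drop = FALSE], q)
          sc_S <- pcs$scores
          sc_T <- sweep(restAmps[Tt, , drop = FALSE], 2, pcs$center) %*%
            pcs$loadings
        } else {
          sc_S <- NULL; sc_T <- NULL
        }
        ens <- fitEnsemble(Yres[S, , drop = FALSE], Fb_S, Fs_S, sc_S,
                           contrast = contrasts[cc])
      } else {
        sc_T <- NULL
        ens <- constituentFit(stk$mode, V, contrasts[cc])
      }
      predT <- orth(predictEnsemble(ens, Fb_T, Fs_T, sc_T))

      out[[cc]]$predBaseline[Tt, ] <- Fb_T
      out[[cc]]$predSparse[Tt, ] <- Fs_T
      out[[cc]]$predEnsemble[Tt, ] <- predT
      out[[cc]]$predRecomposed[Tt, ] <- recompose(
        predT, out[[cc]]$predAmps[Tt], taskTemplate)
      models[[f]]$contrasts[[cc]] <- list(
        taskTemplate = taskTemplate, beta = bl$beta, sparse = sp,
        taskReduction = taskRed, ensemble = ens, amplitude = ampFit,
        stacker = stk$mode, q = q)
      say("fold %d, %s: ensemble (q=%d) and predictions done (%.1fs)",
          f, contrasts[cc], q, proc.time()[["elapsed"]] - t0)
    }
  }

  reports <- stats::setNames(vector("list", length(task)), contrasts)
  for (cc in seq_along(task)) {
    o <- out[[cc]]
    s2res <- o$actualResid2
    reports[[cc]] <- list(
      residual = list(
        baseline = evaluatePredictions(o$predBaseline, o$actualResid1, s2res),
        sparse = evaluatePredictions(o$predSparse, o$actualResid1, s2res),
        ensemble = evaluatePredictions(o$predEnsemble, o$actualResid1, s2res)),
      recomposed = evaluatePredictions(
        o$predRecomposed, task[[cc]][[1L]],
        if (nSessions > 1L) task[[cc]][[2L]] else NULL),
      predictions = o,
      amplitude = list(observed = o$taskAmps, predicted = o$predAmps))
  }
  c(reports,
    list(folds = foldId, models = models,
         config = list(folds = folds, d = d, p = p, qGrid = qGrid,
                       nestedFolds = nestedFolds, nLambda = nLambda,
                       lambdaMinRatio = lambdaMinRatio, seed = seed,
                       contrasts = contrasts, N = N, V = V, k = k)))
}

#' Tabulate evaluation measures across models
#'
#' Summarises the residual-space reports of a [runCrossval()] result into one
#' row per contrast and model.
#'
#' @param result a [runCrossval()] return value.
#' @return data.frame with accuracy, mean discriminability, identification
#'   rate, variability-map correlation and (when repeat sessions exist) mean
#'   test-retest reliability.
#' @export
compareModels <- function(result) {
  contrasts <- result$config$contrasts
  rows <- list()
  for (cc in contrasts) {
    for (m in names(result[[cc]]$residual)) {
      r <- result[[cc]]$residual[[m]]
      rows[[length(rows) + 1L]] <- data.frame(
        contrast = cc, model = m, accuracy = r@accuracy,
        discriminability = r@discriminability$mean,
        identification = r@identificationRate,
        variabilityCorr = r@variabilityCorr,
        reliability = if (length(r@reliability)) mean(r@reliability)
                      else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
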