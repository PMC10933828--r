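#' Dual regression of group templates into a subject time series
#'
#' Two-stage least squares: stage 1 regresses the k group template maps into
#' the 4-D (here T x V) time series, one multiple spatial regression per time
#' point, yielding k time courses; stage 2 regresses those time courses back
#' into the series, one multiple temporal regression per voxel, yielding k
#' subject-specific spatial maps. The series is voxelwise temporally demeaned
#' before both stages and no intercept columns are used.
#'
#' @param templates a [GroupTemplates-class] or a k x V matrix of template
#'   maps.
#' @param series T x V matrix of the subject's resting time series.
#' @param normalise_stage1 if `TRUE`, stage-1 time courses are scaled to unit
#'   variance before stage 2 (off by default; with it off, stage-2 maps are
#'   invariant to template scaling).
#' @return a [DualRegressionResult-class].
#' @export
dualRegress <- function(templates, series, normalise_stage1 = FALSE) {
  G <- if (is(templates, "GroupTemplates")) templates@restMaps else templates
  k <- nrow(G)
  if (ncol(series) != ncol(G))
    stop("series voxel count (", ncol(series),
         ") does not match templates (", ncol(G), ")")
  if (nrow(series) <= k)
    stop("need more time points (", nrow(series), ") than templates (", k, ")")
  qrG <- qr(t(G))
  if (qrG$rank < k)
    stop("templates are rank-deficient (rank ", qrG$rank, " < ", k, ")")
  Y <- sweep(series, 2, colMeans(series))
  # stage 1: per time point, series[t, ] ~ template maps over voxels
  TC <- t(qr.coef(qrG, t(Y)))
  if (normalise_stage1) {
    sds <- apply(TC, 2, stats::sd)
    sds[sds == 0] <- 1
    TC <- sweep(TC, 2, sds, "/")
  }
  # stage 2: per voxel, series[, v] ~ time courses
  qrT <- qr(TC)
  if (qrT$rank < k) {
    maps <- pinvMatrix(TC) %*% Y
  } else {
    maps <- qr.coef(qrT, Y)
  }
  maps[is.na(maps)] <- 0
  new("DualRegressionResult", timecourses = TC, subjectMaps = maps)
}

# internal: Moore-Penrose pseudoinverse via SVD
pinvMatrix <- function(A, tol = NULL) {
  s <- svd(A)
  if (is.null(tol)) tol <- max(dim(A)) * max(s$d) * .Machine$double.eps
  keep <- s$d > tol
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}
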