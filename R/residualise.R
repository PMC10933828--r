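#' Residualise a map against a group template
#'
#' Regresses the group-average map out of an individual map, returning the
#' residual (variation) map and the regression slope, recorded as the map's
#' "amplitude". With `intercept = FALSE` (the default) the pair
#' ([residualise()], [recompose()]) is an exact inverse and the residual is
#' orthogonal to the template.
#'
#' @param map numeric vector (or [SpatialMap-class]) of length V.
#' @param template numeric vector (or [SpatialMap-class]) of length V; must
#'   be non-degenerate (norm at least `1e-12 * sqrt(V)`).
#' @param intercept include a constant term in the regression.
#' @return list with `residual` (numeric V), `amplitude` (slope),
#'   `intercept` (fitted constant, 0 when `intercept = FALSE`).
#' @export
residualise <- function(map, template, intercept = FALSE) {
  m <- if (is(map, "SpatialMap")) map@values else as.numeric(map)
  t <- if (is(template, "SpatialMap")) template@values else as.numeric(template)
  if (length(m) != length(t))
    stop("map length (", length(m), ") does not match template (", length(t), ")")
  tn <- sqrt(sum(t^2))
  if (tn < 1e-12 * sqrt(length(t)))
    stop("degenerate template: norm ", tn, " is effectively zero")
  if (intercept) {
    tc <- t - mean(t)
    a <- sum((m - mean(m)) * tc) / sum(tc^2)
    const <- mean(m) - a * mean(t)
    list(residual = m - a * t - const, amplitude = a, intercept = const)
  } else {
    a <- sum(m * t) / sum(t * t)
    list(residual = m - a * t, amplitude = a, intercept = 0)
  }
}

#' Residualise every subject of a stack against a template
#'
#' Row-wise [residualise()]. Inside cross-validation the template must be
#' computed from training subjects only; this function applies whatever
#' template it is given.
#'
#' @param stack a [CohortStack-class] or N x V matrix.
#' @param template numeric vector (or [SpatialMap-class]) of length V.
#' @param intercept include a constant term per subject.
#' @return list with `residuals` (N x V matrix), `amplitudes` (numeric N),
#'   `intercepts` (numeric N).
#' @export
residualiseCohort <- function(stack, template, intercept = FALSE) {
  X <- if (is(stack, "CohortStack")) stack@data else stack
  t <- if (is(template, "SpatialMap")) template@values else as.numeric(template)
  if (ncol(X) != length(t))
    stop("stack voxel count does not match template length")
  tn <- sqrt(sum(t^2))
  if (tn < 1e-12 * sqrt(length(t)))
    stop("degenerate template: norm ", tn, " is effectively zero")
  if (intercept) {
    tc <- t - mean(t)
    Xc <- sweep(X, 1, rowMeans(X))
    a <- drop(Xc %*% tc) / sum(tc^2)
    const <- rowMeans(X) - a * mean(t)
    res <- X - outer(a, t) - const
  } else {
    a <- drop(X %*% t) / sum(t * t)
    const <- rep(0, nrow(X))
    res <- X - outer(a, t)
  }
  list(residuals = res, amplitudes = a, intercepts = const)
}

#' Recompose a full map from a predicted residual and amplitude
#'
#' Adds the group-average map back into a predicted variation map, scaled by
#' the (predicted) activation amplitude: `amplitude * template + residual`.
#'
#' @param residual numeric vector (or matrix, subjects by voxels).
#' @param amplitude scalar (or numeric vector, one per row of `residual`).
#' @param template numeric vector (or [SpatialMap-class]) of length V.
#' @param intercept optional constant (scalar or per-subject vector).
#' @return vector or matrix matching `residual`.
#' @export
recompose <- function(residual, amplitude, template, intercept = 0) {
  t <- if (is(template, "SpatialMap")) template@values else as.numeric(template)
  if (is.matrix(residual)) {
    if (ncol(residual) != length(t)) stop("dimension mismatch")
    residual + outer(as.numeric(amplitude), t) + intercept
  } else {
    if (length(residual) != length(t)) stop("dimension mismatch")
    amplitude * t + residual + intercept
  }
}
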