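#' @import methods
NULL

#' Brain mask over a 3-D voxel grid
#'
#' A `BrainMask` defines the voxel grid, the set of in-mask voxels and the
#' voxel-to-world affine shared by all maps in an analysis. All spatial data in
#' the package live as flat vectors over the in-mask voxels, in C order over
#' the grid (last grid index varying fastest); volumes exist only at the I/O
#' boundary.
#'
#' @slot dim integer(3), voxel counts along each axis.
#' @slot flags logical array of dimension `dim`; `TRUE` marks in-mask voxels.
#' @slot affine 4x4 voxel-to-world transform (must be invertible).
#'
#' @seealso [applyMask()], [restoreVolume()], [gridMask()]
#' @export
setClass("BrainMask",
  representation(dim = "integer", flags = "array", affine = "matrix"))

setValidity("BrainMask", function(object) {
  if (length(object@dim) != 3L) return("dim must have length 3")
  if (!identical(dim(object@flags), object@dim)) return("flags dimension must equal dim")
  if (!is.logical(object@flags)) return("flags must be logical")
  if (sum(object@flags) < 1L) return("mask must contain at least one voxel")
  if (!identical(dim(object@affine), c(4L, 4L))) return("affine must be 4x4")
  detA <- det(object@affine)
  if (!is.finite(detA) || abs(detA) < 1e-12) return("affine must be invertible")
  TRUE
})

#' Spatial map over a mask
#'
#' A single real-valued map over the in-mask voxels of a [BrainMask-class],
#' e.g. a group template, an individual mode map, or a residual (variation)
#' map.
#'
#' @slot values numeric of length `nVoxels(mask)`; all finite.
#' @slot mask the [BrainMask-class] the values are defined over.
#' @slot label free-text label (mode index or contrast name).
#'
#' @export
setClass("SpatialMap",
  representation(values = "numeric", mask = "BrainMask", label = "character"))

setValidity("SpatialMap", function(object) {
  if (length(object@values) != sum(object@mask@flags))
    return("values length must equal the number of in-mask voxels")
  if (!all(is.finite(object@values))) return("values must be finite")
  if (length(object@label) != 1L) return("label must be a single string")
  TRUE
})

#' Subjects-by-voxels stack of maps
#'
#' Maps of the same kind for an ordered cohort of subjects, stored as an
#' N x V matrix over a shared [BrainMask-class] (one subject per row).
#'
#' @slot subjects character vector of unique subject identifiers (row order).
#' @slot data numeric matrix, subjects by in-mask voxels.
#' @slot mask the shared [BrainMask-class].
#'
#' @export
setClass("CohortStack",
  representation(subjects = "character", data = "matrix", mask = "BrainMask"))

setValidity("CohortStack", function(object) {
  if (nrow(object@data) != length(object@subjects))
    return("row count must equal subject count")
  if (anyDuplicated(object@subjects)) return("subject identifiers must be unique")
  if (ncol(object@data) != sum(object@mask@flags))
    return("column count must equal the number of in-mask voxels")
  TRUE
})

#' Group-average spatial templates
#'
#' The k group-average rest-mode maps and the per-contrast group task maps
#' over a shared mask. Rows of `restMaps` are modes; rows of `taskMaps` are
#' contrasts.
#'
#' @slot restMaps k x V matrix of group rest-mode maps.
#' @slot taskMaps C x V matrix of group task contrast maps.
#' @slot restLabels,taskLabels row labels.
#' @slot mask the shared [BrainMask-class].
#'
#' @export
setClass("GroupTemplates",
  representation(restMaps = "matrix", taskMaps = "matrix",
                 restLabels = "character", taskLabels = "character",
                 mask = "BrainMask"))

setValidity("GroupTemplates", function(object) {
  V <- sum(object@mask@flags)
  if (ncol(object@restMaps) != V || ncol(object@taskMaps) != V)
    return("template maps must have one column per in-mask voxel")
  if (nrow(object@restMaps) != length(object@restLabels))
    return("restLabels must match restMaps rows")
  if (nrow(object@taskMaps) != length(object@taskLabels))
    return("taskLabels must match taskMaps rows")
  TRUE
})

#' Synthetic cohort with ground truth
#'
#' A simulated cohort with the generative structure the prediction framework
#' assumes: per-subject rest modes `a * G + R` (amplitude-scaled group
#' template plus an individual residual), task maps `c * T + b + eps` per
#' session with the task residual `b` linearly coupled to the rest residuals,
#' and the full ground truth recorded.
#'
#' @slot spec the generating parameter list (see [syntheticSpec()]).
#' @slot templates a [GroupTemplates-class].
#' @slot restModes list of k [CohortStack-class] objects (one per mode).
#' @slot taskMaps nested list: per contrast, per session, a [CohortStack-class].
#' @slot truth list with elements `restAmps` (N x k true amplitudes a),
#'   `taskAmps` (N x C true amplitudes c), `restResiduals` (list of k N x V
#'   true R matrices), `taskResiduals` (list of C N x V true b matrices),
#'   `coupling` (k x C), `amplitudeWeights` (C x k).
#'
#' @export
setClass("SyntheticCohort",
  representation(spec = "list", templates = "GroupTemplates",
                 restModes = "list", taskMaps = "list", truth = "list"))

#' Dual-regression result for one subject
#'
#' @slot timecourses T x k matrix of stage-1 mode time courses.
#' @slot subjectMaps k x V matrix of stage-2 subject-specific mode maps.
#'
#' @export
setClass("DualRegressionResult",
  representation(timecourses = "matrix", subjectMaps = "matrix"))

setValidity("DualRegressionResult", function(object) {
  if (ncol(object@timecourses) != nrow(object@subjectMaps))
    return("time-course columns must match map rows (k)")
  if (!all(is.finite(object@subjectMaps))) return("maps must be finite")
  TRUE
})

#' Cross-subject ICA reduction of the rest variation matrices
#'
#' Per-mode factorisation `X_i = A_i S_i` of the subjects-by-voxels rest
#' residual stacks, with the k mixing matrices concatenated into the reduced
#' variation matrix used as sparse-model predictors.
#'
#' @slot sources list of k d x V source matrices (unit-variance rows).
#' @slot mixing list of k N x d mixing matrices.
#' @slot mixingConcat N x (d*k) concatenation of the mixing matrices.
#' @slot d integer, components per mode.
#' @slot converged logical(k), FALSE where ICA fell back to the PCA basis.
#'
#' @export
setClass("RestReduction",
  representation(sources = "list", mixing = "list", mixingConcat = "matrix",
                 d = "integer", converged = "logical"))

#' Reduction of the task variation matrix
#'
#' Either a cross-subject ICA factorisation `Y = A S` into p components, or
#' the identity mode in which the Lasso targets are the raw task voxels.
#'
#' @slot mode `"ica"` or `"identity"`.
#' @slot sources p x V source matrix (`ica` mode) or 0 x 0.
#' @slot mixing N x p mixing matrix (`ica` mode) or 0 x 0.
#' @slot p integer, number of targets (V in identity mode).
#'
#' @export
setClass("TaskReduction",
  representation(mode = "character", sources = "matrix", mixing = "matrix",
                 p = "integer"))

setValidity("TaskReduction", function(object) {
  if (!object@mode %in% c("ica", "identity")) return("mode must be 'ica' or 'identity'")
  TRUE
})

#' Per-column Lasso coefficients of the sparse model
#'
#' @slot W (d*k) x p coefficient matrix (p = V in identity task mode).
#' @slot lambda numeric(p), the per-column penalty chosen by nested CV.
#' @slot cvFolds integer, nested CV folds used.
#' @slot sparsity fraction of exact zeros in `W`.
#'
#' @export
setClass("SparseFit",
  representation(W = "matrix", lambda = "numeric", cvFolds = "integer",
                 sparsity = "numeric"))

#' Per-voxel ensemble coefficients
#'
#' Column i of `theta` weights the baseline-fitted value, the sparse-fitted
#' value and (optionally) q rest-amplitude principal components when
#' predicting voxel i.
#'
#' @slot theta m x V coefficient matrix, m = 2 + q.
#' @slot q integer, number of amplitude PCs included.
#' @slot contrast contrast label.
#'
#' @export
setClass("EnsembleFit",
  representation(theta = "matrix", q = "integer", contrast = "character"))

setValidity("EnsembleFit", function(object) {
  if (nrow(object@theta) < 2L) return("theta must have at least two rows")
  if (!all(is.finite(object@theta))) return("theta must be finite")
  TRUE
})

#' Rest-amplitude to task-amplitude linear model
#'
#' @slot weights numeric(k) regression weights on the rest-mode amplitudes.
#' @slot intercept numeric(1).
#' @slot contrast contrast label.
#' @slot r2 training R-squared.
#'
#' @export
setClass("AmplitudeFit",
  representation(weights = "numeric", intercept = "numeric",
                 contrast = "character", r2 = "numeric"))

#' Evaluation report for one set of predictions
#'
#' @slot corrmat n x n Pearson correlation matrix; entry (i, j) is the
#'   correlation between subject i's predicted map and subject j's actual map.
#' @slot accuracy mean of the diagonal (prediction accuracy).
#' @slot discriminability list with `perSubject` and `mean` (Fisher-z
#'   self-correlation minus mean correlation with other subjects' maps).
#' @slot identificationRate fraction of subjects whose own map is the strict
#'   row maximum.
#' @slot variabilityCorr correlation between predicted and actual
#'   between-subject standard-deviation maps.
#' @slot reliability per-subject session-1 vs session-2 correlations (length
#'   0 when no repeat session was available).
#'
#' @export
setClass("EvaluationReport",
  representation(corrmat = "matrix", accuracy = "numeric",
                 discriminability = "list", identificationRate = "numeric",
                 variabilityCorr = "numeric", reliability = "numeric"))
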