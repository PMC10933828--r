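#' Number of in-mask voxels
#'
#' @param x a [BrainMask-class], [SpatialMap-class], [CohortStack-class] or
#'   [SyntheticCohort-class].
#' @return integer voxel count V.
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))

#' @rdname nVoxels
#' @export
setMethod("nVoxels", "BrainMask", function(x) sum(x@flags))

#' @rdname nVoxels
#' @export
setMethod("nVoxels", "SpatialMap", function(x) length(x@values))

#' @rdname nVoxels
#' @export
setMethod("nVoxels", "CohortStack", function(x) ncol(x@data))

#' @rdname nVoxels
#' @export
setMethod("nVoxels", "SyntheticCohort", function(x) nVoxels(x@templates@mask))

#' Subject identifiers
#'
#' @param x a [CohortStack-class] or [SyntheticCohort-class].
#' @return character vector of subject ids in row order.
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname subjectIds
#' @export
setMethod("subjectIds", "CohortStack", function(x) x@subjects)

#' @rdname subjectIds
#' @export
setMethod("subjectIds", "SyntheticCohort",
          function(x) x@restModes[[1L]]@subjects)

#' Number of subjects
#' @param x a [CohortStack-class] or [SyntheticCohort-class].
#' @return integer subject count.
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' @rdname nSubjects
#' @export
setMethod("nSubjects", "CohortStack", function(x) nrow(x@data))

#' @rdname nSubjects
#' @export
setMethod("nSubjects", "SyntheticCohort", function(x) length(subjectIds(x)))

#' Extract the subjects-by-voxels matrix of a stack
#' @param x a [CohortStack-class].
#' @return numeric matrix (subjects by voxels).
#' @export
setGeneric("stackData", function(x) standardGeneric("stackData"))

#' @rdname stackData
#' @export
setMethod("stackData", "CohortStack", function(x) x@data)

#' Mask accessor
#' @param x an object holding a [BrainMask-class].
#' @return the mask.
#' @export
setGeneric("maskOf", function(x) standardGeneric("maskOf"))

#' @rdname maskOf
#' @export
setMethod("maskOf", "SpatialMap", function(x) x@mask)

#' @rdname maskOf
#' @export
setMethod("maskOf", "CohortStack", function(x) x@mask)

#' @rdname maskOf
#' @export
setMethod("maskOf", "GroupTemplates", function(x) x@mask)

#' @rdname maskOf
#' @export
setMethod("maskOf", "SyntheticCohort", function(x) x@templates@mask)

#' Map values accessor
#' @param x a [SpatialMap-class].
#' @return numeric vector of in-mask values.
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @rdname mapValues
#' @export
setMethod("mapValues", "SpatialMap", function(x) x@values)

setMethod("show", "BrainMask", function(object) {
  cat("BrainMask:", paste(object@dim, collapse = " x "), "grid,",
      sum(object@flags), "in-mask voxels\n")
})

setMethod("show", "SpatialMap", function(object) {
  cat("SpatialMap '", object@label, "': ", length(object@values),
      " voxels, range [", format(min(object@values), digits = 4), ", ",
      format(max(object@values), digits = 4), "]\n", sep = "")
})

setMethod("show", "CohortStack", function(object) {
  cat("CohortStack:", nrow(object@data), "subjects x", ncol(object@data),
      "voxels\n")
})

setMethod("show", "GroupTemplates", function(object) {
  cat("GroupTemplates:", nrow(object@restMaps), "rest modes,",
      nrow(object@taskMaps), "task contrasts over", sum(object@mask@flags),
      "voxels\n")
})

setMethod("show", "SyntheticCohort", function(object) {
  s <- object@spec
  cat("SyntheticCohort: N =", s$N, ", V =", s$V, ", k =", s$k,
      "modes,", s$C, "contrasts,", s$sessions, "session(s)\n")
  cat("  sigma_a =", s$sigma_a, ", sigma_b =", s$sigma_b,
      ", sigma_eps =", s$sigma_eps, ", seed =", s$seed, "\n")
})

setMethod("show", "RestReduction", function(object) {
  cat("RestReduction:", length(object@sources), "modes x", object@d,
      "components;", sum(!object@converged), "PCA fallback(s)\n")
})

setMethod("show", "SparseFit", function(object) {
  cat("SparseFit:", nrow(object@W), "predictors x", ncol(object@W),
      "targets; sparsity", format(object@sparsity, digits = 3), "\n")
})

setMethod("show", "EnsembleFit", function(object) {
  cat("EnsembleFit ('", object@contrast, "'): ", nrow(object@theta),
      " predictors x ", ncol(object@theta), " voxels (q = ", object@q,
      " amplitude PCs)\n", sep = "")
})

setMethod("show", "AmplitudeFit", function(object) {
  cat("AmplitudeFit ('", object@contrast, "'): k = ",
      length(object@weights), ", training R^2 = ",
      format(object@r2, digits = 3), "\n", sep = "")
})

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport over", nrow(object@corrmat), "subjects\n")
  cat("  accuracy            ", format(object@accuracy, digits = 4), "\n")
  cat("  discriminability    ", format(object@discriminability$mean, digits = 4), "\n")
  cat("  identification rate ", format(object@identificationRate, digits = 4), "\n")
  cat("  variability corr    ", format(object@variabilityCorr, digits = 4), "\n")
  if (length(object@reliability))
    cat("  test-retest (mean)  ", format(mean(object@reliability), digits = 4), "\n")
})
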