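#' Construct a brain mask
#'
#' @param flags logical 3-D array; `TRUE` marks in-mask voxels.
#' @param affine 4x4 voxel-to-world transform; defaults to 2 mm isotropic.
#' @return a [BrainMask-class].
#' @export
brainMask <- function(flags, affine = diag(c(2, 2, 2, 1))) {
  if (length(dim(flags)) != 3L)
    stop("mask flags must be a 3-D array")
  new("BrainMask", dim = as.integer(dim(flags)),
      flags = array(as.logical(flags), dim = dim(flags)),
      affine = affine)
}

#' Rectangular mask covering the first V voxels of a compact grid
#'
#' Convenience constructor used by the synthetic generator: builds the
#' smallest near-cubic grid holding `V` voxels and marks the first `V` of
#' them (in C order) as in-mask.
#'
#' @param V number of in-mask voxels.
#' @param affine optional 4x4 affine.
#' @return a [BrainMask-class] with `nVoxels(mask) == V`.
#' @export
gridMask <- function(V, affine = diag(c(2, 2, 2, 1))) {
  stopifnot(V >= 1)
  s <- ceiling(V^(1 / 3))
  d3 <- s
  d2 <- s
  d1 <- ceiling(V / (d2 * d3))
  # fill in C order: column-major over the axis-reversed array
  fr <- array(FALSE, dim = c(d3, d2, d1))
  fr[seq_len(V)] <- TRUE
  brainMask(aperm(fr, 3:1), affine = affine)
}

#' Extract in-mask voxels from a volume
#'
#' Linearises a 3-D volume over the in-mask voxels of `mask`, in C order over
#' the grid (last axis fastest). This ordering is fixed package-wide; all
#' V-vectors and subjects-by-voxels matrices use it.
#'
#' @param volume 3-D numeric array with the same grid as `mask`.
#' @param mask a [BrainMask-class].
#' @param label label for the resulting map.
#' @return a [SpatialMap-class].
#' @seealso [restoreVolume()]
#' @export
applyMask <- function(volume, mask, label = "") {
  if (!identical(as.integer(dim(volume)), mask@dim))
    stop("volume dimensions (", paste(dim(volume), collapse = "x"),
         ") do not match mask grid (", paste(mask@dim, collapse = "x"), ")")
  vr <- aperm(volume, 3:1)
  fr <- aperm(mask@flags, 3:1)
  new("SpatialMap", values = as.numeric(vr[fr]), mask = mask, label = label)
}

#' Restore a masked map to a full volume
#'
#' Inverse of [applyMask()]: places the map values back on the grid (C order)
#' and fills out-of-mask voxels with `fill`.
#'
#' @param map a [SpatialMap-class] or a numeric vector of length V.
#' @param mask required when `map` is a bare vector.
#' @param fill value for out-of-mask voxels.
#' @return 3-D numeric array.
#' @export
restoreVolume <- function(map, mask = NULL, fill = 0) {
  if (is(map, "SpatialMap")) {
    mask <- map@mask
    values <- map@values
  } else {
    if (is.null(mask)) stop("mask required for bare vectors")
    values <- as.numeric(map)
  }
  if (length(values) != nVoxels(mask))
    stop("map length (", length(values), ") does not match mask voxel count (",
         nVoxels(mask), ")")
  fr <- aperm(mask@flags, 3:1)
  out <- array(fill, dim = rev(mask@dim))
  out[fr] <- values
  aperm(out, 3:1)
}

#' Write a masked map (or mask) as a NIfTI-1 volume
#'
#' @param x a [SpatialMap-class], [BrainMask-class], or numeric vector.
#' @param path output file (`.nii` or `.nii.gz`).
#' @param mask required when `x` is a bare vector.
#' @param fill out-of-mask fill value.
#' @return the path, invisibly.
#' @export
writeNiftiMap <- function(x, path, mask = NULL, fill = 0) {
  if (is(x, "BrainMask")) {
    mask <- x
    vol <- array(as.numeric(x@flags), dim = x@dim)
  } else {
    vol <- restoreVolume(x, mask = mask, fill = fill)
    if (is(x, "SpatialMap")) mask <- x@mask
  }
  img <- RNifti::asNifti(vol)
  scales <- sqrt(colSums(mask@affine[1:3, 1:3]^2))
  RNifti::pixdim(img) <- scales
  RNifti::sform(img) <- structure(mask@affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a mask
#'
#' Voxels with non-zero intensity are in-mask.
#'
#' @param path NIfTI file.
#' @return a [BrainMask-class] carrying the file's sform/qform affine.
#' @export
readNiftiMask <- function(path) {
  img <- RNifti::readNifti(path)
  vol <- as.array(img)
  if (length(dim(vol)) != 3L) stop("mask volume must be 3-D: ", path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  brainMask(vol != 0, affine = aff)
}

#' Read per-subject NIfTI maps into a cohort stack
#'
#' All volumes must share the mask's grid and affine (affine entries compared
#' with tolerance 1e-4).
#'
#' @param paths named character vector of NIfTI files; names are subject ids
#'   (basenames are used when unnamed).
#' @param mask a [BrainMask-class].
#' @return a [CohortStack-class] with rows in the order of `paths`.
#' @export
readSubjectMaps <- function(paths, mask) {
  ids <- names(paths)
  if (is.null(ids)) ids <- basename(paths)
  data <- matrix(NA_real_, nrow = length(paths), ncol = nVoxels(mask))
  for (i in seq_along(paths)) {
    if (!file.exists(paths[[i]]))
      stop("missing file for subject '", ids[i], "': ", paths[[i]])
    img <- RNifti::readNifti(paths[[i]])
    vol <- as.array(img)
    if (!identical(as.integer(dim(vol)), mask@dim))
      stop("grid mismatch for subject '", ids[i], "': volume is ",
           paste(dim(vol), collapse = "x"), ", mask is ",
           paste(mask@dim, collapse = "x"))
    aff <- unclass(RNifti::xform(img))
    if (max(abs(aff - mask@affine)) > 1e-4)
      stop("affine mismatch for subject '", ids[i], "'")
    data[i, ] <- applyMask(vol, mask)@values
  }
  new("CohortStack", subjects = ids, data = data, mask = mask)
}

#' Write / read a cohort stack as delimited text
#'
#' Headless matrix format for masked data: a TSV with subject ids in the
#' first column and one column per in-mask voxel. The mask itself travels
#' separately (e.g. via [writeNiftiMap()]).
#'
#' @param stack a [CohortStack-class].
#' @param path TSV file.
#' @return `readCohortTable`: a [CohortStack-class]; `writeCohortTable`: the
#'   path, invisibly.
#' @export
writeCohortTable <- function(stack, path) {
  df <- data.frame(subject = stack@subjects, stack@data,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCohortTable
#' @param mask a [BrainMask-class] matching the stored voxel columns.
#' @export
readCohortTable <- function(path, mask) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  data <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(data) <- NULL
  if (ncol(data) != nVoxels(mask))
    stop("stored voxel count (", ncol(data), ") does not match mask (",
         nVoxels(mask), ")")
  new("CohortStack", subjects = as.character(df[[1L]]), data = data,
      mask = mask)
}

# internal: CohortStack from a bare matrix
cohortStack <- function(data, mask, subjects = NULL) {
  if (is.null(subjects)) subjects <- sprintf("sub%04d", seq_len(nrow(data)))
  new("CohortStack", subjects = subjects, data = data, mask = mask)
}
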