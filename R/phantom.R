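#' Construct a voxel mask set
#'
#' @param masks Named list of logical 3D arrays on a common grid, pairwise
#'   disjoint.
#' @param spacingMm Isotropic voxel spacing in millimetres.
#' @return A [VoxelMaskSet-class].
#' @export
voxelMaskSet <- function(masks, spacingMm) {
  if (!length(masks)) stop("at least one mask is required")
  dims <- dim(masks[[1L]])
  if (length(dims) != 3L) stop("masks must be 3D arrays")
  masks <- lapply(masks, function(m) array(as.logical(m), dims))
  new("VoxelMaskSet", dims = as.integer(dims),
      spacingMm = as.numeric(spacingMm), masks = masks)
}

#' Rasterize an ellipsoid phantom into organ masks
#'
#' Builds a synthetic segmentation from labeled ellipsoids, the fixture used
#' to exercise intensity-diffusion computation without real scans. Voxel v
#' has its centre at `(v - 0.5) * spacingMm`; a voxel belongs to an
#' ellipsoid when the normalized squared distance to its centre is <= 1.
#' Where ellipsoids overlap the first label wins (with a warning).
#'
#' @param dims Grid shape, 3 integers.
#' @param spacingMm Isotropic voxel spacing (mm).
#' @param ellipsoids List of `list(label=, center=, semiAxes=)` with center
#'   and semi-axes in mm.
#' @return A [VoxelMaskSet-class].
#' @examples
#' ph <- makePhantom(c(20, 20, 20), 0.2,
#'   list(list(label = "a", center = c(2, 2, 2), semiAxes = c(1, 1, 1))))
#' sum(organMasks(ph)$a)
#' @export
makePhantom <- function(dims, spacingMm, ellipsoids) {
  dims <- as.integer(dims)
  labs <- vapply(ellipsoids, function(e) e$label, "")
  if (anyDuplicated(labs)) stop("ellipsoid labels must be unique")
  cx <- (seq_len(dims[1]) - 0.5) * spacingMm
  cy <- (seq_len(dims[2]) - 0.5) * spacingMm
  cz <- (seq_len(dims[3]) - 0.5) * spacingMm
  claimed <- array(FALSE, dims)
  masks <- list()
  for (e in ellipsoids) {
    d2 <- outer(outer(((cx - e$center[1]) / e$semiAxes[1])^2,
                      ((cy - e$center[2]) / e$semiAxes[2])^2, `+`),
                ((cz - e$center[3]) / e$semiAxes[3])^2, `+`)
    m <- d2 <= 1
    if (any(m & claimed)) {
      warning(sprintf("ellipsoid '%s' overlaps an earlier label; first label wins",
                      e$label))
      m <- m & !claimed
    }
    if (!any(m))
      stop(sprintf("ellipsoid '%s' rasterizes to an empty mask", e$label))
    claimed <- claimed | m
    masks[[e$label]] <- m
  }
  voxelMaskSet(masks, spacingMm)
}

#' Read organ masks from a labeled NIfTI volume
#'
#' @param path Path to an integer-labeled NIfTI volume.
#' @param labels Named integer vector mapping mask names to label values.
#' @param spacingMm Voxel spacing override; taken from the NIfTI header
#'   (first pixel dimension) when `NULL`.
#' @return A [VoxelMaskSet-class].
#' @export
readMaskSet <- function(path, labels, spacingMm = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("reading NIfTI masks requires the RNifti package")
  vol <- RNifti::readNifti(path)
  if (is.null(spacingMm)) spacingMm <- RNifti::pixdim(vol)[1L]
  arr <- as.array(vol)
  masks <- lapply(labels, function(v) arr == v)
  names(masks) <- names(labels)
  voxelMaskSet(masks, spacingMm)
}

#' @rdname accessors
#' @export
setMethod("organMasks", "VoxelMaskSet", function(x, ...) x@masks)

#' @rdname accessors
#' @export
setMethod("voxelSpacing", "VoxelMaskSet", function(x, ...) x@spacingMm)

setMethod("show", "VoxelMaskSet", function(object) {
  cat(sprintf("VoxelMaskSet: %s grid, %.3g mm spacing, %d masks\n",
              paste(object@dims, collapse = "x"), object@spacingMm,
              length(object@masks)))
  for (nm in names(object@masks))
    cat(sprintf("  %-12s %d voxels\n", nm, sum(object@masks[[nm]])))
})
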