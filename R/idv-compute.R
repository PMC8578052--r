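# Intensity-diffusion matrices from segmentation masks.
#
# The blur emulating the optical point-spread is an isotropic truncated
# discrete Gaussian (sigma = FWHM / 2.355), applied separably per axis with
# mirror (reflective) boundaries. Mirror folding makes each axis operator
# column-stochastic, so total intensity on the grid is conserved and the
# "fraction of blurred intensity inside mask j" reading is exact.

# fold an out-of-range index back into 1..n by mirror reflection
.reflectIndex <- function(i, n) {
  while (i < 1L || i > n) {
    if (i < 1L) i <- 1L - i
    if (i > n) i <- 2L * n + 1L - i
  }
  i
}

# n x n one-axis convolution operator for a truncated Gaussian kernel
.gaussAxisOperator <- function(n, sigmaVox) {
  radius <- max(1L, as.integer(ceiling(4 * sigmaVox)))
  offs <- (-radius):radius
  kern <- exp(-offs^2 / (2 * sigmaVox^2))
  kern <- kern / sum(kern)
  Cm <- matrix(0, n, n)
  for (a in seq_len(n)) {
    for (k in seq_along(offs)) {
      b <- .reflectIndex(a + offs[k], n)
      Cm[b, a] <- Cm[b, a] + kern[k]
    }
  }
  Cm
}

# separable 3D Gaussian blur of a numeric array
.blur3d <- function(x, sigmaVox) {
  d <- dim(x)
  ops <- lapply(d, .gaussAxisOperator, sigmaVox = sigmaVox)
  x <- array(ops[[1L]] %*% matrix(x, d[1L], d[2L] * d[3L]), d)
  x <- aperm(x, c(2L, 1L, 3L))
  x <- array(ops[[2L]] %*% matrix(x, d[2L], d[1L] * d[3L]), d[c(2L, 1L, 3L)])
  x <- aperm(x, c(2L, 1L, 3L))
  x <- aperm(x, c(3L, 1L, 2L))
  x <- array(ops[[3L]] %*% matrix(x, d[3L], d[1L] * d[2L]), d[c(3L, 1L, 2L)])
  aperm(x, c(2L, 3L, 1L))
}

#' Compute an intensity-diffusion matrix from organ masks
#'
#' Blurs each organ's binary mask with an isotropic 3D Gaussian
#' (`sigma = fwhmMm / 2.355`) and tabulates, for every source organ, the
#' fraction of its blurred intensity falling inside each organ mask,
#' including the implicit `"others"` region (the complement of all masks).
#' Mirror boundary handling conserves intensity on the grid, so each row
#' sums to 1 exactly and the diagonal dominates for well-separated organs.
#'
#' @param maskSet A [VoxelMaskSet-class] of disjoint organ masks.
#' @param fwhmMm Full width at half maximum of the blur, in millimetres
#'   (0.5 mm reproduces the optical-resolution regime the reference matrix
#'   was derived in).
#' @return k x k matrix over `c(names(masks), "others")`, rows = sources,
#'   columns = measured regions.
#' @examples
#' ph <- makePhantom(c(24, 12, 12), 0.2, list(
#'   list(label = "a", center = c(1.2, 1.2, 1.2), semiAxes = c(0.8, 0.8, 0.8)),
#'   list(label = "b", center = c(3.6, 1.2, 1.2), semiAxes = c(0.8, 0.8, 0.8))))
#' computeIdv(ph, 0.5)
#' @export
computeIdv <- function(maskSet, fwhmMm = 0.5) {
  stopifnot(is(maskSet, "VoxelMaskSet"))
  if (fwhmMm <= 0) stop("fwhmMm must be positive")
  if (fwhmMm < maskSet@spacingMm / 2)
    warning("blur FWHM is below half a voxel; the kernel is under-resolved")
  sigmaVox <- (fwhmMm / 2.355) / maskSet@spacingMm
  masks <- maskSet@masks
  others <- array(TRUE, maskSet@dims)
  for (m in masks) others <- others & !m
  regions <- c(masks, list(others = others))
  k <- length(regions)
  idv <- matrix(0, k, k, dimnames = list(names(regions), names(regions)))
  for (i in seq_len(k)) {
    b <- .blur3d(array(as.numeric(regions[[i]]), maskSet@dims), sigmaVox)
    tot <- sum(b)
    for (j in seq_len(k)) idv[i, j] <- sum(b[regions[[j]]]) / tot
  }
  idv
}
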