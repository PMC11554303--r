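#' Create a volume map
#'
#' A `volume_map` is the package's container for any 3-D voxel image: a
#' trial-wise activation (beta) map, a signature weight map, a binary brain
#' mask, or an integer-labelled atlas. It bundles the value array with a
#' 4x4 voxel-to-world affine (mm, RAS) and a logical brain mask of the same
#' shape. All in-mask values must be finite.
#'
#' @param values Numeric 3-D array of voxel values.
#' @param affine 4x4 numeric voxel-to-world transform in mm. Defaults to a
#'   diagonal transform with `voxel_size_mm` spacing centred on the origin.
#' @param mask Logical array of the same shape as `values`; `TRUE` marks
#'   in-brain voxels. Defaults to all `TRUE`.
#' @param name Character label carried through reports and file names.
#' @param voxel_size_mm Isotropic voxel size used to build the default affine.
#' @return An object of class `volume_map`.
#' @export
volume_map <- function(values, affine = NULL, mask = NULL, name = "map",
                       voxel_size_mm = 3) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3-D array", call. = FALSE)
  if (is.null(affine)) {
    affine <- diag(c(rep(voxel_size_mm, 3), 1))
    affine[1:3, 4] <- -voxel_size_mm * (dim(values) - 1) / 2
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < .Machine$double.eps)
    stop("`affine` must be an invertible 4x4 matrix", call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, dim(values))
  mask <- array(as.logical(mask), dim(mask))
  if (!identical(dim(mask), dim(values)))
    stop("`mask` must have the same shape as `values`", call. = FALSE)
  if (anyNA(mask)) stop("`mask` must not contain NA", call. = FALSE)
  if (any(!is.finite(values[mask])))
    stop("in-mask values must be finite", call. = FALSE)
  structure(
    list(values = values, affine = affine, mask = mask, name = as.character(name)),
    class = "volume_map"
  )
}

#' @export
print.volume_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume_map> %s  [%d x %d x %d], %d in-mask voxels\n",
              x$name, d[1], d[2], d[3], sum(x$mask)))
  invisible(x)
}

#' Test spatial alignment of two volume maps
#'
#' Two maps are aligned when their array shapes are identical and their
#' affines agree element-wise within `tol` (mm).
#'
#' @param a,b `volume_map` objects.
#' @param tol Absolute affine tolerance in mm.
#' @return Logical scalar.
#' @export
is_aligned <- function(a, b, tol = 1e-4) {
  stopifnot(inherits(a, "volume_map"), inherits(b, "volume_map"))
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$affine - b$affine) < tol)
}

stop_if_misaligned <- function(a, b, what = "maps") {
  if (!is_aligned(a, b))
    stop(sprintf("%s are not aligned (shape or affine mismatch); resample first", what),
         call. = FALSE)
  invisible(TRUE)
}

#' Extract in-mask values as a vector
#'
#' Values are returned in the package's fixed linear scan order: column-major
#' (first array index fastest), restricted to `TRUE` mask voxels.
#'
#' @param vol A `volume_map`.
#' @return Numeric vector of length `sum(vol$mask)`.
#' @export
mask_values <- function(vol) {
  as.numeric(vol$values[vol$mask])
}

#' Embed a vector of in-mask values back into a volume
#'
#' Inverse of [mask_values()]: places `x` at the mask's voxels (same
#' column-major order) and zero elsewhere.
#'
#' @param x Numeric vector, length `sum(ref$mask)`.
#' @param ref Reference `volume_map` supplying grid, affine and mask.
#' @param name Label for the new map.
#' @return A `volume_map`.
#' @export
embed_values <- function(x, ref, name = "map") {
  stopifnot(inherits(ref, "volume_map"), length(x) == sum(ref$mask))
  v <- array(0, dim(ref$values))
  v[ref$mask] <- x
  volume_map(v, affine = ref$affine, mask = ref$mask, name = name)
}

# Coordinates (mm) of in-mask voxels in scan order, as an n x 3 matrix.
mask_coords_mm <- function(vol) {
  idx <- which(vol$mask, arr.ind = TRUE)
  ijk1 <- cbind(idx - 1, 1)  # 0-based voxel indices, homogeneous
  xyz <- ijk1 %*% t(vol$affine)
  xyz[, 1:3, drop = FALSE]
}

#' Read a NIfTI volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param mask Optional `volume_map` or logical array to use as mask; by
#'   default every finite voxel is in-mask.
#' @param name Label; defaults to the file name.
#' @return A `volume_map`.
#' @export
read_volume <- function(path, mask = NULL, name = NULL) {
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim(img)[1:3])
  aff <- unclass(RNifti::xform(img))
  if (inherits(mask, "volume_map")) mask <- mask$mask
  if (is.null(mask)) mask <- array(is.finite(vals), dim(vals))
  vals[!is.finite(vals)] <- 0
  volume_map(vals, affine = aff, mask = mask,
             name = if (is.null(name)) basename(path) else name)
}

#' Write a volume map to NIfTI
#'
#' Out-of-mask voxels are written as 0.
#'
#' @param vol A `volume_map`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_map"))
  v <- vol$values
  v[!vol$mask] <- 0
  img <- RNifti::asNifti(v)
  RNifti::pixdim(img) <- abs(diag(vol$affine)[1:3])
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Separable Gaussian smoothing of a 3-D array, sigma in voxels per axis.
# Implemented as three banded-matrix multiplications; kernels are truncated
# at 4 sigma and row-normalised, so a constant array is left unchanged.
gaussian_smooth_3d <- function(arr, sigma) {
  d <- dim(arr)
  sigma <- rep_len(sigma, 3)
  smooth_axis <- function(n, s) {
    if (s <= 0) return(NULL)
    half <- max(1L, ceiling(4 * s))
    offs <- -half:half
    k <- exp(-offs^2 / (2 * s^2))
    K <- matrix(0, n, n)
    for (j in seq_len(n)) {
      i <- j + offs
      ok <- i >= 1 & i <= n
      K[i[ok], j] <- k[ok]
    }
    sweep(K, 2, colSums(K), "/")
  }
  K1 <- smooth_axis(d[1], sigma[1])
  K2 <- smooth_axis(d[2], sigma[2])
  K3 <- smooth_axis(d[3], sigma[3])
  x <- arr
  if (!is.null(K1)) {
    x <- array(t(K1) %*% matrix(x, d[1]), d)
  }
  if (!is.null(K2)) {
    x <- aperm(x, c(2, 1, 3))
    x <- array(t(K2) %*% matrix(x, d[2]), d[c(2, 1, 3)])
    x <- aperm(x, c(2, 1, 3))
  }
  if (!is.null(K3)) {
    x <- aperm(x, c(3, 1, 2))
    x <- array(t(K3) %*% matrix(x, d[3]), d[c(3, 1, 2)])
    x <- aperm(x, c(2, 3, 1))
  }
  x
}

fwhm_to_sigma <- function(fwhm_mm, voxel_size_mm) {
  (fwhm_mm / voxel_size_mm) / (2 * sqrt(2 * log(2)))
}

# Smooth only within the mask, renormalising by the smoothed mask so that
# values near the brain edge are not attenuated toward zero. `den` allows the
# (constant) smoothed mask to be precomputed when smoothing many volumes.
masked_smooth <- function(values, mask, sigma, den = NULL) {
  if (all(sigma <= 0)) return(values)
  num <- gaussian_smooth_3d(values * mask, sigma)
  if (is.null(den)) den <- gaussian_smooth_3d(mask * 1, sigma)
  out <- array(0, dim(values))
  nz <- den > 1e-12
  out[nz] <- num[nz] / den[nz]
  out * mask
}
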