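#' Voxel grid geometry
#'
#' A `voxel_grid` records the array dimensions, physical voxel sizes and the
#' 4x4 affine that maps 0-based voxel indices to millimetre coordinates.
#' It is shared by every volume, series and mask in the package so that
#' millimetre-specified quantities (6-mm smoothing kernels, 6-mm seed
#' spheres, radius-limited region growth) resolve to voxels consistently.
#'
#' @param dims integer vector of length 3, the array dimensions (all >= 1).
#' @param voxel_size_mm numeric vector of length 3, physical voxel edge
#'   lengths in mm (all > 0).
#' @param affine optional 4x4 matrix mapping 0-based voxel indices to mm.
#'   Defaults to a diagonal scaling by `voxel_size_mm` (origin at voxel 0).
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(dims, voxel_size_mm, affine = NULL) {
  dims <- as.integer(dims)
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(dims) != 3L || any(dims < 1L))
    stop("`dims` must be three integers, all >= 1", call. = FALSE)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    stop("`voxel_size_mm` must be three positive reals", call. = FALSE)
  if (is.null(affine)) {
    affine <- diag(c(voxel_size_mm, 1))
  }
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)) || !all(is.finite(affine)))
    stop("`affine` must be a finite 4x4 matrix", call. = FALSE)
  if (abs(det(affine)) < .Machine$double.eps)
    stop("`affine` must be invertible", call. = FALSE)
  structure(
    list(dims = dims, voxel_size_mm = voxel_size_mm, affine = affine),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("<voxel_grid> ", paste(x$dims, collapse = " x "),
      " voxels, ", paste(signif(x$voxel_size_mm, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(a$dims, b$dims) &&
    max(abs(a$voxel_size_mm - b$voxel_size_mm)) < tol &&
    max(abs(a$affine - b$affine)) < tol
}

stopifnot_same_grid <- function(a, b, what = "objects") {
  if (!same_grid(a, b))
    stop(sprintf("%s are not defined on the same voxel grid", what),
         call. = FALSE)
  invisible(TRUE)
}

#' Convert between 0-based voxel indices and mm coordinates
#'
#' Voxel indices are 0-based, matching the NIfTI convention that the affine
#' maps index (0,0,0) to the origin. `mm_to_vox0` returns fractional indices;
#' round and add 1 to address an R array.
#'
#' @param grid a [voxel_grid()].
#' @param vox0,mm numeric length-3 coordinate (or 3-column matrix).
#' @return A coordinate (or matrix) in the other space.
#' @export
vox0_to_mm <- function(grid, vox0) {
  was_vector <- !is.matrix(vox0)
  v <- rbind(t(matrix(as.numeric(vox0), ncol = 3)), 1)
  out <- t(grid$affine %*% v)[, 1:3, drop = FALSE]
  if (was_vector && length(vox0) == 3L) drop(out) else out
}

#' @rdname vox0_to_mm
#' @export
mm_to_vox0 <- function(grid, mm) {
  was_vector <- !is.matrix(mm)
  v <- rbind(t(matrix(as.numeric(mm), ncol = 3)), 1)
  out <- t(solve(grid$affine) %*% v)[, 1:3, drop = FALSE]
  if (was_vector && length(mm) == 3L) drop(out) else out
}

# resolve a user-supplied point (0-based voxel or mm) to a 1-based array index
resolve_point <- function(grid, point, space = c("voxel", "mm")) {
  space <- match.arg(space)
  if (length(point) != 3L || any(!is.finite(point)))
    stop("a seed point must be three finite coordinates", call. = FALSE)
  vox0 <- if (space == "mm") mm_to_vox0(grid, point) else as.numeric(point)
  idx <- as.integer(round(vox0)) + 1L
  if (any(idx < 1L) || any(idx > grid$dims))
    stop("seed point falls outside the image bounds", call. = FALSE)
  idx
}

#' Scalar volume on a voxel grid
#'
#' @param values a 3D numeric array whose dimensions equal `grid$dims`.
#' @param grid a [voxel_grid()].
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(values, grid) {
  values <- as.array(values)
  if (!identical(dim(values), grid$dims))
    stop("value array shape does not match the grid dimensions", call. = FALSE)
  if (!all(is.finite(values)))
    stop("volume values must all be finite", call. = FALSE)
  structure(list(values = values, grid = grid), class = "volume3d")
}

#' 4D BOLD series on a voxel grid
#'
#' @param values a 4D numeric array `(x, y, z, t)` with `t >= 2`.
#' @param grid a [voxel_grid()].
#' @param tr_seconds repetition time in seconds (> 0).
#' @return An object of class `series4d`.
#' @export
series4d <- function(values, grid, tr_seconds) {
  values <- as.array(values)
  if (length(dim(values)) != 4L || !identical(dim(values)[1:3], grid$dims))
    stop("series shape does not match the grid dimensions", call. = FALSE)
  if (dim(values)[4] < 2L)
    stop("a series needs at least 2 frames", call. = FALSE)
  if (!all(is.finite(values)))
    stop("series values must all be finite", call. = FALSE)
  if (!is.finite(tr_seconds) || tr_seconds <= 0)
    stop("`tr_seconds` must be positive", call. = FALSE)
  structure(list(values = values, grid = grid,
                 n_frames = dim(values)[4], tr_seconds = tr_seconds),
            class = "series4d")
}

#' Binary mask on a voxel grid
#'
#' @param member a logical 3D array (brain mask, tumor template, or a
#'   thresholded component map).
#' @param grid a [voxel_grid()].
#' @return An object of class `binary_mask` with an `n_voxels` field.
#' @export
binary_mask <- function(member, grid) {
  member <- as.array(member)
  storage.mode(member) <- "logical"
  if (!identical(dim(member), grid$dims))
    stop("mask shape does not match the grid dimensions", call. = FALSE)
  if (anyNA(member)) stop("mask must not contain NA", call. = FALSE)
  structure(list(member = member, grid = grid,
                 n_voxels = sum(member)),
            class = "binary_mask")
}

#' @export
print.volume3d <- function(x, ...) {
  cat("<volume3d> "); print(x$grid); invisible(x)
}

#' @export
print.series4d <- function(x, ...) {
  cat("<series4d> ", x$n_frames, " frames, TR ", x$tr_seconds, " s\n  ",
      sep = "")
  print(x$grid); invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", x$n_voxels, " voxels\n  ", sep = "")
  print(x$grid); invisible(x)
}

#' Number of member voxels of a mask
#' @param mask a [binary_mask()].
#' @return Integer count of `TRUE` voxels.
#' @export
n_voxels <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  mask$n_voxels
}

#' Voxelwise mean image of a 4D series
#' @param series a [series4d()].
#' @return A [volume3d()] of temporal means.
#' @export
mean_volume <- function(series) {
  stopifnot(inherits(series, "series4d"))
  m <- rowMeans(matrix(series$values, prod(series$grid$dims),
                       series$n_frames))
  volume3d(array(m, series$grid$dims), series$grid)
}

#' Dice overlap coefficient of two binary masks
#'
#' `2|A intersect B| / (|A| + |B|)`; returns `NA` when both masks are empty.
#'
#' @param a,b [binary_mask()] objects on the same grid.
#' @return The Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  stopifnot_same_grid(a$grid, b$grid, "masks")
  denom <- a$n_voxels + b$n_voxels
  if (denom == 0L) return(NA_real_)
  2 * sum(a$member & b$member) / denom
}
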