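#' Read a NIfTI-1 volume or series
#'
#' 3D files are returned as [volume3d()], 4D files as [series4d()] (with the
#' repetition time taken from the header's fourth pixdim). The voxel grid
#' carries the header's voxel sizes and xform affine, so downstream
#' millimetre-specified operations work in the image's native space.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [volume3d()] or [series4d()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop(sprintf("NIfTI file does not exist: %s", path), call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop(sprintf("cannot read NIfTI file %s: %s",
                                 path, conditionMessage(e)), call. = FALSE))
  d <- dim(img)
  if (!length(d) %in% c(3L, 4L))
    stop(sprintf("%s: only 3D and 4D NIfTI images are supported", path),
         call. = FALSE)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  vs <- RNifti::pixdim(img)[1:3]
  grid <- voxel_grid(d[1:3], vs, aff)
  vals <- as.array(img)
  attributes(vals) <- list(dim = d)
  if (length(d) == 3L) {
    volume3d(vals, grid)
  } else {
    tr <- img$pixdim[5]
    if (!is.finite(tr) || tr <= 0) tr <- 1
    series4d(vals, grid, tr_seconds = tr)
  }
}

#' Write a volume, series or mask as NIfTI-1
#'
#' Masks are encoded as unsigned 8-bit 0/1 volumes. Values and the affine
#' round-trip exactly through [read_volume()].
#'
#' @param vol a [volume3d()], [series4d()] or [binary_mask()].
#' @param path output path (`.nii` or `.nii.gz`); the parent directory must
#'   be writable.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (inherits(vol, "binary_mask")) {
    vals <- array(as.integer(vol$member), vol$grid$dims)
    storage.mode(vals) <- "integer"
    grid <- vol$grid
    datatype <- "uint8"  # masks stored as 0/1 bytes
  } else if (inherits(vol, "volume3d") || inherits(vol, "series4d")) {
    vals <- vol$values
    grid <- vol$grid
    datatype <- "double"
  } else {
    stop("`vol` must be a volume3d, series4d or binary_mask", call. = FALSE)
  }
  img <- RNifti::asNifti(vals)
  # pixdim length must match the image dimensionality, and must be set
  # before the xforms or their scaling is normalised away
  if (inherits(vol, "series4d")) {
    RNifti::pixdim(img) <- c(grid$voxel_size_mm, vol$tr_seconds)
  } else {
    RNifti::pixdim(img) <- grid$voxel_size_mm
  }
  RNifti::sform(img) <- structure(grid$affine, code = 2L)
  RNifti::qform(img) <- structure(grid$affine, code = 2L)
  ok <- tryCatch({ RNifti::writeNifti(img, path, datatype = datatype); TRUE },
                 error = function(e) FALSE)
  if (!ok || !file.exists(path))
    stop(sprintf("cannot write NIfTI file: %s", path), call. = FALSE)
  invisible(path)
}
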