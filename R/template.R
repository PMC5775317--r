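#' Parameters for intensity-based 3D region growth
#'
#' The three intensity parameters mirror the classic VOI-drawing controls of
#' GUI neuroimaging tools: a radius that bounds the growth around the seed,
#' an intensity band around the seed ("difference from origin") and a local
#' step constraint between neighbouring voxels ("difference from edge").
#'
#' @param seed_point length-3 seed coordinate.
#' @param seed_space `"voxel"` (0-based indices) or `"mm"`.
#' @param radius_mm maximum mm distance from the seed (> 0).
#' @param diff_from_origin maximum absolute intensity difference from the
#'   seed voxel (>= 0).
#' @param diff_from_edge maximum absolute intensity difference between a
#'   voxel and the admitted neighbour it grows from (>= 0).
#' @param closing_radius_vox radius (voxels) of one morphological closing
#'   applied after growth to polish the edge; 0 disables it.
#' @return An object of class `growth_params`.
#' @export
growth_params <- function(seed_point, seed_space = c("voxel", "mm"),
                          radius_mm, diff_from_origin, diff_from_edge,
                          closing_radius_vox = 1L) {
  seed_space <- match.arg(seed_space)
  if (!is.finite(radius_mm) || radius_mm <= 0)
    stop("`radius_mm` must be > 0", call. = FALSE)
  if (diff_from_origin < 0 || diff_from_edge < 0)
    stop("intensity differences must be nonnegative", call. = FALSE)
  structure(list(seed_point = as.numeric(seed_point),
                 seed_space = seed_space,
                 radius_mm = as.numeric(radius_mm),
                 diff_from_origin = as.numeric(diff_from_origin),
                 diff_from_edge = as.numeric(diff_from_edge),
                 closing_radius_vox = as.integer(closing_radius_vox)),
            class = "growth_params")
}

#' Grow a rough tumor template from an anatomical image
#'
#' Breadth-first 26-connected growth from the seed. A voxel is admitted when
#' it (a) touches an already admitted voxel, (b) lies within
#' `diff_from_origin` of the seed intensity, (c) lies within `diff_from_edge`
#' of *some* admitted neighbour's intensity, and (d) is within `radius_mm`
#' of the seed in mm. Because (c) is evaluated against any admitted
#' neighbour, the admitted set is the unique monotone closure of the seed and
#' does not depend on traversal order. One optional morphological closing
#' then polishes the edge; the result is clipped back to the radius bound and
#' always contains the seed.
#'
#' @param anat a [volume3d()] anatomical image.
#' @param params a [growth_params()].
#' @return An object of class `tumor_template`: a list with `mask`
#'   ([binary_mask()]), `params` and `source_image_id`.
#' @export
grow_voi <- function(anat, params) {
  stopifnot(inherits(anat, "volume3d"), inherits(params, "growth_params"))
  grid <- anat$grid
  seed <- resolve_point(grid, params$seed_point, params$seed_space)
  v <- anat$values
  dims <- grid$dims
  seed_lin <- seed[1] + (seed[2] - 1L) * dims[1] +
    (seed[3] - 1L) * dims[1] * dims[2]
  i_seed <- v[seed_lin]
  if (!is.finite(i_seed))
    stop("seed voxel intensity is not finite", call. = FALSE)

  # precompute the admissible field: intensity band + radius bound
  mm <- vox0_to_mm(grid, arrayInd(seq_len(prod(dims)), dims) - 1L)
  seed_mm <- vox0_to_mm(grid, seed - 1L)
  dist_ok <- sqrt((mm[, 1] - seed_mm[1])^2 + (mm[, 2] - seed_mm[2])^2 +
                  (mm[, 3] - seed_mm[3])^2) <= params$radius_mm + 1e-9
  band_ok <- abs(v - i_seed) <= params$diff_from_origin + 1e-12
  eligible <- array(band_ok & dist_ok, dims)

  offs <- conn_offsets(26L)
  admitted <- array(FALSE, dims)
  admitted[seed_lin] <- TRUE
  frontier <- seed_lin
  while (length(frontier)) {
    co <- arrayInd(frontier, dims)
    n <- nrow(co); m <- nrow(offs)
    nb <- co[rep(seq_len(n), each = m), , drop = FALSE] +
      offs[rep(seq_len(m), times = n), , drop = FALSE]
    parent <- rep(frontier, each = m)
    keep <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
      nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    nb_lin <- nb[keep, 1] + (nb[keep, 2] - 1L) * dims[1] +
      (nb[keep, 3] - 1L) * dims[1] * dims[2]
    parent <- parent[keep]
    ok <- eligible[nb_lin] & !admitted[nb_lin] &
      abs(v[nb_lin] - v[parent]) <= params$diff_from_edge + 1e-12
    new <- unique(nb_lin[ok])
    admitted[new] <- TRUE
    frontier <- new
  }
  if (params$closing_radius_vox > 0L) {
    admitted <- close_member(admitted, params$closing_radius_vox)
    admitted <- admitted & array(dist_ok, dims)
    admitted[seed_lin] <- TRUE
  }
  structure(list(mask = binary_mask(admitted, grid),
                 params = params,
                 source_image_id = digest_volume(anat)),
            class = "tumor_template")
}

digest_volume <- function(vol) {
  f <- tempfile(fileext = ".bin")
  on.exit(unlink(f))
  writeBin(as.numeric(vol$values), f)
  unname(tools::md5sum(f))
}

#' Summary statistics of a tumor template
#'
#' @param t a `tumor_template` from [grow_voi()], or a [binary_mask()].
#' @return A one-row tibble with `n_voxels`, `volume_mm3` and the centroid in
#'   mm (`centroid_x/y/z`).
#' @export
template_stats <- function(t) {
  mask <- if (inherits(t, "tumor_template")) t$mask else t
  stopifnot(inherits(mask, "binary_mask"))
  grid <- mask$grid
  vox_vol <- prod(grid$voxel_size_mm)
  idx <- which(mask$member)
  if (!length(idx))
    return(tibble::tibble(n_voxels = 0L, volume_mm3 = 0,
                          centroid_x = NA_real_, centroid_y = NA_real_,
                          centroid_z = NA_real_))
  mm <- vox0_to_mm(grid, arrayInd(idx, grid$dims) - 1L)
  ctr <- colMeans(mm)
  tibble::tibble(n_voxels = length(idx),
                 volume_mm3 = length(idx) * vox_vol,
                 centroid_x = ctr[1], centroid_y = ctr[2], centroid_z = ctr[3])
}

#' Coerce a binary mask into a tumor template
#'
#' Useful when the template comes from ground truth (phantoms) or an external
#' segmentation rather than from [grow_voi()].
#'
#' @param mask a [binary_mask()].
#' @param id identifier recorded as the template's source.
#' @return A `tumor_template`.
#' @export
as_tumor_template <- function(mask, id = "external") {
  stopifnot(inherits(mask, "binary_mask"))
  if (mask$n_voxels < 1L) stop("template mask is empty", call. = FALSE)
  structure(list(mask = mask, params = NULL, source_image_id = id),
            class = "tumor_template")
}
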