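#' Spherical seed specification for seed-based correlation
#'
#' @param center length-3 seed centre coordinate.
#' @param space `"voxel"` (0-based indices) or `"mm"`.
#' @param radius_mm sphere radius in mm (default 6, the conventional seed
#'   size); membership is by voxel-centre distance.
#' @param r_thresholds strictly increasing correlation thresholds in (0, 1)
#'   used when binarizing the map (default 0.5 and 0.8).
#' @return An object of class `seed_spec`.
#' @export
seed_spec <- function(center, space = c("voxel", "mm"), radius_mm = 6,
                      r_thresholds = c(0.5, 0.8)) {
  space <- match.arg(space)
  if (!is.finite(radius_mm) || radius_mm <= 0)
    stop("`radius_mm` must be > 0", call. = FALSE)
  if (any(r_thresholds <= 0) || any(r_thresholds >= 1) ||
      any(diff(r_thresholds) <= 0))
    stop("`r_thresholds` must be strictly increasing within (0, 1)",
         call. = FALSE)
  structure(list(center = as.numeric(center), space = space,
                 radius_mm = as.numeric(radius_mm),
                 r_thresholds = as.numeric(r_thresholds)),
            class = "seed_spec")
}

sphere_member <- function(grid, center, space, radius_mm) {
  ctr_vox1 <- resolve_point(grid, center, space)
  ctr_mm <- vox0_to_mm(grid, ctr_vox1 - 1L)
  mm <- vox0_to_mm(grid, arrayInd(seq_len(prod(grid$dims)), grid$dims) - 1L)
  d <- sqrt((mm[, 1] - ctr_mm[1])^2 + (mm[, 2] - ctr_mm[2])^2 +
            (mm[, 3] - ctr_mm[3])^2)
  array(d <= radius_mm + 1e-9, grid$dims)
}

#' Seed-based Pearson correlation map
#'
#' The seed time course is the unweighted mean of the in-sphere mask voxels;
#' the map holds each mask voxel's Pearson correlation with it (in-seed
#' voxels included). This is the classical comparator for ICA-based tumor
#' delineation.
#'
#' @param series a [series4d()].
#' @param mask the analysis [binary_mask()].
#' @param seed a [seed_spec()].
#' @return An object of class `correlation_map`: `r` (3D array, `NA` outside
#'   the mask), `grid`, `seed`.
#' @export
seed_correlation <- function(series, mask, seed) {
  stopifnot(inherits(series, "series4d"), inherits(mask, "binary_mask"),
            inherits(seed, "seed_spec"))
  stopifnot_same_grid(series$grid, mask$grid, "series and mask")
  sph <- sphere_member(series$grid, seed$center, seed$space, seed$radius_mm)
  in_seed <- which(sph & mask$member)
  if (!length(in_seed))
    stop("seed sphere does not intersect the mask", call. = FALSE)
  X <- matrix(series$values, prod(series$grid$dims), series$n_frames)
  course <- colMeans(X[in_seed, , drop = FALSE])
  if (stats::sd(course) == 0)
    stop("seed time course has zero variance", call. = FALSE)
  idx <- which(mask$member)
  r_vals <- as.vector(stats::cor(course, t(X[idx, , drop = FALSE])))
  r_vals[is.na(r_vals)] <- 0  # zero-variance voxels correlate with nothing
  r <- array(NA_real_, series$grid$dims)
  r[idx] <- r_vals
  structure(list(r = r, grid = series$grid, seed = seed),
            class = "correlation_map")
}

#' Threshold a correlation map into a binary mask
#'
#' No cluster-extent filtering is applied (none is conventional for this
#' baseline).
#'
#' @param cmap a `correlation_map`.
#' @param r_thr threshold in (0, 1); voxels with `r > r_thr` are kept.
#' @return A [binary_mask()].
#' @export
threshold_correlation <- function(cmap, r_thr) {
  stopifnot(inherits(cmap, "correlation_map"))
  if (!is.finite(r_thr) || r_thr <= 0 || r_thr >= 1)
    stop("`r_thr` must lie in (0, 1)", call. = FALSE)
  member <- !is.na(cmap$r) & cmap$r > r_thr
  binary_mask(member, cmap$grid)
}
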