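#' Configuration of a repeated spatial ICA decomposition
#'
#' @param tncs model order: the total number of components requested.
#' @param n_runs number of ICA repetitions with randomised initial rotations
#'   (25 is the conventional choice; tests use fewer).
#' @param base_rng_seed integer; run `i` uses seed `base_rng_seed + i - 1`.
#' @param max_iter maximum Infomax iterations per run.
#' @param convergence_tol convergence tolerance on the unmixing update.
#' @return An object of class `decomposition_config`.
#' @export
decomposition_config <- function(tncs, n_runs = 25L, base_rng_seed = 1L,
                                 max_iter = 500L, convergence_tol = 1e-5) {
  tncs <- as.integer(tncs); n_runs <- as.integer(n_runs)
  if (is.na(tncs) || tncs < 2L)
    stop("`tncs` must be an integer >= 2", call. = FALSE)
  if (is.na(n_runs) || n_runs < 1L)
    stop("`n_runs` must be >= 1", call. = FALSE)
  structure(list(tncs = tncs, n_runs = n_runs,
                 base_rng_seed = as.integer(base_rng_seed),
                 max_iter = as.integer(max_iter),
                 convergence_tol = convergence_tol),
            class = "decomposition_config")
}

#' PCA dimension reduction of a masked 4D series
#'
#' Builds the voxel-by-time matrix over mask voxels, removes each voxel's
#' temporal mean, and keeps the top `tncs` principal components. The
#' whitened spatial scores feed the ICA runs; the temporal loadings
#' reconstruct component time courses afterwards.
#'
#' @param series a [series4d()].
#' @param mask a [binary_mask()] selecting the voxels to decompose.
#' @param tncs number of components to retain (`2 <= tncs < n_frames`).
#' @return A list of class `reduced_bold` with the whitened spatial matrix
#'   (`whitened`, voxels x tncs), temporal loadings, singular values, the
#'   retained-variance fraction and bookkeeping fields.
#' @export
reduce_pca <- function(series, mask, tncs) {
  stopifnot(inherits(series, "series4d"), inherits(mask, "binary_mask"))
  stopifnot_same_grid(series$grid, mask$grid, "series and mask")
  tncs <- as.integer(tncs)
  if (mask$n_voxels < 1L) stop("mask is empty", call. = FALSE)
  if (tncs < 2L || tncs >= series$n_frames)
    stop(sprintf("`tncs` must satisfy 2 <= tncs < n_frames (= %d)",
                 series$n_frames), call. = FALSE)
  if (tncs >= mask$n_voxels)
    stop("`tncs` must be smaller than the number of mask voxels",
         call. = FALSE)
  X <- matrix(series$values, prod(series$grid$dims), series$n_frames)
  X <- X[which(mask$member), , drop = FALSE]
  X <- X - rowMeans(X)
  sv <- svd(X, nu = tncs, nv = tncs)
  ev <- sv$d^2
  structure(list(
    whitened = sv$u[, seq_len(tncs), drop = FALSE] * sqrt(nrow(X) - 1),
    temporal = sv$v[, seq_len(tncs), drop = FALSE],
    d = sv$d[seq_len(tncs)],
    var_retained = sum(ev[seq_len(tncs)]) / sum(ev),
    centered = X,
    tncs = tncs, n_frames = series$n_frames, mask = mask),
    class = "reduced_bold")
}

random_orthogonal <- function(k) {
  qr_d <- qr(matrix(stats::rnorm(k * k), k, k))
  q <- qr.Q(qr_d)
  q * rep(sign(diag(qr.R(qr_d))), each = k)
}

#' One Infomax ICA run on reduced data
#'
#' Rotates the whitened spatial scores with Infomax (logistic nonlinearity,
#' Newton-type updates) from a random orthogonal initial rotation drawn from
#' `rng_seed`. Deterministic given the seed. Non-convergence within
#' `cfg$max_iter` is flagged on the result, which is retained.
#'
#' @param reduced a `reduced_bold` from [reduce_pca()].
#' @param rng_seed integer seed for the initial rotation.
#' @param cfg a [decomposition_config()].
#' @return A list of class `ica_run`: `maps` (mask voxels x tncs spatial
#'   sources), `time_courses` (frames x tncs), `converged`, `seed`.
#' @export
run_ica_once <- function(reduced, rng_seed, cfg) {
  stopifnot(inherits(reduced, "reduced_bold"),
            inherits(cfg, "decomposition_config"))
  k <- reduced$tncs
  fit <- withr::with_seed(as.integer(rng_seed), {
    R0 <- random_orthogonal(k)
    ica::icaimax(reduced$whitened, nc = k, center = TRUE,
                 maxit = cfg$max_iter, tol = cfg$convergence_tol,
                 Rmat = R0, alg = "newton", fun = "log")
  })
  maps <- fit$S
  # time courses: least-squares mixing of the centred data onto the maps,
  # computed in the reduced basis (centred = U D V', maps = whitened W)
  utS <- crossprod(reduced$whitened, maps) / (nrow(maps) - 1)
  A <- reduced$temporal %*% (reduced$d * utS) %*% solve(crossprod(maps) /
                                                        (nrow(maps) - 1)) /
    sqrt(nrow(maps) - 1)
  structure(list(maps = maps, time_courses = A,
                 converged = isTRUE(fit$converged),
                 seed = as.integer(rng_seed), tncs = k),
            class = "ica_run")
}

#' Merge repeated ICA runs into one reproducible component set
#'
#' Components are matched across runs by greedy maximum absolute spatial
#' correlation against the first run's components (each run contributes
#' exactly one member per cluster; ties break toward the lower component
#' index). Members are sign-aligned to the exemplar and averaged; each
#' cluster's reproducibility is the mean pairwise absolute spatial
#' correlation of its members. Merged maps are sign-flipped so their skewness
#' over mask voxels is positive, z-standardised over mask voxels (mean 0,
#' SD 1), and ordered by descending reproducibility.
#'
#' @param runs a list of `ica_run` objects sharing `tncs` and mask.
#' @param mask the [binary_mask()] the maps live on.
#' @return An object of class `component_set`: `tncs`, `maps` (voxels x
#'   tncs z-maps), `time_courses`, `reproducibility` (1 when a single run is
#'   merged), `converged`, `mask`.
#' @export
merge_runs_raicar <- function(runs, mask) {
  stopifnot(length(runs) >= 1L, all(vapply(runs, inherits, TRUE, "ica_run")))
  k <- runs[[1]]$tncs
  if (any(vapply(runs, function(r) r$tncs, 1L) != k))
    stop("all runs must share the same `tncs`", call. = FALSE)
  if (any(vapply(runs, function(r) nrow(r$maps), 1L) != nrow(runs[[1]]$maps)))
    stop("all runs must share the same mask", call. = FALSE)
  R <- length(runs)
  maps1 <- runs[[1]]$maps
  mem_map <- array(0, c(nrow(maps1), k, R))
  mem_tc <- array(0, c(nrow(runs[[1]]$time_courses), k, R))
  mem_map[, , 1] <- maps1
  mem_tc[, , 1] <- runs[[1]]$time_courses
  for (r in seq_len(R)[-1]) {
    cc <- stats::cor(maps1, runs[[r]]$maps)  # k x k exemplar-by-member
    assigned <- rep(FALSE, k)
    for (j in seq_len(k)) {
      cand <- abs(cc[j, ])
      cand[assigned] <- -Inf
      pick <- which.max(cand)  # which.max takes the first (lowest index) tie
      assigned[pick] <- TRUE
      s <- if (cc[j, pick] < 0) -1 else 1
      mem_map[, j, r] <- s * runs[[r]]$maps[, pick]
      mem_tc[, j, r] <- s * runs[[r]]$time_courses[, pick]
    }
  }
  maps <- matrix(0, nrow(maps1), k)
  tcs <- matrix(0, nrow(mem_tc), k)
  repro <- numeric(k)
  for (j in seq_len(k)) {
    members <- mem_map[, j, , drop = TRUE]
    if (R == 1L) {
      members <- matrix(members, ncol = 1)
      repro[j] <- 1
    } else {
      cm <- abs(stats::cor(members))
      repro[j] <- mean(cm[upper.tri(cm)])
    }
    m <- rowMeans(members)
    if (spatial_skewness(m) < 0) {
      m <- -m
      tcs[, j] <- -rowMeans(mem_tc[, j, , drop = FALSE], dims = 1)
    } else {
      tcs[, j] <- rowMeans(mem_tc[, j, , drop = FALSE], dims = 1)
    }
    maps[, j] <- (m - mean(m)) / stats::sd(m)
  }
  ord <- order(-repro)
  structure(list(tncs = k,
                 maps = maps[, ord, drop = FALSE],
                 time_courses = tcs[, ord, drop = FALSE],
                 reproducibility = repro[ord],
                 converged = vapply(runs, function(r) r$converged, TRUE),
                 mask = mask),
            class = "component_set")
}

spatial_skewness <- function(x) {
  m <- mean(x); s <- stats::sd(x)
  if (s == 0) return(0)
  mean(((x - m) / s)^3)
}

#' Decompose a masked series at one model order
#'
#' Runs [reduce_pca()], then `cfg$n_runs` Infomax runs with seeds
#' `base_rng_seed`, `base_rng_seed + 1`, ..., then [merge_runs_raicar()].
#'
#' @param series a [series4d()].
#' @param mask a [binary_mask()].
#' @param cfg a [decomposition_config()].
#' @return A `component_set` (see [merge_runs_raicar()]).
#' @export
decompose <- function(series, mask, cfg) {
  stopifnot(inherits(cfg, "decomposition_config"))
  reduced <- reduce_pca(series, mask, cfg$tncs)
  runs <- lapply(seq_len(cfg$n_runs), function(i)
    run_ica_once(reduced, cfg$base_rng_seed + i - 1L, cfg))
  cset <- merge_runs_raicar(runs, mask)
  cset$var_retained <- reduced$var_retained
  cset
}

#' @export
print.component_set <- function(x, ...) {
  cat("<component_set> ", x$tncs, " components over ", x$mask$n_voxels,
      " voxels\n  reproducibility: ",
      paste(sprintf("%.2f", utils::head(x$reproducibility, 8)),
            collapse = " "),
      if (x$tncs > 8) " ..." else "", "\n", sep = "")
  invisible(x)
}

#' Extract one component's spatial z-map as a volume
#'
#' Mask voxels carry the z-standardised map; voxels outside the mask are 0.
#'
#' @param cset a `component_set`.
#' @param k component index (1-based, reproducibility order).
#' @return A [volume3d()].
#' @export
component_map <- function(cset, k) {
  stopifnot(inherits(cset, "component_set"))
  k <- as.integer(k)
  if (k < 1L || k > ncol(cset$maps))
    stop("component index out of range", call. = FALSE)
  vol <- array(0, cset$mask$grid$dims)
  vol[which(cset$mask$member)] <- cset$maps[, k]
  volume3d(vol, cset$mask$grid)
}

#' Write a component set to disk
#'
#' Maps go to a 4D NIfTI (one frame per component); time courses and
#' reproducibility go to TSV sidecars.
#'
#' @param cset a `component_set`.
#' @param stem output path stem; writes `<stem>.nii.gz`,
#'   `<stem>_timecourses.tsv`, `<stem>_reproducibility.tsv`.
#' @return Character vector of written paths, invisibly.
#' @export
write_component_set <- function(cset, stem) {
  stopifnot(inherits(cset, "component_set"))
  d <- cset$mask$grid$dims
  vals <- array(0, c(d, cset$tncs))
  idx <- which(cset$mask$member)
  for (k in seq_len(cset$tncs)) {
    frame <- array(0, d); frame[idx] <- cset$maps[, k]
    vals[, , , k] <- frame
  }
  p_nii <- paste0(stem, ".nii.gz")
  write_volume(series4d(vals, cset$mask$grid, 1), p_nii)
  tc <- tibble::as_tibble(cset$time_courses, .name_repair = ~ sprintf(
    "component_%02d", seq_len(cset$tncs)))
  p_tc <- paste0(stem, "_timecourses.tsv")
  readr::write_tsv(tc, p_tc)
  p_rep <- paste0(stem, "_reproducibility.tsv")
  readr::write_tsv(tibble::tibble(component = seq_len(cset$tncs),
                                  reproducibility = cset$reproducibility,
                                  converged_runs = sum(cset$converged)),
                   p_rep)
  invisible(c(p_nii, p_tc, p_rep))
}
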