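#' Specification of a synthetic lesion-bearing BOLD phantom
#'
#' The phantom emulates the empirical premise behind BOLD-based tumor
#' detection: voxels inside a contiguous lesion share a coherent
#' low-frequency time course that is distinct from the signals outside it.
#' A head ellipsoid carries a constant baseline; the tumor ellipsoid adds a
#' band-limited coherent signal; a few network-like ellipsoids add their own
#' coherent signals (so ICA has plausible non-tumor structure to separate);
#' per-voxel linear drift and white Gaussian noise complete the series.
#'
#' @param grid a [voxel_grid()].
#' @param n_frames number of time frames (>= 2).
#' @param tr_seconds repetition time in seconds.
#' @param head_semi_axes ellipsoid semi-axes of the head, in voxels.
#' @param head_center head ellipsoid centre (1-based voxel coordinates);
#'   defaults to the grid centre.
#' @param tumor_center,tumor_semi_axes tumor ellipsoid centre and semi-axes
#'   in voxels; the tumor must lie strictly inside the head.
#' @param tumor_amplitude amplitude (signal units) of the unit-variance
#'   coherent tumor time course. With `noise_sd = 1` this is the tumor
#'   contrast-to-noise ratio.
#' @param tumor_band_hz length-2 frequency band (Hz) of the tumor course.
#' @param tumor_core_frac fraction of the ellipsoidal radius belonging to
#'   the lesion core; the surrounding rim carries a partially distinct
#'   course. Real lesions are heterogeneous (core vs infiltrative rim), and
#'   this is what makes the model order genuinely matter: too few
#'   components fuse the lesion with confounds, too many split core from
#'   rim.
#' @param tumor_rim_cor correlation between the rim and core time courses
#'   (1 collapses the lesion to a single homogeneous source).
#' @param vessel_amplitude amplitude of a small peritumoral "vessel" source
#'   placed just outside the lesion that shares the lesion's mixed time
#'   course, the way draining/feeding vessels share tumor vasomotion. It
#'   guarantees that genuinely tumor-related components carry some
#'   false-alarm load outside the template, as they do in real data.
#'   0 disables it.
#' @param n_networks number of network-like confound ellipsoids.
#' @param network_amplitude amplitude of each network time course.
#' @param drift_amplitude standard deviation of per-voxel linear drift
#'   (signal units over the whole scan).
#' @param noise_sd standard deviation of additive white noise (> 0).
#' @param baseline constant head intensity (signal units).
#' @param rng_seed integer seed; identical spec and seed reproduce the
#'   phantom bit for bit.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid,
                         n_frames = 150L,
                         tr_seconds = 2,
                         head_semi_axes = (grid$dims - 4) / 2,
                         head_center = (grid$dims + 1) / 2,
                         tumor_center = head_center + c(round(head_semi_axes[1] * 0.4), 0, 0),
                         tumor_semi_axes = pmax(2, round(head_semi_axes * 0.3)),
                         tumor_amplitude = 3,
                         tumor_band_hz = c(0.01, 0.03),
                         tumor_core_frac = 0.6,
                         tumor_rim_cor = 0.9,
                         vessel_amplitude = 0,
                         n_networks = 3L,
                         network_amplitude = 2,
                         drift_amplitude = 1,
                         noise_sd = 1,
                         baseline = 100,
                         rng_seed = 42L) {
  stopifnot(inherits(grid, "voxel_grid"))
  n_frames <- as.integer(n_frames)
  if (n_frames < 2L) stop("`n_frames` must be >= 2", call. = FALSE)
  if (!is.finite(noise_sd) || noise_sd <= 0)
    stop("`noise_sd` must be > 0", call. = FALSE)
  if (length(tumor_band_hz) != 2L || tumor_band_hz[1] <= 0 ||
      tumor_band_hz[2] <= tumor_band_hz[1])
    stop("`tumor_band_hz` must be an increasing positive interval",
         call. = FALSE)
  spec <- structure(
    list(grid = grid, n_frames = n_frames, tr_seconds = tr_seconds,
         head_semi_axes = head_semi_axes, head_center = head_center,
         tumor_center = tumor_center, tumor_semi_axes = tumor_semi_axes,
         tumor_amplitude = tumor_amplitude, tumor_band_hz = tumor_band_hz,
         tumor_core_frac = tumor_core_frac, tumor_rim_cor = tumor_rim_cor,
         vessel_amplitude = vessel_amplitude,
         n_networks = as.integer(n_networks),
         network_amplitude = network_amplitude,
         drift_amplitude = drift_amplitude, noise_sd = noise_sd,
         baseline = baseline, rng_seed = as.integer(rng_seed)),
    class = "phantom_spec")
  tum <- ellipsoid_member(grid$dims, spec$tumor_center, spec$tumor_semi_axes)
  head <- ellipsoid_member(grid$dims, spec$head_center, spec$head_semi_axes)
  if (!any(tum)) stop("tumor ellipsoid contains no voxels", call. = FALSE)
  if (any(tum & !head))
    stop("tumor ellipsoid must lie strictly inside the head ellipsoid",
         call. = FALSE)
  spec
}

# squared ellipsoidal radius sum(((x - c) / a)^2) per voxel (1-based coords)
ellipsoid_radius2 <- function(dims, center, semi_axes) {
  x <- ((seq_len(dims[1]) - center[1]) / semi_axes[1])^2
  y <- ((seq_len(dims[2]) - center[2]) / semi_axes[2])^2
  z <- ((seq_len(dims[3]) - center[3]) / semi_axes[3])^2
  array(outer(outer(x, y, "+"), z, "+"), dims)
}

# logical array of voxels with sum(((x - c) / a)^2) <= 1 (1-based coords)
ellipsoid_member <- function(dims, center, semi_axes) {
  ellipsoid_radius2(dims, center, semi_axes) <= 1
}

# zero-mean unit-variance sum of 3 random sinusoids inside a frequency band
band_limited_course <- function(n_frames, tr, band_hz) {
  t <- (seq_len(n_frames) - 1) * tr
  f <- stats::runif(3, band_hz[1], band_hz[2])
  ph <- stats::runif(3, 0, 2 * pi)
  s <- rowSums(vapply(1:3, function(i) sin(2 * pi * f[i] * t + ph[i]),
                      numeric(n_frames)))
  s <- s - mean(s)
  s / stats::sd(s)
}

#' Named phantom presets
#'
#' `small_fast` is sized so the full pipeline (decomposition sweep included)
#' completes in minutes on one CPU: a 24^3 grid of 3-mm voxels and 120
#' frames. `default` is a slightly larger 28^3 grid with 150 frames.
#' `hard_low_cnr` is `default` with the tumor amplitude lowered to the noise
#' floor (contrast-to-noise ratio 1).
#'
#' @param name one of `"small_fast"`, `"default"`, `"hard_low_cnr"`.
#' @return A [phantom_spec()].
#' @export
phantom_presets <- function(name) {
  known <- c("small_fast", "default", "hard_low_cnr")
  if (!is.character(name) || length(name) != 1L || !name %in% known)
    stop(sprintf("unknown phantom preset %s; available: %s",
                 deparse(substitute(name)), paste(known, collapse = ", ")),
         call. = FALSE)
  switch(name,
    small_fast = phantom_spec(
      voxel_grid(c(24L, 24L, 24L), c(3, 3, 3)),
      n_frames = 120L,
      head_semi_axes = c(10, 10, 10),
      head_center = c(12.5, 12.5, 12.5),
      tumor_center = c(16.5, 12.5, 12.5),
      tumor_semi_axes = c(4, 3, 3),
      tumor_rim_cor = 1,        # homogeneous lesion: a screening fixture
      n_networks = 3L),
    default = phantom_spec(
      voxel_grid(c(28L, 28L, 28L), c(3, 3, 3)),
      n_frames = 150L,
      head_semi_axes = c(12, 12, 11),
      head_center = c(14.5, 14.5, 14.5),
      tumor_center = c(19.5, 14.5, 14.5),
      tumor_semi_axes = c(4, 3.5, 3),
      n_networks = 12L,
      vessel_amplitude = 3),
    hard_low_cnr = {
      s <- phantom_presets("default")
      s$tumor_amplitude <- 1
      s
    })
}

#' Generate a synthetic lesion-bearing 4D BOLD series with ground truth
#'
#' The series is
#' `baseline * head + A_tum * s_tum(t) * tumor + sum_k A_net * s_k(t) * net_k
#'  + drift + noise`, where every coherent time course is zero-mean with unit
#' variance, drift is a per-voxel linear trend, and noise is white Gaussian
#' inside the head. Identical spec and seed reproduce the output exactly.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `phantom_output` with elements `series`
#'   ([series4d()]), `truth_tumor`, `brain` and `truth_networks`
#'   ([binary_mask()] objects) and `truth_time_courses` (tibble, one column
#'   per source).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid$dims
  head <- ellipsoid_member(d, spec$head_center, spec$head_semi_axes)
  tumor <- ellipsoid_member(d, spec$tumor_center, spec$tumor_semi_axes)
  r2 <- ellipsoid_radius2(d, spec$tumor_center, spec$tumor_semi_axes)
  core <- tumor & (r2 <= spec$tumor_core_frac^2)
  rim <- tumor & !core
  vessel <- place_vessel(spec, head, tumor)
  withr::with_seed(spec$rng_seed, {
    nets <- place_networks(spec, head, tumor | vessel)
    s_core <- band_limited_course(spec$n_frames, spec$tr_seconds,
                                  spec$tumor_band_hz)
    rho <- spec$tumor_rim_cor
    s_rim <- rho * s_core + sqrt(1 - rho^2) *
      band_limited_course(spec$n_frames, spec$tr_seconds, spec$tumor_band_hz)
    s_rim <- (s_rim - mean(s_rim)) / stats::sd(s_rim)
    s_ves <- s_core + s_rim
    s_ves <- (s_ves - mean(s_ves)) / stats::sd(s_ves)
    s_net <- lapply(seq_along(nets), function(k)
      band_limited_course(spec$n_frames, spec$tr_seconds, c(0.01, 0.08)))
    tt <- (seq_len(spec$n_frames) - 1) / max(1L, spec$n_frames - 1L) - 0.5
    slopes <- array(stats::rnorm(prod(d), sd = spec$drift_amplitude), d)
    vals <- array(0, c(d, spec$n_frames))
    noise <- array(stats::rnorm(prod(d) * spec$n_frames,
                                sd = spec$noise_sd), c(d, spec$n_frames))
    for (t in seq_len(spec$n_frames)) {
      frame <- spec$baseline * head +
        spec$tumor_amplitude * (s_core[t] * core + s_rim[t] * rim) +
        spec$vessel_amplitude * s_ves[t] * vessel
      for (k in seq_along(nets))
        frame <- frame + spec$network_amplitude * s_net[[k]][t] * nets[[k]]
      frame <- frame + head * slopes * tt[t]
      vals[, , , t] <- frame + head * noise[, , , t]
    }
    courses <- tibble::as_tibble(
      c(list(tumor_core = s_core, tumor_rim = s_rim, vessel = s_ves),
        stats::setNames(s_net, paste0("network_", seq_along(s_net)))))
    structure(
      list(series = series4d(vals, spec$grid, spec$tr_seconds),
           truth_tumor = binary_mask(tumor, spec$grid),
           truth_vessel = binary_mask(vessel, spec$grid),
           truth_networks = lapply(nets, binary_mask, grid = spec$grid),
           truth_time_courses = courses,
           brain = binary_mask(head, spec$grid),
           spec = spec),
      class = "phantom_output")
  })
}

# elongated "vessel" ellipsoid just outside the lesion, inside the head
place_vessel <- function(spec, head, tumor) {
  d <- spec$grid$dims
  if (spec$vessel_amplitude == 0) return(array(FALSE, d))
  hc <- spec$head_center
  # push it outward from the lesion centre, away from the head centre when
  # possible, hugging the lesion boundary
  dir <- spec$tumor_center - hc
  if (all(abs(dir) < 1e-9)) dir <- c(1, 0, 0)
  dir <- dir / sqrt(sum(dir^2))
  ctr <- spec$tumor_center + dir * (max(spec$tumor_semi_axes) + 2.5)
  m <- ellipsoid_member(d, ctr, c(3, 1.5, 1.5)) & head &
    !dilate_member(tumor, 1)
  m
}

# non-overlapping network ellipsoids inside the head, disjoint from the
# lesion and vessel; centres follow a golden-angle spiral on a mid-radius
# shell with a small seed-driven jitter
place_networks <- function(spec, head, exclude) {
  if (spec$n_networks < 1L) return(list())
  d <- spec$grid$dims
  hc <- spec$head_center; ha <- spec$head_semi_axes
  n <- spec$n_networks
  i <- seq_len(n)
  z <- 1 - (2 * i - 1) / n          # uniform on [-1, 1]
  theta <- pi * (3 - sqrt(5)) * i   # golden angle
  dirs <- cbind(sqrt(1 - z^2) * cos(theta), sqrt(1 - z^2) * sin(theta), z)
  occupied <- exclude
  nets <- list()
  for (k in i) {
    ctr <- hc + dirs[k, ] * ha * stats::runif(1, 0.5, 0.65) +
      stats::runif(3, -0.5, 0.5)
    ax <- pmax(1.5, ha * stats::runif(1, 0.16, 0.22))
    m <- ellipsoid_member(d, ctr, ax) & head & !dilate_member(occupied, 1)
    occupied <- occupied | m
    nets[[k]] <- m
  }
  nets
}

#' Write a phantom to disk
#'
#' Writes the series, truth masks and brain mask as NIfTI-1, the source time
#' courses as TSV, and the spec as a JSON sidecar.
#'
#' @param phantom a `phantom_output` from [generate_phantom()].
#' @param dir output directory (created if needed).
#' @return A character vector of the written paths, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "phantom_output"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    bold = file.path(dir, "bold.nii.gz"),
    truth_tumor = file.path(dir, "truth_tumor.nii.gz"),
    brain = file.path(dir, "brain.nii.gz"))
  write_volume(phantom$series, paths[["bold"]])
  write_volume(phantom$truth_tumor, paths[["truth_tumor"]])
  write_volume(phantom$brain, paths[["brain"]])
  for (k in seq_along(phantom$truth_networks)) {
    p <- file.path(dir, sprintf("truth_network_%d.nii.gz", k))
    write_volume(phantom$truth_networks[[k]], p)
    paths[[sprintf("truth_network_%d", k)]] <- p
  }
  tc <- file.path(dir, "truth_time_courses.tsv")
  readr::write_tsv(phantom$truth_time_courses, tc)
  paths[["time_courses"]] <- tc
  sp <- file.path(dir, "phantom_spec.json")
  spec <- phantom$spec
  spec$grid <- list(dims = spec$grid$dims,
                    voxel_size_mm = spec$grid$voxel_size_mm,
                    affine = spec$grid$affine)
  jsonlite::write_json(unclass(spec), sp, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  paths[["spec"]] <- sp
  invisible(paths)
}
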