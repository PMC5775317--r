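# Shared fixtures. Expensive ones (phantom decompositions) are computed once
# per session and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

tiny_grid <- function(n = 10L, vs = 2) voxel_grid(rep(n, 3), rep(vs, 3))

# two-level ellipsoid "head" image for masking tests
ellipsoid_image <- function(n = 16L, semi = c(6, 5, 5), value = 100) {
  g <- tiny_grid(n, 2)
  ctr <- (n + 1) / 2
  x <- ((seq_len(n) - ctr) / semi[1])^2
  y <- ((seq_len(n) - ctr) / semi[2])^2
  z <- ((seq_len(n) - ctr) / semi[3])^2
  vals <- array(outer(outer(x, y, "+"), z, "+") <= 1, rep(n, 3)) * value
  volume3d(vals, g)
}

small_phantom <- function(seed = 42L) {
  cached(paste0("small_phantom_", seed), {
    s <- phantom_presets("small_fast")
    s$rng_seed <- as.integer(seed)
    generate_phantom(s)
  })
}

# the default phantom, preprocessed and decomposed at TNCs {10,20,30,40}
# with 5 randomised runs each -- shared by the robustness, template-tolerance
# and seed-comparison acceptance checks
default_sweep_fixture <- function() {
  cached("default_sweep", {
    ph <- generate_phantom(phantom_presets("default"))
    prep <- preprocess(ph$series)
    csets <- sweep_components(prep$series, prep$mask,
                              decomposition_config(10L, n_runs = 5L,
                                                   base_rng_seed = 1L),
                              tncs_grid = c(10L, 20L, 30L, 40L))
    list(phantom = ph, prep = prep, csets = csets)
  })
}

# synthetic anatomical image for the default phantom: head at 100, tumor at
# 130, mild noise -- what a T1 with visible lesion contrast looks like to the
# region grower
phantom_anat <- function(ph, seed = 7L) {
  withr::with_seed(seed, {
    vals <- 100 * ph$brain$member + 30 * ph$truth_tumor$member +
      array(rnorm(prod(ph$brain$grid$dims), sd = 2), ph$brain$grid$dims)
    volume3d(vals, ph$brain$grid)
  })
}

# independent standard-normal quantile: invert pnorm by bisection, never
# touching qnorm
quantile_oracle <- function(p) {
  vapply(p, function(pp) {
    stats::uniroot(function(z) stats::pnorm(z) - pp,
                   lower = -10, upper = 10, tol = 1e-12)$root
  }, numeric(1))
}

# brute-force confusion counter: explicit per-voxel conditionals
confusion_oracle <- function(bin, template, brain) {
  hit <- 0L; miss <- 0L; fa <- 0L; cr <- 0L
  b <- as.vector(bin); tm <- as.vector(template); br <- as.vector(brain)
  for (i in seq_along(b)) {
    if (!br[i]) next
    if (tm[i]) {
      if (b[i]) hit <- hit + 1L else miss <- miss + 1L
    } else {
      if (b[i]) fa <- fa + 1L else cr <- cr + 1L
    }
  }
  list(hit = hit, miss = miss, fa = fa, cr = cr)
}

# brute-force region-growth oracle: repeat-until-stable set expansion with
# explicit rule checks (no closing)
grow_oracle <- function(anat, seed_vox1, radius_mm, diff_origin, diff_edge) {
  v <- anat$values; dims <- dim(v); grid <- anat$grid
  i_seed <- v[seed_vox1[1], seed_vox1[2], seed_vox1[3]]
  seed_mm <- vox0_to_mm(grid, seed_vox1 - 1L)
  admitted <- array(FALSE, dims)
  admitted[seed_vox1[1], seed_vox1[2], seed_vox1[3]] <- TRUE
  repeat {
    changed <- FALSE
    for (x in seq_len(dims[1])) for (y in seq_len(dims[2]))
      for (z in seq_len(dims[3])) {
        if (admitted[x, y, z]) next
        mm <- vox0_to_mm(grid, c(x, y, z) - 1L)
        if (sqrt(sum((mm - seed_mm)^2)) > radius_mm + 1e-9) next
        if (abs(v[x, y, z] - i_seed) > diff_origin + 1e-12) next
        ok <- FALSE
        for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
          if (dx == 0 && dy == 0 && dz == 0) next
          nx <- x + dx; ny <- y + dy; nz <- z + dz
          if (nx < 1 || nx > dims[1] || ny < 1 || ny > dims[2] ||
              nz < 1 || nz > dims[3]) next
          if (admitted[nx, ny, nz] &&
              abs(v[x, y, z] - v[nx, ny, nz]) <= diff_edge + 1e-12)
            ok <- TRUE
        }
        if (ok) { admitted[x, y, z] <- TRUE; changed <- TRUE }
      }
    if (!changed) break
  }
  admitted
}

# sparse super-Gaussian spatial sources mixed without noise
make_mixture <- function(n_voxels = 2000L, n_sources = 3L, n_frames = 20L,
                         seed = 1L) {
  withr::with_seed(seed, {
    S <- matrix(0, n_voxels, n_sources)
    blocks <- split(seq_len(n_voxels),
                    rep(seq_len(n_sources + 1), length.out = n_voxels))
    for (j in seq_len(n_sources))
      S[sample(blocks[[j]], length(blocks[[j]]) %/% 2), j] <-
        rexp(length(blocks[[j]]) %/% 2) + 1
    A <- matrix(rnorm(n_frames * n_sources), n_frames, n_sources)
    list(S = S, A = A, X = S %*% t(A))
  })
}
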