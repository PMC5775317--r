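test_that("voxel_grid validates its invariants", {
  expect_error(voxel_grid(c(0, 10, 10), c(2, 2, 2)), ">= 1")
  expect_error(voxel_grid(c(10, 10, 10), c(2, -1, 2)), "positive")
  expect_error(voxel_grid(c(10, 10, 10), c(2, 2, 2),
                          affine = matrix(0, 4, 4)), "invertible")
  g <- voxel_grid(c(10, 10, 10), c(2, 2, 2))
  expect_equal(g$affine[1, 1], 2)
})

test_that("voxel/mm conversion round-trips through a non-trivial affine", {
  aff <- diag(c(2, 2.5, 3, 1))
  aff[1:3, 4] <- c(-20, -25, -30)
  aff[1, 2] <- 0.3
  g <- voxel_grid(c(12, 12, 12), c(2, 2.5, 3), aff)
  p <- c(3, 7, 5)
  expect_equal(mm_to_vox0(g, vox0_to_mm(g, p)), p, tolerance = 1e-12)
  expect_equal(vox0_to_mm(g, c(0, 0, 0)), c(-20, -25, -30))
})

test_that("NIfTI round trip preserves values, affine, frames and TR", {
  dir <- withr::local_tempdir()
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- c(-9, -9, -9)
  g <- voxel_grid(c(10, 10, 10), c(2, 2, 2), aff)
  vol <- volume3d(array(rnorm(1000), c(10, 10, 10)), g)
  p <- file.path(dir, "vol.nii.gz")
  write_volume(vol, p)
  back <- read_volume(p)
  expect_s3_class(back, "volume3d")
  expect_equal(back$values, vol$values, tolerance = 0)
  expect_equal(back$grid$affine, g$affine, tolerance = 1e-5)
  expect_equal(back$grid$voxel_size_mm, c(2, 2, 2), tolerance = 1e-6)

  ser <- series4d(array(rnorm(10 * 10 * 10 * 7), c(10, 10, 10, 7)), g,
                  tr_seconds = 2.5)
  ps <- file.path(dir, "ser.nii.gz")
  write_volume(ser, ps)
  back4 <- read_volume(ps)
  expect_s3_class(back4, "series4d")
  expect_identical(back4$n_frames, 7L)
  expect_equal(back4$tr_seconds, 2.5)
  expect_equal(back4$values, ser$values, tolerance = 0)
  expect_equal(back4$grid$affine, g$affine, tolerance = 1e-5)
  expect_equal(back4$grid$voxel_size_mm, c(2, 2, 2), tolerance = 1e-6)
})

test_that("masks are written as 0/1 volumes and survive the round trip", {
  dir <- withr::local_tempdir()
  g <- tiny_grid(8)
  m <- array(FALSE, c(8, 8, 8)); m[2:4, 2:4, 2:4] <- TRUE
  mask <- binary_mask(m, g)
  p <- file.path(dir, "mask.nii.gz")
  write_volume(mask, p)
  back <- read_volume(p)
  expect_true(all(back$values %in% c(0, 1)))
  expect_equal(back$values == 1, m)
})

test_that("unreadable inputs and unwritable outputs raise clear errors", {
  expect_error(read_volume("/nonexistent/file.nii"), "does not exist")
  junk <- withr::local_tempfile(fileext = ".nii")
  writeLines("this is not a nifti", junk)
  expect_error(suppressWarnings(read_volume(junk)), "cannot read")
  g <- tiny_grid(4)
  vol <- volume3d(array(0, c(4, 4, 4)), g)
  expect_error(suppressWarnings(write_volume(vol, "/nonexistent/dir/out.nii")),
               "cannot write")
})

test_that("brain mask recovers a two-level ellipsoid and drops islands", {
  img <- ellipsoid_image()
  mask <- compute_brain_mask(img, frac = 0.2)
  expect_equal(mask$member, img$values > 0)

  # isolated bright voxel: removed by the largest-component rule
  v2 <- img$values; v2[1, 1, 1] <- 500
  mask2 <- compute_brain_mask(volume3d(v2, img$grid), frac = 0.2)
  expect_false(mask2$member[1, 1, 1])
  expect_equal(mask2$member, img$values > 0)

  expect_error(compute_brain_mask(volume3d(array(0, c(16, 16, 16)),
                                           img$grid)), "degenerate")
})

test_that("brain masking is idempotent on the masked mean image", {
  img <- ellipsoid_image()
  m1 <- compute_brain_mask(img, frac = 0.2)
  masked <- volume3d(img$values * m1$member, img$grid)
  m2 <- compute_brain_mask(masked, frac = 0.2)
  expect_equal(m1$member, m2$member)
})

test_that("FWHM converts to the closed-form sigma", {
  # 6 mm FWHM on 3 mm voxels: sigma = 6 / (2 sqrt(2 ln 2)) / 3 voxels
  expect_equal(fwhm_to_sigma(6) / 3, 0.8493218, tolerance = 1e-6)
})

test_that("smoothing matches a direct dense-convolution oracle", {
  n <- 9
  g <- voxel_grid(rep(n, 3), c(3, 3, 3))
  set.seed(5)
  frame <- array(rnorm(n^3), rep(n, 3))
  ser <- series4d(array(rep(frame, 2), c(n, n, n, 2)), g, 2)
  sm <- smooth_gaussian(ser, fwhm_mm = 6)

  sigma <- fwhm_to_sigma(6) / 3
  r <- ceiling(4 * sigma)
  k1 <- exp(-((-r:r)^2) / (2 * sigma^2)); k1 <- k1 / sum(k1)
  oracle <- array(0, rep(n, 3))
  for (x in 1:n) for (y in 1:n) for (z in 1:n) {
    acc <- 0; w <- 0
    for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
      i <- x + dx; j <- y + dy; k <- z + dz
      if (i < 1 || i > n || j < 1 || j > n || k < 1 || k > n) next
      kw <- k1[dx + r + 1] * k1[dy + r + 1] * k1[dz + r + 1]
      acc <- acc + kw * frame[i, j, k]
      w <- w + kw
    }
    oracle[x, y, z] <- acc / w
  }
  expect_equal(sm$values[, , , 1], oracle, tolerance = 1e-10)
})

test_that("smoothing preserves constants, unit impulses and linearity", {
  n <- 15
  g <- voxel_grid(rep(n, 3), c(3, 3, 3))
  const <- series4d(array(7, c(n, n, n, 2)), g, 2)
  expect_equal(smooth_gaussian(const, 6)$values, const$values,
               tolerance = 1e-12)

  imp <- array(0, c(n, n, n, 2)); imp[8, 8, 8, ] <- 1
  sm <- smooth_gaussian(series4d(imp, g, 2), 6)
  expect_equal(sum(sm$values[, , , 1]), 1, tolerance = 1e-6)

  set.seed(1)
  a <- array(rnorm(n^3 * 2), c(n, n, n, 2))
  b <- array(rnorm(n^3 * 2), c(n, n, n, 2))
  lhs <- smooth_gaussian(series4d(2 * a + 3 * b, g, 2), 6)$values
  rhs <- 2 * smooth_gaussian(series4d(a, g, 2), 6)$values +
    3 * smooth_gaussian(series4d(b, g, 2), 6)$values
  expect_equal(lhs, rhs, tolerance = 1e-8)

  expect_warning(smooth_gaussian(const, 0), "unchanged")
})
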