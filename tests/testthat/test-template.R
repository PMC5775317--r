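sphere_image <- function(n = 15L, radius = 5, value = 100) {
  g <- voxel_grid(rep(n, 3L), c(1, 1, 1))
  ctr <- (n + 1) / 2
  d2 <- outer(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+"),
              (seq_len(n) - ctr)^2, "+")
  volume3d(array((d2 <= radius^2) * value, rep(n, 3L)), g)
}

test_that("growth on a two-level sphere recovers exactly the sphere", {
  img <- sphere_image()
  ctr0 <- c(7, 7, 7)  # 0-based centre of a 15^3 grid
  tpl <- grow_voi(img, growth_params(ctr0, "voxel", radius_mm = 10,
                                     diff_from_origin = 10,
                                     diff_from_edge = 10))
  expect_equal(tpl$mask$member, img$values > 0)
  # with closing disabled too
  tpl0 <- grow_voi(img, growth_params(ctr0, "voxel", radius_mm = 10,
                                      diff_from_origin = 10,
                                      diff_from_edge = 10,
                                      closing_radius_vox = 0))
  expect_equal(tpl0$mask$member, img$values > 0)
})

test_that("zero tolerances confine growth to the seed voxel", {
  img <- sphere_image()
  v <- img$values; v[8, 8, 8] <- 250  # unique seed intensity
  img2 <- volume3d(v, img$grid)
  tpl <- grow_voi(img2, growth_params(c(7, 7, 7), "voxel", radius_mm = 10,
                                      diff_from_origin = 0,
                                      diff_from_edge = 0))
  expect_identical(n_voxels(tpl$mask), 1L)
  expect_true(tpl$mask$member[8, 8, 8])
})

test_that("growth matches the brute-force fixpoint oracle", {
  n <- 11L
  g <- voxel_grid(rep(n, 3L), c(2, 2, 2))
  # gradient ramp: origin band is limiting, edge steps always pass
  ramp <- volume3d(array(rep(seq_len(n) * 10, times = n * n), rep(n, 3L)), g)
  seed1 <- c(6L, 6L, 6L)
  p <- growth_params(seed1 - 1L, "voxel", radius_mm = 12,
                     diff_from_origin = 25, diff_from_edge = 1000,
                     closing_radius_vox = 0)
  got <- grow_voi(ramp, p)$mask$member
  want <- grow_oracle(ramp, seed1, 12, 25, 1000)
  expect_identical(got, want)

  # textured image where the edge rule matters
  set.seed(11)
  tex <- volume3d(array(sample(c(0, 4, 8, 12, 100), n^3, replace = TRUE,
                               prob = c(.2, .25, .25, .2, .1)), rep(n, 3L)),
                  g)
  v <- tex$values; v[6, 6, 6] <- 6; tex <- volume3d(v, g)
  p2 <- growth_params(c(5, 5, 5), "voxel", radius_mm = 9,
                      diff_from_origin = 8, diff_from_edge = 5,
                      closing_radius_vox = 0)
  got2 <- grow_voi(tex, p2)$mask$member
  want2 <- grow_oracle(tex, c(6L, 6L, 6L), 9, 8, 5)
  expect_identical(got2, want2)
})

test_that("growth is invariant to traversal order (axis-mirrored image)", {
  set.seed(3)
  n <- 9L
  g <- voxel_grid(rep(n, 3L), c(1, 1, 1))
  vals <- array(round(rnorm(n^3, 50, 10)), rep(n, 3L))
  img <- volume3d(vals, g)
  p <- function(seed0) growth_params(seed0, "voxel", radius_mm = 6,
                                     diff_from_origin = 12,
                                     diff_from_edge = 6,
                                     closing_radius_vox = 0)
  direct <- grow_voi(img, p(c(4, 4, 4)))$mask$member
  mirrored <- grow_voi(volume3d(vals[n:1, , ], g),
                       p(c(n - 5, 4, 4)))$mask$member
  expect_identical(direct, mirrored[n:1, , ])
})

test_that("enlarging the origin band never shrinks the mask", {
  set.seed(8)
  n <- 9L
  g <- voxel_grid(rep(n, 3L), c(1, 1, 1))
  img <- volume3d(array(round(rnorm(n^3, 50, 15)), rep(n, 3L)), g)
  sizes <- vapply(c(5, 10, 20, 40), function(d) {
    n_voxels(grow_voi(img, growth_params(c(4, 4, 4), "voxel",
                                         radius_mm = 8,
                                         diff_from_origin = d,
                                         diff_from_edge = 1000,
                                         closing_radius_vox = 0))$mask)
  }, integer(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("template respects the radius bound and stays nonempty", {
  img <- sphere_image()
  tpl <- grow_voi(img, growth_params(c(7, 7, 7), "voxel", radius_mm = 3,
                                     diff_from_origin = 10,
                                     diff_from_edge = 10))
  expect_gte(n_voxels(tpl$mask), 1L)
  st <- template_stats(tpl)
  mm <- vox0_to_mm(img$grid, c(7, 7, 7))
  idx <- which(tpl$mask$member)
  co <- vox0_to_mm(img$grid, arrayInd(idx, img$grid$dims) - 1L)
  dists <- sqrt(rowSums((co - matrix(mm, nrow(co), 3, byrow = TRUE))^2))
  expect_true(all(dists <= 3 + 1e-9))
  expect_error(grow_voi(img, growth_params(c(50, 0, 0), "voxel", 5, 1, 1)),
               "outside")
})

test_that("template_stats reports counts, volume and centroid", {
  g <- voxel_grid(c(10L, 10L, 10L), c(2, 2, 2))
  m <- array(FALSE, c(10, 10, 10)); m[3, 4, 5] <- TRUE
  st1 <- template_stats(binary_mask(m, g))
  expect_identical(st1$n_voxels, 1L)
  expect_equal(st1$volume_mm3, 8)
  expect_equal(c(st1$centroid_x, st1$centroid_y, st1$centroid_z),
               vox0_to_mm(g, c(2, 3, 4)))

  img <- sphere_image()
  tpl <- grow_voi(img, growth_params(c(7, 7, 7), "voxel", 10, 10, 10))
  st <- template_stats(tpl)
  expect_equal(st$volume_mm3, st$n_voxels * 1)
  ctr_mm <- vox0_to_mm(img$grid, c(7, 7, 7))
  expect_true(all(abs(c(st$centroid_x, st$centroid_y, st$centroid_z) -
                        ctr_mm) < 0.5))
})
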