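# helper: a z-map volume with chosen suprathreshold structure
zmap_volume <- function(assign_fun, n = 12L) {
  g <- voxel_grid(rep(n, 3L), c(3, 3, 3))
  v <- array(0, rep(n, 3L))
  v <- assign_fun(v)
  volume3d(v, g)
}

test_that("binarization keeps the positive tail and filters small clusters", {
  vol <- zmap_volume(function(v) {
    v[2:4, 2:5, 2:4] <- 2            # 36-voxel blob, 26-connected
    v[10, 10, 10] <- 3               # isolated voxels
    v[1, 10, 5] <- 3
    v[10, 1, 2] <- 3
    v[5, 10, 10] <- 3
    v[10, 5, 1] <- 3
    v[7, 7, 7] <- -5                 # negative tail never survives
    v
  })
  bin <- binarize_component(vol, dici_config())
  expect_identical(n_voxels(bin), 36L)
  expect_true(all(bin$member[2:4, 2:5, 2:4]))

  # a cluster of exactly the minimum size is removed (strictly greater-than)
  vol20 <- zmap_volume(function(v) { v[2:6, 2:5, 2] <- 2; v })
  expect_identical(n_voxels(binarize_component(vol20, dici_config())), 0L)
  vol21 <- zmap_volume(function(v) { v[2:6, 2:5, 2] <- 2; v[2, 2, 3] <- 2; v })
  expect_identical(n_voxels(binarize_component(vol21, dici_config())), 21L)

  empty <- zmap_volume(identity)
  expect_identical(n_voxels(binarize_component(empty, dici_config())), 0L)
})

test_that("the worked example scores DICI ~ 3.13 via the quantile oracle", {
  g <- tiny_grid(10)
  brain <- binary_mask(array(TRUE, c(10, 10, 10)), g)
  tmpl <- array(FALSE, c(10, 10, 10)); tmpl[1:100] <- TRUE
  bin <- array(FALSE, c(10, 10, 10))
  bin[1:80] <- TRUE      # 80 hits
  bin[101:110] <- TRUE   # 10 false alarms among 900 non-template voxels
  sc <- score_component(binary_mask(bin, g), binary_mask(tmpl, g), brain)
  expect_equal(sc$hr, 0.8)
  expect_equal(sc$far, 10 / 900)
  want <- quantile_oracle(0.8) - quantile_oracle(10 / 900)
  expect_equal(sc$dici, want, tolerance = 1e-9)
  expect_equal(sc$dici, 3.13, tolerance = 0.005)
})

test_that("chance-level matches score zero and empty maps are invalid", {
  g <- tiny_grid(10)
  brain <- binary_mask(array(TRUE, c(10, 10, 10)), g)
  tmpl <- array(FALSE, c(10, 10, 10)); tmpl[1:500] <- TRUE
  bin <- array(FALSE, c(10, 10, 10))
  bin[1:250] <- TRUE; bin[501:750] <- TRUE  # HR = FAR = 0.5
  sc <- score_component(binary_mask(bin, g), binary_mask(tmpl, g), brain)
  expect_equal(sc$dici, 0, tolerance = 1e-12)

  sc0 <- score_component(binary_mask(array(FALSE, c(10, 10, 10)), g),
                         binary_mask(tmpl, g), brain)
  expect_false(sc0$valid)
  expect_true(is.na(sc0$dici))

  expect_error(score_component(binary_mask(bin, g),
                               binary_mask(array(TRUE, c(10, 10, 10)), g),
                               brain), "degenerate template")
  expect_error(score_component(binary_mask(bin, g),
                               binary_mask(array(FALSE, c(10, 10, 10)), g),
                               brain), "degenerate template")
})

test_that("scoring matches brute-force counts and the quantile oracle", {
  # a reduced version of the randomized oracle sweep (the full 1000-pair
  # comparison runs in the acceptance suite)
  g <- tiny_grid(12)
  withr::with_seed(31, {
    for (i in 1:25) {
      brain_arr <- array(runif(12^3) < 0.9, rep(12, 3L))
      tmpl_arr <- brain_arr & array(runif(12^3) < 0.1, rep(12, 3L))
      bin_arr <- array(runif(12^3) < runif(1, 0.02, 0.3), rep(12, 3L))
      if (!any(tmpl_arr) || all(tmpl_arr == brain_arr)) next
      oc <- confusion_oracle(bin_arr, tmpl_arr, brain_arr)
      sc <- score_component(binary_mask(bin_arr, g),
                            binary_mask(tmpl_arr, g),
                            binary_mask(brain_arr, g))
      if (!sc$valid) { expect_identical(oc$hit + oc$fa, 0L); next }
      n_t <- oc$hit + oc$miss; n_nt <- oc$fa + oc$cr
      hr <- if (oc$hit == 0) 1 / (2 * n_t) else
        if (oc$hit == n_t) 1 - 1 / (2 * n_t) else oc$hit / n_t
      far <- if (oc$fa == 0) 1 / (2 * n_nt) else
        if (oc$fa == n_nt) 1 - 1 / (2 * n_nt) else oc$fa / n_nt
      expect_equal(sc$hr, hr, tolerance = 0)
      expect_equal(sc$far, far, tolerance = 0)
      expect_equal(sc$dici, quantile_oracle(hr) - quantile_oracle(far),
                   tolerance = 1e-9)
    }
  })
})

test_that("DICI is monotone: increasing in HR, decreasing in FAR", {
  g <- tiny_grid(10)
  brain <- binary_mask(array(TRUE, c(10, 10, 10)), g)
  tmpl <- array(FALSE, c(10, 10, 10)); tmpl[1:100] <- TRUE
  tm <- binary_mask(tmpl, g)
  dici_at <- function(hits, fas) {
    b <- array(FALSE, c(10, 10, 10))
    if (hits > 0) b[seq_len(hits)] <- TRUE
    if (fas > 0) b[100 + seq_len(fas)] <- TRUE
    score_component(binary_mask(b, g), tm, brain)$dici
  }
  d_hr <- vapply(c(10, 30, 50, 70, 90), dici_at, numeric(1), fas = 20)
  expect_true(all(diff(d_hr) > 0))
  d_far <- vapply(c(10, 50, 200, 500, 800), dici_at, numeric(1), hits = 50)
  expect_true(all(diff(d_far) < 0))
})

# a component_set (labelled with a chosen model order) whose k-th map has a
# chosen suprathreshold blob
fake_cset <- function(blobs, tncs, mask) {
  nv <- mask$n_voxels
  n_comp <- length(blobs)
  maps <- matrix(0, nv, n_comp)
  for (k in seq_along(blobs)) maps[blobs[[k]], k] <- 5
  maps <- scale(maps)
  structure(list(tncs = as.integer(tncs), maps = maps,
                 time_courses = matrix(0, 10, n_comp),
                 reproducibility = rep(1, n_comp),
                 converged = TRUE, mask = mask),
            class = "component_set")
}

test_that("selection takes the largest candidate DICI, ties to lower TNCs", {
  g <- tiny_grid(12)
  brain <- binary_mask(array(TRUE, rep(12, 3L)), g)
  tmpl_idx <- 1:120
  tm_arr <- array(FALSE, rep(12, 3L)); tm_arr[tmpl_idx] <- TRUE
  tm <- binary_mask(tm_arr, g)
  # blobs of growing template coverage; contiguity guaranteed by taking
  # linear runs (column-major order keeps runs 26-connected on a 12^3 grid)
  cs_a <- fake_cset(list(1:60, 400:440), 10, brain)      # HR 0.5 candidate
  cs_b <- fake_cset(list(1:110, 400:440), 20, brain)     # HR ~0.92 candidate
  cs_c <- fake_cset(list(1:80, 400:440), 30, brain)      # HR ~0.67
  sel <- select_tumor_component(list("10" = cs_a, "20" = cs_b, "30" = cs_c),
                                tm, brain)
  expect_identical(sel$optimal_tncs, 20L)
  expect_identical(sel$best$component_index, 1L)

  # exact tie between TNCs 20 and 30 resolves to the lower model order
  cs_b30 <- cs_b; cs_b30$tncs <- 30L
  sel_tie <- select_tumor_component(list("20" = cs_b, "30" = cs_b30),
                                    tm, brain)
  expect_identical(sel_tie$optimal_tncs, 20L)

  # all-empty binarizations raise the dedicated condition
  cs_null <- fake_cset(list(1:5, 30:34), 10, brain)  # below cluster minimum
  expect_error(select_tumor_component(list("10" = cs_null), tm, brain),
               class = "boldica_no_tumor_component")
})

test_that("delta-DICI entries are nonnegative for ordered rank pairs", {
  g <- tiny_grid(12)
  brain <- binary_mask(array(TRUE, rep(12, 3L)), g)
  tm_arr <- array(FALSE, rep(12, 3L)); tm_arr[1:120] <- TRUE
  tm <- binary_mask(tm_arr, g)
  cs <- fake_cset(list(1:110, 1:60, 200:260, 400:450, 700:780), 10, brain)
  sel <- select_tumor_component(list("10" = cs), tm, brain)
  expect_true(all(sel$delta_dici$delta_dici >= 0))
  expect_identical(nrow(sel$delta_dici), 6L)  # choose(4, 2)
  g1 <- glance(sel)
  t4 <- dplyr::filter(tidy(sel), tncs == 10)
  expect_equal(g1$delta_dici_1st_2nd, t4$dici[1] - t4$dici[2])
})

test_that("the DICI report writes ranks 1-4 per model order deterministically", {
  dir <- withr::local_tempdir()
  g <- tiny_grid(12)
  brain <- binary_mask(array(TRUE, rep(12, 3L)), g)
  tm_arr <- array(FALSE, rep(12, 3L)); tm_arr[1:120] <- TRUE
  tm <- binary_mask(tm_arr, g)
  blobs <- list(1:110, 1:60, 200:260, 400:450, 700:780)
  csets <- list("10" = fake_cset(blobs, 10, brain),
                "20" = fake_cset(blobs[c(2, 1, 3, 4, 5)], 20, brain))
  sel <- select_tumor_component(csets, tm, brain)
  p1 <- file.path(dir, "report.tsv")
  write_dici_report(sel, p1)
  rep_tbl <- readr::read_tsv(p1, show_col_types = FALSE)
  expect_identical(nrow(rep_tbl), 8L)  # 2 TNCs x ranks 1-4
  expect_equal(sort(unique(rep_tbl$rank)), 1:4, ignore_attr = TRUE)
  js <- jsonlite::read_json(file.path(dir, "report.json"))
  r1 <- rep_tbl[rep_tbl$tncs == js$optimal_tncs, ]
  expect_equal(js$delta_dici_1st_2nd, r1$dici[1] - r1$dici[2],
               tolerance = 1e-12)

  p2 <- file.path(dir, "report2.tsv")
  write_dici_report(sel, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})
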