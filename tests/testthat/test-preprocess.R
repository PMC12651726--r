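make_ct <- function(vals, spacing = c(1, 1, 1))
  volume3d(array(vals, c(2, 2, 2)), spacing, modality = "CT")

test_that("HU clipping replaces out-of-range values and is idempotent", {
  ct <- make_ct(c(1500, -2000, 250, 0, 999, -999, 1000, -1000))
  cl <- clip_hu(ct)
  expect_equal(as.vector(cl$data),
               c(1000, -1000, 250, 0, 999, -999, 1000, -1000))
  expect_identical(clip_hu(cl)$data, cl$data)
  expect_error(clip_hu(volume3d(array(0, c(2, 2, 2)), modality = "T2")), "CT")
})

test_that("scaling factors pool CT extremes and map per-series MRI", {
  ct1 <- make_ct(seq(-500, 400, length.out = 8))
  ct2 <- make_ct(seq(-900, 800, length.out = 8))
  mri <- volume3d(array(seq(10, 210, length.out = 8), c(2, 2, 2)),
                  modality = "T2")
  sf <- fit_scaling(list(ct1, ct2, mri))
  expect_equal(sf$ct, c(-900, 800))
  n <- normalize_volume(volume3d(array(110, c(2, 2, 2)), modality = "T2"), sf)
  expect_equal(unique(as.vector(n$data)), 0.5)
  # endpoints map to 0 and 1; CT midpoint of a symmetric window to 0.5
  sym <- fit_scaling(list(make_ct(c(-1000, 1000, rep(0, 6)))))
  n2 <- normalize_volume(make_ct(c(-1000, 1000, 0, rep(250, 5))), sym)
  expect_equal(n2$data[1, 1, 1], 0)
  expect_equal(n2$data[2, 1, 1], 1)
  expect_equal(n2$data[1, 2, 1], 0.5)
  expect_error(fit_scaling(list(make_ct(rep(5, 8)))), "constant")
  expect_error(normalize_volume(mri, sf, series = "T9"), "T9")
})

test_that("renormalizing already-normalized data is the identity", {
  v <- volume3d(array(runif(64), c(4, 4, 4)), modality = "T1CE")
  n1 <- normalize_volume(v, fit_scaling(list(v)))
  n2 <- normalize_volume(n1, fit_scaling(list(n1)))
  expect_equal(n2$data, n1$data, tolerance = 1e-12)
})

test_that("scaling factors survive a JSON round trip", {
  sf <- fit_scaling(list(make_ct(c(-800, 600, rep(0, 6))),
                         volume3d(array(1:8, c(2, 2, 2)), modality = "T2")))
  p <- withr::local_tempfile(fileext = ".json")
  write_scaling(sf, p)
  sf2 <- read_scaling(p)
  expect_equal(sf2$ct, sf$ct)
  expect_equal(sf2$series$T2, sf$series$T2)
})

test_that("isotropic resampling preserves extent, constancy and label sets", {
  # constant volume at spacing 2 doubles its grid per axis
  v <- volume3d(array(3, c(5, 5, 5)), spacing = c(2, 2, 2))
  r <- resample_isotropic(v, 1)
  expect_equal(dim(r$data), c(10, 10, 10))
  expect_true(all(abs(r$data - 3) < 1e-12))
  expect_equal(r$spacing, c(1, 1, 1))
  # already isotropic: identity
  v2 <- volume3d(array(runif(125), c(5, 5, 5)))
  expect_equal(resample_isotropic(v2, 1)$data, v2$data, tolerance = 1e-12)
  # a 2-slice bright slab at z-spacing 4 becomes ~8 voxels thick at 1 mm
  arr <- array(0, c(8, 8, 6)); arr[, , 3:4] <- 1
  slab <- resample_isotropic(volume3d(arr, spacing = c(1, 1, 4)), 1)
  thick <- sum(apply(slab$data > 0.5, 3, any))
  expect_gte(thick, 7); expect_lte(thick, 9)
  # masks stay binary under nearest-neighbour
  m <- label_mask(array(as.integer(runif(125) > 0.7), c(5, 5, 5)),
                  spacing = c(1, 1, 2))
  rm_ <- resample_isotropic(m, 1)
  expect_true(all(rm_$data %in% c(0L, 1L)))
  expect_error(resample_isotropic(v, -1), "positive")
})
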