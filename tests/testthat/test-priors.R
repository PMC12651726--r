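mask_of <- function(vals, dims = c(4, 3, 2))
  label_mask(array(as.integer(vals), dims))

test_that("enhanced region selects exactly the supra-threshold voxels", {
  v <- volume3d(array(c(rep(0.2, 10), rep(0.9, 14)), c(4, 3, 2)),
                modality = "T1CE")
  m <- enhanced_region(v, 0.5)
  expect_identical(as.vector(m$data), c(rep(0L, 10), rep(1L, 14)))
  expect_equal(sum(enhanced_region(v, 0.95)$data), 0)
  expect_error(enhanced_region(v, 1.5), "threshold")
})

test_that("vessel region is the set difference enhanced minus GTV", {
  enh <- mask_of(c(rep(1, 10), rep(0, 14)))
  gtv <- mask_of(c(rep(1, 6), rep(0, 18)))
  vr <- vessel_region(enh, gtv)
  expect_equal(sum(vr$data), 4)
  expect_equal(sum(vr$data & gtv$data), 0)
  expect_equal(sum(vessel_region(enh, enh)$data), 0)
  empty <- mask_of(rep(0, 24))
  expect_identical(vessel_region(enh, empty)$data, enh$data)
  expect_error(vessel_region(enh, label_mask(array(0L, c(2, 2, 2)))),
               "mismatch")
})

test_that("bone mask thresholds normalized CT; edge thresholds behave", {
  v <- volume3d(array(runif(24, 0, 0.5), c(4, 3, 2)), modality = "CT")
  expect_equal(sum(bone_mask(v, 0.65)$data), 0)
  expect_equal(sum(bone_mask(v, 1e-9)$data), 24)
})

test_that("bone destruction is the GTV-bone intersection", {
  gtv <- mask_of(c(rep(1, 8), rep(0, 16)))
  bone <- mask_of(c(rep(0, 4), rep(1, 8), rep(0, 12)))
  bd <- bone_destruction(gtv, bone)
  # independent set-intersection oracle on the listed coordinates
  expect_equal(which(bd$data == 1), intersect(which(gtv$data == 1),
                                              which(bone$data == 1)))
  expect_equal(sum(bone_destruction(gtv, mask_of(c(rep(0, 12), rep(1, 12))))$data), 0)
  sub <- mask_of(c(rep(1, 4), rep(0, 20)))
  expect_identical(bone_destruction(sub, gtv)$data, sub$data)
})

test_that("auto thresholds recover the phantom truth regions", {
  b <- phantom64(5)
  tg <- prior_targets(b)
  un <- label_mask(array(as.integer(b$gtvp$data | b$vessel_truth$data),
                         dim(b$gtvp$data)), b$spacing)
  expect_gte(jaccard(tg$enhanced_t1ce, un), 0.9)
  expect_gte(jaccard(tg$bone, b$bone_truth), 0.9)
})

test_that("prior subset invariants hold across phantom seeds", {
  for (seed in c(2, 11, 23, 31)) {
    b <- generate_case(phantom_config(grid_shape = c(32, 32, 8),
                                      tumor_radius_range = c(3, 5),
                                      seed = seed))
    tg <- prior_targets(b)
    expect_equal(sum(tg$vessel_t2$data & !tg$enhanced_t1ce$data), 0)
    expect_equal(sum(tg$bone_destruction_ct$data & !tg$bone$data), 0)
    expect_equal(sum(tg$bone_destruction_ct$data & !tg$gtv$data), 0)
    # thresholding is idempotent: re-applying to the binary mask keeps it
    mvol <- volume3d(tg$enhanced_t1ce$data + 0, b$spacing, modality = "T1CE")
    expect_identical(enhanced_region(mvol, 0.5)$data, tg$enhanced_t1ce$data)
  }
})

test_that("small-component removal drops isolated specks", {
  arr <- array(0L, c(8, 8, 4))
  arr[2:4, 2:4, 2:3] <- 1L   # 18-voxel blob
  arr[7, 7, 1] <- 1L         # single speck
  v <- volume3d(arr + 0, modality = "T1CE")
  tgless <- gsdiff:::remove_small_components(enhanced_region(v, 0.5), 5)
  expect_equal(sum(tgless$data), 18)
})
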