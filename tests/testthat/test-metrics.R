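single_voxel_mask <- function(at, dims = c(8, 4, 4)) {
  m <- array(0L, dims); m[at[1], at[2], at[3]] <- 1L
  label_mask(m)
}

test_that("Dice matches hand-counted overlaps and conventions", {
  d <- c(4, 3, 2)
  p <- array(0L, d); p[1:4, 1, 1] <- 1L              # |P| = 4
  r <- array(0L, d); r[1:4, 1, 1] <- 1L; r[1:4, 2, 1] <- 1L  # |R| = 8, overlap 4
  expect_equal(dsc(label_mask(p), label_mask(r)), 2 * 4 / 12)
  expect_equal(dsc(label_mask(r), label_mask(r)), 1)
  q <- array(0L, d); q[1, 1, 2] <- 1L
  expect_equal(dsc(label_mask(p), label_mask(q)), 0)
  expect_message(val <- dsc(label_mask(array(0L, d)), label_mask(array(0L, d))),
                 "empty")
  expect_equal(val, 1)
})

test_that("surface distances on single-voxel pairs are spacing-weighted", {
  a <- single_voxel_mask(c(2, 2, 2)); b <- single_voxel_mask(c(5, 2, 2))
  sd <- surface_distances(a, b)
  expect_true(all(sd$pred_to_ref == 3) && all(sd$ref_to_pred == 3))
  expect_equal(assd(a, b), 3)
  expect_equal(hd95(a, b), 3)
  expect_equal(assd(a, b, spacing = c(2, 1, 1)), 6)
  expect_equal(hd95(a, b, spacing = c(2, 1, 1)), 6)
  expect_equal(assd(a, a), 0)
  expect_equal(hd95(a, a), 0)
  expect_error(surface_distances(a, label_mask(array(0L, c(8, 4, 4)))),
               "empty")
})

test_that("metrics equal the brute-force all-pairs oracle on random masks", {
  set.seed(77)
  for (trial in 1:25) {
    p <- random_blob_mask(); r <- random_blob_mask()
    o <- oracle_surface_metrics(p$data, r$data)
    expect_equal(assd(p, r), o$assd, tolerance = 1e-9)
    expect_equal(hd95(p, r), o$hd95, tolerance = 1e-9)
    # percentile bound: hd95 never exceeds the exact Hausdorff distance
    expect_lte(hd95(p, r), o$hd + 1e-12)
    # symmetry
    expect_equal(assd(p, r), assd(r, p), tolerance = 1e-12)
    expect_equal(hd95(p, r), hd95(r, p), tolerance = 1e-12)
    expect_equal(dsc(p, r), dsc(r, p))
  }
})

test_that("metrics are invariant under joint translation", {
  set.seed(5)
  p <- random_blob_mask(c(16, 16, 10), clearance = 2)
  r <- random_blob_mask(c(16, 16, 10), clearance = 2)
  shift <- function(m, by) {
    d <- dim(m$data); out <- array(0L, d)
    out[(1 + by[1]):d[1], (1 + by[2]):d[2], (1 + by[3]):d[3]] <-
      m$data[1:(d[1] - by[1]), 1:(d[2] - by[2]), 1:(d[3] - by[3])]
    label_mask(out)
  }
  ps <- shift(p, c(2, 1, 1)); rs <- shift(r, c(2, 1, 1))
  # guard: nothing fell off the grid
  expect_equal(sum(ps$data), sum(p$data))
  expect_equal(sum(rs$data), sum(r$data))
  expect_equal(dsc(ps, rs), dsc(p, r))
  expect_equal(assd(ps, rs), assd(p, r), tolerance = 1e-12)
  expect_equal(hd95(ps, rs), hd95(p, r), tolerance = 1e-12)
})

test_that("metric_result and cohort tables handle empty predictions", {
  p <- single_voxel_mask(c(2, 2, 2))
  e <- label_mask(array(0L, c(8, 4, 4)))
  m <- metric_result(e, p)
  expect_equal(m$dsc, 0)
  expect_true(is.na(m$assd_mm) && is.na(m$hd95_mm))
  preds <- list(list(gtvp = p, gtvnd = e))
  refs <- list(list(gtvp = p, gtvnd = e))
  tab <- evaluate_cases(preds, refs)
  expect_equal(nrow(tab), 2 + 3)   # 2 per-case rows + 3 summary rows
  expect_equal(tab$dsc[tab$label == "GTVP"], 1)
})
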