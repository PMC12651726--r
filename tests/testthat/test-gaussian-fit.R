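test_that("locate_region zeroes exactly the voxels outside the prior", {
  v <- volume3d(array(runif(64, 0.2, 1), c(4, 4, 4)))
  full <- label_mask(array(1L, c(4, 4, 4)))
  expect_identical(locate_region(v, full)$data, v$data)
  pr <- array(0L, c(4, 4, 4)); pr[1:2, , ] <- 1L
  r <- locate_region(v, label_mask(pr))
  expect_true(all(r$data[3:4, , ] == 0))
  expect_identical(r$data > 0, pr == 1L)
  expect_error(locate_region(v, label_mask(array(0L, c(4, 4, 4)))),
               "threshold")
})

test_that("point initialization is seeded, in-support, and degenerate-safe", {
  b <- phantom32(4)
  tg <- prior_targets(b)
  region <- locate_region(b$t1ce, tg$enhanced_t1ce)
  f1 <- init_points(region, 64, seed = 9)
  f2 <- init_points(region, 64, seed = 9)
  expect_identical(f1$points, f2$points)
  # all means inside the prior's bounding box
  idx <- which(tg$enhanced_t1ce$data == 1, arr.ind = TRUE)
  expect_true(all(f1$points$mux >= min(idx[, 1]) & f1$points$mux <= max(idx[, 1])))
  expect_true(all(f1$points$muy >= min(idx[, 2]) & f1$points$muy <= max(idx[, 2])))
  expect_true(all(f1$points$muz >= min(idx[, 3]) & f1$points$muz <= max(idx[, 3])))
  # single nonzero voxel: the mean lands on that voxel centre
  v1 <- volume3d(array(0, c(5, 5, 5)))
  v1$data[3, 4, 2] <- 0.8
  p1 <- init_points(v1, 1, seed = 1)$points
  expect_equal(c(p1$mux, p1$muy, p1$muz), c(3, 4, 2))
  expect_error(init_points(volume3d(array(0, c(4, 4, 4))), 4), "all-zero")
})

test_that("a single-Gaussian target is recovered to sub-voxel accuracy", {
  for (seed in c(1, 2, 3)) {
    tru <- gaussian_point(c(16, 16, 4), c(2, 2, 2), intensity = 0.8)
    target <- render_volume(gaussian_field(list(tru), c(32, 32, 8)))
    fit <- gs_fit(target, n_points = 1, iterations = 300, seed = seed)
    p <- coef(fit)
    err <- sqrt((p$mux - 16)^2 + (p$muy - 16)^2 + (p$muz - 4)^2)
    expect_lt(err, 0.5)
    expect_lt(abs(p$i - 0.8) / 0.8, 0.1)
    expect_lte(fit$report$final_loss, fit$report$initial_loss)
  }
})

test_that("fitting the phantom enhanced region reconstructs it", {
  b <- phantom32(1)
  tg <- prior_targets(b)
  region <- locate_region(b$t1ce, tg$enhanced_t1ce)
  fit <- gs_fit(region, n_points = 96, iterations = 150, seed = 2)
  expect_lte(fit$report$final_loss, 0.25 * fit$report$initial_loss)
  r <- cor(as.numeric(fitted(fit)), as.numeric(region$data))
  expect_gte(r, 0.8)
  expect_equal(dim(residuals(fit)), dim(region$data))
  expect_error(gs_fit(region, n_points = 1, iterations = 0), "iterations")
})

test_that("extract_all returns three modality fields and propagates errors", {
  b <- phantom32(2)
  tg <- prior_targets(b)
  fits <- extract_all(b, tg, n_points = 48, iterations = 60)
  expect_named(fits, c("t1ce", "t2", "ct"))
  for (f in fits) expect_s3_class(f, "gsfit")
  # splat mass centre of the t1ce field near the truth-union projection
  img <- splat_2d(fits$t1ce$field)
  un <- apply(b$gtvp$data | b$vessel_truth$data, c(1, 2), max)
  cx <- sum(row(un) * un) / sum(un); cy <- sum(col(un) * un) / sum(un)
  mx <- sum(row(img) * img) / sum(img); my <- sum(col(img) * img) / sum(img)
  expect_lt(sqrt((mx - cx)^2 + (my - cy)^2), 2)
  # empty vessel prior (no vessels) fails naming the modality
  b0 <- generate_case(phantom_config(grid_shape = c(32, 32, 8),
                                     tumor_radius_range = c(3, 5),
                                     n_vessels = 0, seed = 3))
  tg0 <- prior_targets(b0)
  expect_error(extract_all(b0, tg0, n_points = 8, iterations = 2), "t2")
})

test_that("the learned decoder refines without replacing the analytic path", {
  tru <- gaussian_point(c(8, 8, 4), c(1.5, 1.5, 1.5), intensity = 0.6)
  target <- render_volume(gaussian_field(list(tru), c(16, 16, 8)))
  fit <- gs_fit(target, n_points = 4, iterations = 80, seed = 1,
                use_learned_decoder = TRUE)
  ana <- predict(fit, type = "analytic")$data
  dec <- predict(fit, type = "decoded")$data
  expect_false(identical(ana, dec))
  mse <- function(a) mean((a - target$data)^2)
  expect_lte(mse(dec), mse(ana) * 1.05)
})
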