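# tiny training setup reused across blocks
tiny_setup <- function(n_cases = 1, T = 10, epochs = 8, seed = 1) {
  cfg <- phantom_config(grid_shape = c(16, 16, 8), tumor_radius_range = c(2, 3),
                        n_vessels = 1, seed = seed)
  cases <- generate_cohort(cfg, n_cases, base_seed = seed)
  sched <- make_schedule(T)
  spec <- denoiser_spec(base_channels = 3, in_shape = c(16, 16, 8))
  model <- ddpm_train(cases, spec, sched, epochs = epochs, seed = seed)
  list(cases = cases, sched = sched, spec = spec, model = model)
}
.tiny <- NULL
get_tiny <- function() {
  if (is.null(.tiny)) .tiny <<- tiny_setup()
  .tiny
}

test_that("schedules carry the windowed modality assignment", {
  s <- make_schedule(1000)
  expect_equal(s$windows$start, c(1, 351, 701))
  expect_equal(s$windows$end, c(350, 700, 1000))
  expect_equal(s$windows$modality, c("t1ce", "t2", "ct"))
  s100 <- make_schedule(100)
  expect_equal(s100$windows$start, c(1, 36, 71))
  expect_equal(s100$windows$end, c(35, 70, 100))
  expect_true(all(diff(s$alpha_bar) < 0))
  # coverage: every step belongs to exactly one window
  mods <- vapply(1:100, function(s_) gsdiff:::window_modality(s100, s_),
                 character(1))
  expect_equal(as.vector(table(mods)[c("t1ce", "t2", "ct")]), c(35, 35, 30))
  bad <- data.frame(start = c(1, 400), end = c(500, 1000),
                    modality = c("t1ce", "t2"))
  expect_error(make_schedule(1000, windows = bad), "contiguous")
  expect_error(make_schedule(2), "T must be")
})

test_that("forward noising follows the closed-form marginal", {
  sched <- make_schedule(50)
  x0 <- array(sample(c(-1, 1), 64, TRUE), c(4, 4, 4))
  n <- array(runif(64, -1, 1), c(4, 4, 4))
  # near t = 1, alpha_bar ~ 1 and the output is ~ x0 (unit-bounded noise)
  expect_lt(max(abs(forward_noise(x0, 1, n, sched) - x0)), 0.02)
  # x0 = 0: exactly the scaled noise
  expect_equal(forward_noise(x0 * 0, 20, n, sched),
               sqrt(1 - sched$alpha_bar[20]) * n)
  expect_error(forward_noise(x0, 0, n, sched), "range")
  expect_error(forward_noise(x0, 51, n, sched), "range")
  # Monte-Carlo variance law at a fixed voxel
  set.seed(1)
  t <- 30
  draws <- forward_noise(rep(0, 1e4), t, rnorm(1e4), sched)
  expect_equal(var(draws), 1 - sched$alpha_bar[t], tolerance = 0.05)
})

test_that("training learns, and identical seeds give identical traces", {
  tn <- get_tiny()
  expect_lt(tail(tn$model$loss_trace, 1), tn$model$loss_trace[1])
  model2 <- ddpm_train(tn$cases, tn$spec, tn$sched, epochs = 8, seed = 1)
  expect_identical(tn$model$loss_trace, model2$loss_trace)
  expect_error(ddpm_train(tn$cases, denoiser_spec(3, in_shape = c(8, 8, 4)),
                          tn$sched), "in_shape")
})

test_that("zero-strength prompting is bit-identical to unconditional", {
  tn <- get_tiny()
  b <- tn$cases[[1]]
  fits <- list(t1ce = init_points(locate_region(b$t1ce,
                  enhanced_region(b$t1ce)), 8, 1))
  ps <- prompt_set(fits, lambda = 0.5)
  unc <- sample_conditional(tn$model, b$ct, NULL, seed = 11)
  con0 <- sample_conditional(tn$model, b$ct, ps, lambda = 0, seed = 11,
                             quiet = TRUE)
  expect_identical(con0$continuous, unc$continuous)
  con <- sample_conditional(tn$model, b$ct, ps, lambda = 0.5, seed = 11,
                            quiet = TRUE)
  expect_false(identical(con$continuous, unc$continuous))
  # prompt images must match the in-plane grid
  bad <- ps; bad$images$t1ce <- matrix(0, 4, 4)
  expect_error(sample_conditional(tn$model, b$ct, bad, seed = 1, quiet = TRUE),
               "shape mismatch")
})

test_that("sampled labels are disjoint, ties go to GTVp, and output decodes", {
  tn <- get_tiny()
  sm <- sample_conditional(tn$model, tn$cases[[1]]$ct, seed = 2)
  expect_equal(sum(sm$gtvp$data & sm$gtvnd$data), 0)
  over <- sm$continuous[, , , 1] > 0 & sm$continuous[, , , 2] > 0
  won_p <- sm$continuous[, , , 1] >= sm$continuous[, , , 2]
  expect_true(all(sm$gtvp$data[over & won_p] == 1))
  sims <- simulate(tn$model, nsim = 2, seed = 5, ct = tn$cases[[1]]$ct)
  expect_length(sims, 2)
  expect_false(identical(sims[[1]]$continuous, sims[[2]]$continuous))
})

test_that("ablation tables have one row per configuration and case", {
  tn <- get_tiny()
  b <- tn$cases[[1]]
  fits <- list(t1ce = init_points(locate_region(b$t1ce,
                  enhanced_region(b$t1ce)), 8, 1))
  ps <- prompt_set(fits)
  tab <- ablation_run(list(b), list(ps), tn$model,
                      configs = list(character(0), "t1ce"), seeds = 1:2)
  expect_equal(nrow(tab), 2 * 1)
  expect_equal(tab$config, c("none", "t1ce"))
  expect_true(all(tab$dsc_gtvp >= 0 & tab$dsc_gtvp <= 1))
})

test_that("translated prompts steer predictions in the same direction", {
  tn <- get_tiny()
  b <- tn$cases[[1]]
  # synthetic single-blob prompt and its +4-voxel x-translation
  g <- gaussian_field(list(gaussian_point(c(6, 8, 4), c(2, 2, 2),
                                          intensity = 1)), c(16, 16, 8))
  gt <- gaussian_field(list(gaussian_point(c(10, 8, 4), c(2, 2, 2),
                                           intensity = 1)), c(16, 16, 8))
  centroid_x <- function(ps) {
    xs <- vapply(1:10, function(s) {
      sm <- sample_conditional(tn$model, b$ct, ps, lambda = 2, seed = s,
                               quiet = TRUE)
      idx <- which(sm$gtvp$data == 1, arr.ind = TRUE)
      if (nrow(idx) == 0) NA_real_ else mean(idx[, 1])
    }, numeric(1))
    mean(xs, na.rm = TRUE)
  }
  base_x <- centroid_x(prompt_set(list(t1ce = g), lambda = 2))
  shift_x <- centroid_x(prompt_set(list(t1ce = gt), lambda = 2))
  expect_gt(shift_x, base_x)
})

test_that("models survive the save/load round trip", {
  tn <- get_tiny()
  base <- file.path(withr::local_tempdir(), "model")
  write_ddpm(tn$model, base)
  m2 <- read_ddpm(base)
  s1 <- sample_conditional(tn$model, tn$cases[[1]]$ct, seed = 3)
  s2 <- sample_conditional(m2, tn$cases[[1]]$ct, seed = 3)
  expect_identical(s1$continuous, s2$continuous)
  hdr <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  expect_equal(hdr$T, 10)
})
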