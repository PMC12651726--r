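test_that("eval_point matches an independent quadratic-form oracle", {
  set.seed(42)
  for (i in 1:200) {
    mu <- runif(3, 2, 14); sc <- runif(3, 0.5, 3); q <- rnorm(4)
    ii <- runif(1); x <- runif(3, 0, 16)
    g <- gaussian_point(mu, sc, q, ii)
    expect_equal(eval_point(x, g), oracle_eval(x, mu, sc, q, ii),
                 tolerance = 1e-12)
  }
  g <- gaussian_point(c(1, 2, 3), intensity = 0.7)
  expect_equal(eval_point(c(1, 2, 3), g), 0.7)
  g2 <- gaussian_point(c(0, 0, 0), c(2, 1, 1), intensity = 1)
  expect_equal(eval_point(c(2, 0, 0), g2), exp(-0.5))
  expect_error(gaussian_point(c(0, 0, 0), c(0, 1, 1)), "scale")
})

test_that("eval_point is invariant under joint rotation of offset and point", {
  set.seed(7)
  for (i in 1:25) {
    sc <- runif(3, 0.5, 2.5); ii <- runif(1)
    off <- rnorm(3)
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    R <- quat_to_rot(q)
    base <- eval_point(off, gaussian_point(c(0, 0, 0), sc, c(1, 0, 0, 0), ii))
    rot <- eval_point(drop(R %*% off),
                      gaussian_point(c(0, 0, 0), sc, q, ii))
    expect_equal(rot, base, tolerance = 1e-10)
  }
})

test_that("rendering is additive, linear in intensity, and mass-correct", {
  set.seed(3)
  mk <- function() gaussian_point(runif(3, 6, 26), runif(3, 0.7, 2),
                                  rnorm(4), runif(1))
  fa <- gaussian_field(lapply(1:3, function(i) mk()), c(32, 32, 32))
  fb <- gaussian_field(lapply(1:5, function(i) mk()), c(32, 32, 32))
  fm <- merge_fields(fa, fb)
  expect_equal(length(fm), 8)
  va <- render_volume(fa)$data; vb <- render_volume(fb)$data
  expect_lt(max(abs(render_volume(fm)$data - va - vb)), 1e-9)
  # linearity in intensity
  fc <- fa; fc$points$i <- 3 * fc$points$i
  expect_equal(render_volume(fc)$data, 3 * va, tolerance = 1e-12)
  # single tight point peaks at the voxel nearest its mean
  g <- gaussian_point(c(10.2, 20.4, 15.8), c(0.5, 0.5, 0.5), intensity = 1)
  v <- render_volume(gaussian_field(list(g), c(32, 32, 32)))$data
  expect_equal(unname(which(v == max(v), arr.ind = TRUE)[1, ]),
               c(10, 20, 16))
  # discrete mass of an isotropic point ~ i (2 pi)^{3/2} s^3
  s <- 1.7
  gi <- gaussian_point(c(16, 16, 16), rep(s, 3), intensity = 0.6)
  mass <- sum(render_volume(gaussian_field(list(gi), c(32, 32, 32)))$data)
  expect_equal(mass, 0.6 * (2 * pi)^1.5 * s^3, tolerance = 0.02)
  expect_warning(render_volume(gaussian_field(NULL, c(4, 4, 4))), "empty")
  expect_error(merge_fields(fa, gaussian_field(list(mk()), c(8, 8, 8))),
               "mismatch")
})

test_that("covariance projection follows Sigma' = J W Sigma W' J'", {
  set.seed(11)
  g <- random_point()
  S <- point_cov(g)
  expect_equal(project_covariance(g, diag(3), diag(3)), S)
  expect_equal(project_covariance(g, diag(c(2, 2, 2)), diag(3)), 4 * S)
  for (i in 1:30) {
    g <- random_point()
    q <- rnorm(4); R <- quat_to_rot(q)
    Sp <- project_covariance(g, diag(3), R)
    expect_equal(sort(eigen(Sp, symmetric = TRUE)$values),
                 sort(eigen(point_cov(g), symmetric = TRUE)$values),
                 tolerance = 1e-10)
  }
})

test_that("z-marginalization keeps the xy block and the Gaussian z-mass", {
  g <- gaussian_point(c(1, 2, 3), c(1, 1, 1), intensity = 1)
  m <- marginalize_z(g)
  expect_equal(m$mu2, c(1, 2))
  expect_equal(m$cov2, diag(2))
  expect_equal(m$intensity, sqrt(2 * pi))
  # correlated covariance: the 2D block is exactly the top-left submatrix,
  # cross-checked by numerically integrating the 3D density over z
  set.seed(5)
  for (i in 1:20) {
    g <- random_point()
    S <- point_cov(g)
    m <- marginalize_z(g)
    expect_equal(m$cov2, S[1:2, 1:2], tolerance = 1e-12)
    # numeric z-integration at a probe (x, y): agrees with the 2D density
    zs <- seq(g$mu[3] - 12, g$mu[3] + 12, by = 0.01)
    xy <- g$mu[1:2] + c(0.9, -0.7)
    vals <- vapply(zs, function(z) eval_point(c(xy, z), g), numeric(1))
    num <- sum(vals) * 0.01
    Ai <- solve(m$cov2); d <- xy - m$mu2
    ana <- m$intensity * exp(-0.5 * drop(t(d) %*% Ai %*% d))
    expect_equal(num, ana, tolerance = 1e-4)
  }
})

test_that("2D splats agree with z-summed 3D renders and track centroids", {
  set.seed(9)
  pts <- lapply(1:4, function(i)
    gaussian_point(c(runif(2, 8, 24), runif(1, 6, 10)), runif(3, 0.8, 1.6),
                   rnorm(4), runif(1, 0.3, 1)))
  f <- gaussian_field(pts, c(32, 32, 16))
  img <- splat_2d(f, normalize = FALSE)
  zsum <- apply(render_volume(f)$data, c(1, 2), sum)
  expect_lt(max(abs(img - zsum)) / max(img), 0.02)
  # normalized splat peaks at 1 near the point's (x, y)
  f1 <- gaussian_field(pts[1], c(32, 32, 16))
  img1 <- splat_2d(f1)
  expect_equal(max(img1), 1)
  pk <- which(img1 == 1, arr.ind = TRUE)[1, ]
  expect_lt(max(abs(pk - pts[[1]]$mu[1:2])), 1)
  # zero intensities give a zero image
  f0 <- f; f0$points$i <- 0
  expect_true(all(splat_2d(f0) == 0))
})

test_that("fields survive the TSV + JSON round trip", {
  set.seed(2)
  f <- gaussian_field(lapply(1:5, function(i) random_point()), c(16, 16, 16),
                      "T1CE")
  base <- file.path(withr::local_tempdir(), "field")
  write_field(f, base)
  f2 <- read_field(base)
  expect_equal(f2$points, f$points, tolerance = 1e-12)
  expect_equal(f2$grid_shape, f$grid_shape)
  expect_equal(f2$modality, "T1CE")
})
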