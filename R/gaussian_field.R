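#' Intensity-valued 3D Gaussian feature point
#'
#' A point carries a continuous voxel-space mean, an anisotropic covariance
#' parameterized as scale + unit quaternion (`Sigma = R diag(scale^2) R'`,
#' which is symmetric positive definite by construction), and a
#' non-negative scalar intensity that replaces view-dependent color.
#'
#' @param mu numeric 3-vector, mean position (voxel coordinates).
#' @param scale positive numeric 3-vector, per-axis standard deviations.
#' @param rotation quaternion `c(w, x, y, z)`; renormalized to unit norm.
#' @param intensity non-negative scalar.
#' @return an object of class `gaussian_point`.
#' @export
gaussian_point <- function(mu, scale = c(1, 1, 1), rotation = c(1, 0, 0, 0),
                           intensity = 1) {
  mu <- as.numeric(mu); scale <- as.numeric(scale)
  rotation <- as.numeric(rotation)
  if (length(mu) != 3 || any(!is.finite(mu))) stop("mu must be a finite 3-vector")
  if (length(scale) != 3 || any(scale <= 0) || any(!is.finite(scale)))
    stop("scale must be a positive 3-vector (degenerate scale gives a singular covariance)")
  nq <- sqrt(sum(rotation^2))
  if (length(rotation) != 4 || nq < 1e-12) stop("rotation must be a nonzero quaternion")
  if (intensity < 0) stop("intensity must be >= 0")
  structure(list(mu = mu, scale = scale, rotation = rotation / nq,
                 intensity = intensity), class = "gaussian_point")
}

#' Rotation matrix of a unit quaternion
#' @param q quaternion `c(w, x, y, z)` (normalized internally).
#' @return 3x3 rotation matrix.
#' @export
quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3)  # column-major: columns are images of the basis vectors
}

#' Covariance matrix of a Gaussian point
#' @param g a [gaussian_point] (or list with `scale`, `rotation`).
#' @return 3x3 SPD covariance matrix.
#' @export
point_cov <- function(g) {
  R <- quat_to_rot(g$rotation)
  R %*% diag(g$scale^2) %*% t(R)
}

#' Evaluate one Gaussian point at a position
#'
#' Returns `i * exp(-1/2 (x - mu)' Sigma^{-1} (x - mu))`.
#'
#' @param x numeric 3-vector, evaluation position (voxel coordinates).
#' @param g a [gaussian_point].
#' @return scalar field value.
#' @export
eval_point <- function(x, g) {
  if (any(g$scale < 1e-8))
    stop("singular covariance: scale components must be positive")
  d <- as.numeric(x) - g$mu
  S <- point_cov(g)
  as.numeric(g$intensity * exp(-0.5 * drop(crossprod(d, solve(S, d)))))
}

#' Ordered collection of Gaussian points on a grid
#'
#' @param points data frame with columns `mux, muy, muz, sx, sy, sz,
#'   qw, qx, qy, qz, i` (one row per point), or a list of
#'   [gaussian_point]s.
#' @param grid_shape integer triple, the carrier grid.
#' @param modality modality tag.
#' @return an object of class `gaussian_field`.
#' @export
gaussian_field <- function(points, grid_shape, modality = "OTHER") {
  if (is.list(points) && !is.data.frame(points)) {
    points <- do.call(rbind, lapply(points, function(g) {
      data.frame(mux = g$mu[1], muy = g$mu[2], muz = g$mu[3],
                 sx = g$scale[1], sy = g$scale[2], sz = g$scale[3],
                 qw = g$rotation[1], qx = g$rotation[2], qy = g$rotation[3],
                 qz = g$rotation[4], i = g$intensity)
    }))
  }
  need <- c("mux", "muy", "muz", "sx", "sy", "sz", "qw", "qx", "qy", "qz", "i")
  if (is.null(points) || nrow(points) == 0)
    points <- as.data.frame(matrix(numeric(0), 0, 11, dimnames = list(NULL, need)))
  if (!all(need %in% names(points))) stop("missing point columns")
  if (any(!is.finite(as.matrix(points[need]))))
    stop("all point parameters must be finite")
  if (any(points$i < 0)) stop("intensities must be >= 0")
  structure(list(points = points[need], grid_shape = as.integer(grid_shape),
                 modality = modality),
            class = "gaussian_field")
}

#' @export
print.gaussian_field <- function(x, ...) {
  cat(sprintf("<gaussian_field %s> %d points on %s grid\n", x$modality,
              nrow(x$points), paste(x$grid_shape, collapse = "x")))
  invisible(x)
}

#' @export
length.gaussian_field <- function(x) nrow(x$points)

# i-th row as a gaussian_point
field_point <- function(field, i) {
  p <- field$points[i, ]
  gaussian_point(c(p$mux, p$muy, p$muz), c(p$sx, p$sy, p$sz),
                 c(p$qw, p$qx, p$qy, p$qz), p$i)
}

# packed inverse covariances (a11,a22,a33,a12,a13,a23) for the C++ kernels
field_ainv <- function(points) {
  n <- nrow(points)
  A <- matrix(0, n, 6)
  for (k in seq_len(n)) {
    R <- quat_to_rot(c(points$qw[k], points$qx[k], points$qy[k], points$qz[k]))
    Ai <- R %*% diag(1 / c(points$sx[k], points$sy[k], points$sz[k])^2) %*% t(R)
    A[k, ] <- c(Ai[1, 1], Ai[2, 2], Ai[3, 3], Ai[1, 2], Ai[1, 3], Ai[2, 3])
  }
  A
}

#' Render a Gaussian field to a volume
#'
#' Analytic additive compositing: the value at each voxel centre is the sum
#' of [eval_point()] over all points (each truncated beyond
#' `cutoff_sigmas` standard deviations). Values are non-negative by
#' construction. An empty field renders a zero volume with a warning.
#'
#' @param field a [gaussian_field].
#' @param spacing spacing of the output volume.
#' @param cutoff_sigmas evaluation radius per point, in units of its
#'   largest scale.
#' @return a [volume3d].
#' @export
render_volume <- function(field, spacing = c(1, 1, 1), cutoff_sigmas = 6) {
  dims <- field$grid_shape
  if (nrow(field$points) == 0) {
    warning("empty field: rendering a zero volume")
    return(volume3d(array(0, dims), spacing, modality = field$modality))
  }
  pts <- field$points
  mu <- as.matrix(pts[, c("mux", "muy", "muz")])
  A <- field_ainv(pts)
  radius <- cutoff_sigmas * pmax(pts$sx, pmax(pts$sy, pts$sz))
  v <- render_gaussians_cpp(mu, A, pts$i, dims, radius)
  volume3d(array(pmax(v, 0), dims), spacing, modality = field$modality)
}

#' Project a Gaussian covariance through view and affine transforms
#'
#' Returns `Sigma' = J W Sigma W' J'`, the covariance of the splatted
#' Gaussian under a view transformation `W` and the Jacobian `J` of the
#' affine approximation of the projective transformation. The result may be
#' rank-deficient for projective `J`.
#'
#' @param g a [gaussian_point].
#' @param J,W 3x3 matrices.
#' @return 3x3 matrix.
#' @export
project_covariance <- function(g, J = diag(3), W = diag(3)) {
  if (any(!is.finite(J)) || any(!is.finite(W))) stop("J, W must be finite")
  S <- point_cov(g)
  J %*% W %*% S %*% t(W) %*% t(J)
}

#' Marginalize a 3D Gaussian point over the z axis
#'
#' Integrating the 3D density over z yields a 2D Gaussian whose mean is
#' `(mu_x, mu_y)` and whose covariance is the top-left 2x2 block of
#' `Sigma`; the intensity carries the exact Gaussian z-mass factor
#' `sqrt(2 pi / (Sigma^{-1})_zz)` (the Schur complement of the xy block,
#' equal to `sqrt(2 pi Sigma_zz)` when z is uncorrelated) so 3D and 2D
#' masses stay consistent.
#'
#' @param g a [gaussian_point].
#' @return an object of class `gaussian2d` with `mu2`, `cov2`, `intensity`.
#' @export
marginalize_z <- function(g) {
  S <- point_cov(g)
  zmass <- S[3, 3] - drop(S[3, 1:2] %*% solve(S[1:2, 1:2], S[1:2, 3]))
  structure(list(mu2 = g$mu[1:2], cov2 = S[1:2, 1:2],
                 intensity = g$intensity * sqrt(2 * pi * zmass)),
            class = "gaussian2d")
}

#' Splat a Gaussian field onto a 2D grid along z
#'
#' Each point is z-marginalized and its 2D density evaluated at pixel
#' centres; contributions are summed and the image is normalized to
#' maximum 1 when nonzero.
#'
#' @param field a [gaussian_field].
#' @param grid_shape_2d integer pair; defaults to the field's x-y grid.
#' @param normalize logical, rescale the image to max 1.
#' @return 2D numeric matrix.
#' @export
splat_2d <- function(field, grid_shape_2d = field$grid_shape[1:2],
                     normalize = TRUE) {
  nx <- grid_shape_2d[1]; ny <- grid_shape_2d[2]
  img <- matrix(0, nx, ny)
  if (nrow(field$points) == 0) return(img)
  gx <- rep(seq_len(nx), ny); gy <- rep(seq_len(ny), each = nx)
  for (k in seq_len(nrow(field$points))) {
    g2 <- marginalize_z(field_point(field, k))
    Ai <- solve(g2$cov2)
    dx <- gx - g2$mu2[1]; dy <- gy - g2$mu2[2]
    q <- Ai[1, 1] * dx^2 + 2 * Ai[1, 2] * dx * dy + Ai[2, 2] * dy^2
    img <- img + matrix(g2$intensity * exp(-0.5 * q), nx, ny)
  }
  if (normalize && max(img) > 0) img <- img / max(img)
  img
}

#' Merge two Gaussian fields
#'
#' Mathematical addition of Gaussian mixtures: point collections are
#' concatenated, so the merged rendering equals the sum of the individual
#' renderings exactly.
#'
#' @param a,b [gaussian_field]s on the same grid.
#' @return merged [gaussian_field].
#' @export
merge_fields <- function(a, b) {
  if (!identical(a$grid_shape, b$grid_shape))
    stop("grid mismatch between fields")
  gaussian_field(rbind(a$points, b$points), a$grid_shape,
                 if (a$modality == b$modality) a$modality else "OTHER")
}

#' Write / read a Gaussian field as TSV + JSON header
#'
#' One row per point (`mux muy muz sx sy sz qw qx qy qz i`); the header
#' stores the grid shape and modality.
#'
#' @param field a [gaussian_field].
#' @param path base path; writes `<path>.tsv` and `<path>.json`.
#' @return base path (write) or the field (read).
#' @export
write_field <- function(field, path) {
  utils::write.table(field$points, paste0(path, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(grid_shape = field$grid_shape,
                            modality = field$modality,
                            n_points = nrow(field$points)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pts <- utils::read.table(paste0(path, ".tsv"), header = TRUE, sep = "\t")
  gaussian_field(pts, hdr$grid_shape, hdr$modality)
}
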