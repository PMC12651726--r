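#' Restrict a volume to a prior region
#'
#' Zeroes every voxel outside the prior mask, producing the "regional
#' anatomy image" that supervises Gaussian-field fitting.
#'
#' @param volume a [volume3d].
#' @param prior a [label_mask] on the same grid.
#' @return the masked [volume3d].
#' @export
locate_region <- function(volume, prior) {
  stop_if_grid_mismatch(volume, prior)
  if (sum(prior$data) == 0)
    stop("empty prior region: adjust the threshold before fitting")
  volume$data[prior$data == 0] <- 0
  volume
}

#' Initialize Gaussian points from a regional image
#'
#' Point means are sampled from the nonzero voxels weighted by intensity
#' (with replacement when the region has fewer voxels than points); scales
#' start at the mean inter-point distance implied by the region volume;
#' intensities start at the sampled voxel values. Deterministic under
#' `seed`.
#'
#' @param region masked [volume3d] from [locate_region()].
#' @param n_points positive integer.
#' @param seed integer.
#' @return a [gaussian_field].
#' @export
init_points <- function(region, n_points, seed = 1) {
  nz <- which(region$data > 0)
  if (!length(nz)) stop("all-zero region: nothing to initialize from")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  w <- region$data[nz]
  pick <- if (length(nz) == 1L) rep(nz, n_points)
          else sample(nz, n_points, replace = n_points > length(nz), prob = w)
  d <- dim(region$data)
  z <- (pick - 1L) %/% (d[1] * d[2]) + 1L
  y <- ((pick - 1L) %/% d[1]) %% d[2] + 1L
  x <- (pick - 1L) %% d[1] + 1L
  s0 <- min(max((length(nz) / n_points)^(1 / 3), 0.6), 4)
  gaussian_field(data.frame(
    mux = as.numeric(x), muy = as.numeric(y), muz = as.numeric(z),
    sx = s0, sy = s0, sz = s0, qw = 1, qx = 0, qy = 0, qz = 0,
    i = region$data[pick]), d, region$modality)
}

#' Fit a Gaussian field to a regional image
#'
#' Gradient-optimizes the means, scales, rotations and intensities of
#' `n_points` Gaussian points so that the analytic rendering reconstructs
#' the masked regional image, by Adam on an unconstrained parameterization
#' (log-scales, raw quaternion, log-intensity, so the covariance stays SPD
#' and the intensity non-negative). The best iterate is reported, so the
#' final loss never exceeds the initial loss.
#'
#' @param region masked [volume3d] target (see [locate_region()]).
#' @param n_points number of Gaussian points (desk default 256).
#' @param iterations Adam iterations (>= 1).
#' @param learning_rate Adam step size.
#' @param loss_kind `"L2"` (mean squared error) or `"L1"`.
#' @param seed integer seed for the initialization.
#' @param use_learned_decoder if `TRUE`, a small volumetric convolutional
#'   refiner is trained on top of the analytic rendering after the Gaussian
#'   fit (the analytic path is unchanged and remains the reference output).
#' @param cutoff_sigmas render truncation radius in units of each point's
#'   largest scale.
#' @return an object of class `gsfit` with elements `field` (the fitted
#'   [gaussian_field]), `report` (initial/final loss, trace, iterations),
#'   `target`, and optionally `decoder`.
#' @export
gs_fit <- function(region, n_points = 256, iterations = 400,
                   learning_rate = 0.05, loss_kind = c("L2", "L1"),
                   seed = 1, use_learned_decoder = FALSE,
                   cutoff_sigmas = 6) {
  loss_kind <- match.arg(loss_kind)
  if (n_points < 1 || iterations < 1)
    stop("n_points and iterations must be >= 1")
  dims <- dim(region$data)
  field <- init_points(region, n_points, seed)
  pts <- field$points
  n <- nrow(pts)

  # unconstrained parameter matrix: mu(3), log-scale(3), quat(4), log-i(1)
  theta <- cbind(pts$mux, pts$muy, pts$muz,
                 log(pts$sx), log(pts$sy), log(pts$sz),
                 pts$qw, pts$qx, pts$qy, pts$qz,
                 log(pmax(pts$i, 1e-4)))
  target <- as.numeric(region$data)
  lk <- if (loss_kind == "L2") 0L else 1L
  m <- v <- matrix(0, n, 11)
  b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8
  smin <- log(0.4); smax <- log(max(4, min(dims) / 2))
  trace <- numeric(iterations)
  best <- NULL; best_loss <- Inf; initial_loss <- NA_real_

  for (it in seq_len(iterations)) {
    mu <- theta[, 1:3, drop = FALSE]
    sc <- exp(theta[, 4:6, drop = FALSE])
    qn <- theta[, 7:10, drop = FALSE]
    ii <- exp(theta[, 11])
    A <- matrix(0, n, 6)
    Rlist <- vector("list", n)
    for (k in seq_len(n)) {
      R <- quat_to_rot(qn[k, ])
      Rlist[[k]] <- R
      Ai <- R %*% diag(1 / sc[k, ]^2) %*% t(R)
      A[k, ] <- c(Ai[1, 1], Ai[2, 2], Ai[3, 3], Ai[1, 2], Ai[1, 3], Ai[2, 3])
    }
    radius <- pmin(cutoff_sigmas * apply(sc, 1, max), max(dims))
    out <- render_loss_grad_cpp(mu, A, ii, dims, radius, target, lk)
    loss <- out$loss
    if (!is.finite(loss))
      stop("fit diverged at iteration ", it, " (non-finite loss); trace: ",
           paste(signif(trace[seq_len(it - 1)], 4), collapse = ", "))
    trace[it] <- loss
    if (it == 1) initial_loss <- loss
    if (loss < best_loss) { best_loss <- loss; best <- theta }

    grad <- matrix(0, n, 11)
    grad[, 1:3] <- out$grad_mu
    grad[, 11] <- out$grad_i * ii
    h <- 1e-6
    for (k in seq_len(n)) {
      gA <- out$grad_A[k, ]
      Gm <- matrix(c(gA[1], gA[4] / 2, gA[5] / 2,
                     gA[4] / 2, gA[2], gA[6] / 2,
                     gA[5] / 2, gA[6] / 2, gA[3]), 3)
      Ai <- matrix(c(A[k, 1], A[k, 4], A[k, 5],
                     A[k, 4], A[k, 2], A[k, 6],
                     A[k, 5], A[k, 6], A[k, 3]), 3)
      dS <- -Ai %*% Gm %*% Ai            # dL/dSigma (full-matrix sense)
      R <- Rlist[[k]]
      for (ax in 1:3)                     # dSigma/dlog s = 2 s^2 r r'
        grad[k, 3 + ax] <- 2 * sc[k, ax]^2 *
          drop(crossprod(R[, ax], dS %*% R[, ax]))
      D <- diag(sc[k, ]^2)
      for (j in 1:4) {                    # quaternion via central differences
        qp <- qn[k, ]; qm <- qn[k, ]
        qp[j] <- qp[j] + h; qm[j] <- qm[j] - h
        Rp <- quat_to_rot(qp); Rm <- quat_to_rot(qm)
        dSigma <- (Rp %*% D %*% t(Rp) - Rm %*% D %*% t(Rm)) / (2 * h)
        grad[k, 6 + j] <- sum(dS * dSigma)
      }
    }

    m <- b1 * m + (1 - b1) * grad
    v <- b2 * v + (1 - b2) * grad^2
    mh <- m / (1 - b1^it); vh <- v / (1 - b2^it)
    theta <- theta - learning_rate * mh / (sqrt(vh) + epsA)
    theta[, 1] <- pmin(pmax(theta[, 1], 1), dims[1])
    theta[, 2] <- pmin(pmax(theta[, 2], 1), dims[2])
    theta[, 3] <- pmin(pmax(theta[, 3], 1), dims[3])
    theta[, 4:6] <- pmin(pmax(theta[, 4:6], smin), smax)
    theta[, 11] <- pmin(pmax(theta[, 11], log(1e-4)), log(50))
    qnorm_ <- sqrt(rowSums(theta[, 7:10, drop = FALSE]^2))
    theta[, 7:10] <- theta[, 7:10, drop = FALSE] / qnorm_
  }

  qb <- best[, 7:10, drop = FALSE]
  qb <- qb / sqrt(rowSums(qb^2))
  fitted_field <- gaussian_field(data.frame(
    mux = best[, 1], muy = best[, 2], muz = best[, 3],
    sx = exp(best[, 4]), sy = exp(best[, 5]), sz = exp(best[, 6]),
    qw = qb[, 1], qx = qb[, 2], qy = qb[, 3], qz = qb[, 4],
    i = exp(best[, 11])), dims, region$modality)

  obj <- structure(list(
    field = fitted_field,
    report = list(initial_loss = initial_loss, final_loss = best_loss,
                  loss_trace = trace, elapsed_iterations = iterations),
    target = region, loss_kind = loss_kind, seed = seed,
    cutoff_sigmas = cutoff_sigmas, decoder = NULL,
    call = match.call()), class = "gsfit")
  if (use_learned_decoder)
    obj$decoder <- train_decoder(obj, seed = seed)
  obj
}

#' @export
print.gsfit <- function(x, ...) {
  r <- x$report
  cat(sprintf("<gsfit %s> %d points, %d iterations\n", x$field$modality,
              nrow(x$field$points), r$elapsed_iterations))
  cat(sprintf("  loss (%s): %.6g -> %.6g (%.1f%% of initial)\n", x$loss_kind,
              r$initial_loss, r$final_loss,
              100 * r$final_loss / r$initial_loss))
  invisible(x)
}

#' @export
summary.gsfit <- function(object, ...) {
  print(object)
  v <- predict(object)
  cc <- stats::cor(as.numeric(v$data), as.numeric(object$target$data))
  cat(sprintf("  render-target Pearson r: %.4f\n", cc))
  invisible(list(report = object$report, pearson_r = cc))
}

#' @export
coef.gsfit <- function(object, ...) object$field$points

#' Render a fitted Gaussian field
#'
#' With `type = "analytic"` (the reference path) the fitted field is
#' rendered analytically; `type = "decoded"` additionally applies the
#' learned convolutional refiner when one was trained.
#'
#' @param object a `gsfit`.
#' @param type `"analytic"` or `"decoded"`.
#' @param ... unused.
#' @return a [volume3d].
#' @export
predict.gsfit <- function(object, type = c("analytic", "decoded"), ...) {
  type <- match.arg(type)
  v <- render_volume(object$field, object$target$spacing,
                     object$cutoff_sigmas)
  if (type == "decoded") {
    if (is.null(object$decoder))
      stop("no learned decoder was trained for this fit")
    v$data[] <- decoder_apply(object$decoder, v$data)
  }
  v
}

#' @export
fitted.gsfit <- function(object, ...) predict(object)$data

#' @export
residuals.gsfit <- function(object, ...) {
  object$target$data - fitted(object)
}

#' @export
plot.gsfit <- function(x, slice = NULL, ...) {
  opar <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(opar))
  plot(x$report$loss_trace, type = "l", log = "y", xlab = "iteration",
       ylab = sprintf("%s loss", x$loss_kind), main = "fit trace")
  d <- dim(x$target$data)
  if (is.null(slice)) slice <- round(d[3] / 2)
  graphics::image(x$target$data[, , slice], main = "target (mid slice)",
                  col = grDevices::gray.colors(64), axes = FALSE)
  graphics::image(fitted(x)[, , slice], main = "rendered",
                  col = grDevices::gray.colors(64), axes = FALSE)
  invisible(x)
}

#' Fit per-modality Gaussian fields for one case
#'
#' Runs the full prior-guided extraction: the T1-ce field is fitted to the
#' enhanced (cancer+vessel) region, the T2 field to the vessel region, and
#' the CT field to the bone-destruction region, each with its own derived
#' seed.
#'
#' @param bundle a `case_bundle`.
#' @param targets a `prior_targets` for the same case.
#' @param n_points,iterations,learning_rate,loss_kind,seed fit settings
#'   (see [gs_fit()]).
#' @return named list (`t1ce`, `t2`, `ct`) of `gsfit` objects.
#' @export
extract_all <- function(bundle, targets, n_points = 256, iterations = 400,
                        learning_rate = 0.05, loss_kind = "L2", seed = 1) {
  jobs <- list(
    t1ce = list(vol = bundle$t1ce, prior = targets$enhanced_t1ce),
    t2 = list(vol = bundle$t2, prior = targets$vessel_t2),
    ct = list(vol = bundle$ct, prior = targets$bone_destruction_ct))
  out <- vector("list", 3); names(out) <- names(jobs)
  for (j in seq_along(jobs)) {
    mod <- names(jobs)[j]
    region <- tryCatch(locate_region(jobs[[j]]$vol, jobs[[j]]$prior),
                       error = function(e)
                         stop(mod, " extraction failed: ", conditionMessage(e),
                              call. = FALSE))
    out[[j]] <- gs_fit(region, n_points = n_points, iterations = iterations,
                       learning_rate = learning_rate, loss_kind = loss_kind,
                       seed = seed + j)
  }
  out
}
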