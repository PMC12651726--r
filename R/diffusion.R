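#' Diffusion noise schedule with modality prompt windows
#'
#' A linear variance schedule (`beta` from 1e-4 to 0.02 over `T` steps)
#' together with the step-windowed modality assignment used during
#' conditional sampling: by default the T1-ce prompt is active in reverse
#' iterations 1-350, T2 in 351-700 and CT in 701-1000 (at `T = 1000`);
#' for other `T` the window boundaries scale proportionally.
#'
#' @param T number of diffusion steps (>= 3).
#' @param kind schedule kind; `"linear"` is implemented.
#' @param windows optional data frame with columns `start`, `end`,
#'   `modality`; must be contiguous, non-overlapping, and cover `1..T`.
#' @return an object of class `diffusion_schedule` with `T`, `beta`,
#'   `alpha_bar` (strictly decreasing) and `windows`.
#' @export
make_schedule <- function(T = 1000, kind = c("linear"), windows = NULL) {
  kind <- match.arg(kind)
  T <- as.integer(T)
  if (T < 3) stop("T must be >= 3")
  beta <- seq(1e-4, 0.02, length.out = T)
  alpha_bar <- cumprod(1 - beta)
  if (is.null(windows)) {
    b1 <- as.integer(round(350 * T / 1000))
    b2 <- as.integer(round(700 * T / 1000))
    windows <- data.frame(start = c(1L, b1 + 1L, b2 + 1L),
                          end = c(b1, b2, T),
                          modality = c("t1ce", "t2", "ct"),
                          stringsAsFactors = FALSE)
  }
  windows <- windows[order(windows$start), ]
  if (windows$start[1] != 1L || windows$end[nrow(windows)] != T ||
      any(windows$start[-1] != windows$end[-nrow(windows)] + 1L) ||
      any(windows$end < windows$start))
    stop("prompt windows must be contiguous, non-overlapping, and cover 1..T")
  structure(list(T = T, beta = beta, alpha_bar = alpha_bar, kind = kind,
                 windows = windows),
            class = "diffusion_schedule")
}

#' @export
print.diffusion_schedule <- function(x, ...) {
  cat(sprintf("<diffusion_schedule %s> T = %d, beta in [%g, %g]\n",
              x$kind, x$T, x$beta[1], x$beta[x$T]))
  for (r in seq_len(nrow(x$windows)))
    cat(sprintf("  steps %4d-%4d: %s prompt\n", x$windows$start[r],
                x$windows$end[r], x$windows$modality[r]))
  invisible(x)
}

# modality whose prompt window contains reverse iteration s (1 = first)
window_modality <- function(schedule, s) {
  w <- schedule$windows
  w$modality[w$start <= s & s <= w$end][1]
}

#' Forward diffusion (noising) step
#'
#' Returns `sqrt(alpha_bar_t) x0 + sqrt(1 - alpha_bar_t) noise`, the
#' closed-form marginal of the forward process at diffusion time `t`.
#'
#' @param x0 array with mask values encoded in `[-1, 1]`.
#' @param t diffusion time, `1 <= t <= T`.
#' @param noise array of the same shape as `x0`.
#' @param schedule a [make_schedule()] object.
#' @return noisy array.
#' @export
forward_noise <- function(x0, t, noise, schedule) {
  if (t < 1 || t > schedule$T) stop("t out of range [1, ", schedule$T, "]")
  ab <- schedule$alpha_bar[t]
  sqrt(ab) * x0 + sqrt(1 - ab) * noise
}

# stack GTVp/GTVnd masks into a two-channel tensor in {-1, +1}
encode_masks <- function(gtvp, gtvnd) {
  d <- dim(gtvp$data)
  x0 <- array(-1, c(d, 2))
  x0[, , , 1][gtvp$data == 1] <- 1
  x0[, , , 2][gtvnd$data == 1] <- 1
  x0
}

#' Pretrain the unconditional diffusion segmentation model
#'
#' Trains the relation-encoding denoiser to predict the injected noise from
#' the noisy two-channel GTV mask, the diffusion time, and the source CT,
#' encoding the CT-to-GTV segmentation relation. Masks are encoded to
#' `{-1, +1}`. Training is serial and fully seeded, so identical seeds give
#' identical loss traces.
#'
#' @param cases list of `case_bundle`s (or lists with `ct`, `gtvp`,
#'   `gtvnd`), all on the same grid.
#' @param spec a [denoiser_spec()].
#' @param schedule a [make_schedule()] object.
#' @param epochs passes over the cases.
#' @param seed integer seed.
#' @param learning_rate initial Adam step size.
#' @param lr_decay_at epoch fractions at which the step size is multiplied
#'   by `lr_decay_factor` (step decay; `NULL` disables).
#' @param lr_decay_factor multiplier applied at each decay point.
#' @return an object of class `ddpm` with the trained weights, the
#'   per-epoch mean loss trace, and the training configuration.
#' @export
ddpm_train <- function(cases, spec = denoiser_spec(), schedule = make_schedule(100),
                       epochs = 150, seed = 1, learning_rate = 2e-3,
                       lr_decay_at = c(0.6, 0.85), lr_decay_factor = 0.3) {
  dims <- dim(cases[[1]]$ct$data)
  for (cs in cases)
    if (!identical(dim(cs$ct$data), dims)) stop("cases must share grid shape")
  if (!identical(as.integer(dims), spec$in_shape))
    stop("spec in_shape ", paste(spec$in_shape, collapse = "x"),
         " does not match case grid ", paste(dims, collapse = "x"))
  data <- lapply(cases, function(cs)
    list(ct = cs$ct$data, x0 = encode_masks(cs$gtvp, cs$gtvnd)))
  params <- unet_init(spec, seed)
  st <- adam_state(params)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  trace <- numeric(epochs)
  decay_epochs <- if (is.null(lr_decay_at)) integer(0)
                  else pmax(1L, ceiling(lr_decay_at * epochs))
  lr <- learning_rate
  for (ep in seq_len(epochs)) {
    lr <- learning_rate * lr_decay_factor^sum(ep >= decay_epochs)
    ord <- sample(length(data))
    ep_loss <- 0
    for (ci in ord) {
      t <- sample.int(schedule$T, 1)
      noise <- array(stats::rnorm(length(data[[ci]]$x0)), dim(data[[ci]]$x0))
      xt <- forward_noise(data[[ci]]$x0, t, noise, schedule)
      fw <- unet_forward(params, xt, data[[ci]]$ct, t, schedule$T, spec,
                         keep_cache = TRUE)
      resid <- fw$eps - noise
      loss <- mean(resid^2)
      if (!is.finite(loss)) stop("non-finite training loss at epoch ", ep)
      ep_loss <- ep_loss + loss
      deps <- 2 * resid / length(resid)
      grads <- unet_backward(params, fw$cache, deps)
      upd <- adam_step(params, grads, st, lr)
      params <- upd$params; st <- upd$state
    }
    trace[ep] <- ep_loss / length(data)
  }
  structure(list(params = params, spec = spec, schedule = schedule,
                 loss_trace = trace, epochs = epochs, seed = seed,
                 learning_rate = learning_rate),
            class = "ddpm")
}

#' @rdname ddpm_train
#' @export
train_unconditional <- ddpm_train

#' @export
print.ddpm <- function(x, ...) {
  cat(sprintf("<ddpm> T = %d, base channels %d, trained %d epochs (seed %d)\n",
              x$schedule$T, x$spec$base_channels, x$epochs, x$seed))
  cat(sprintf("  epoch-mean loss: %.5f -> %.5f\n", x$loss_trace[1],
              x$loss_trace[x$epochs]))
  invisible(x)
}

#' Build a prompt set from fitted Gaussian fields
#'
#' Each per-modality field is z-marginalized and splatted to a 2D prompt
#' image (max-normalized). Signs encode how each prompt steers the GTVp
#' channel: the T1-ce (coarse cancer+vessel) and CT (bone destruction)
#' prompts push towards foreground, the T2 (vessel) prompt suppresses the
#' vessel region so fine cancer contouring remains.
#'
#' @param fields named list (subset of `t1ce`, `t2`, `ct`) of
#'   [gaussian_field]s or `gsfit` objects.
#' @param lambda non-negative prompt strength.
#' @param signs named numeric vector of injection signs per modality.
#' @return an object of class `prompt_set`.
#' @export
prompt_set <- function(fields, lambda = 0.5,
                       signs = c(t1ce = 1, t2 = -1, ct = 1)) {
  if (lambda < 0) stop("lambda must be non-negative")
  imgs <- lapply(fields, function(f) {
    if (inherits(f, "gsfit")) f <- f$field
    splat_2d(f)
  })
  structure(list(images = imgs, lambda = lambda, signs = signs),
            class = "prompt_set")
}

#' Gaussian-prompted conditional sampling
#'
#' Runs the full ancestral reverse diffusion; at reverse iteration `s`
#' (1 = highest noise) the modality whose window contains `s` is active and
#' its 2D prompt, broadcast identically to every slice, is added (with its
#' sign, scaled by `lambda`) to the per-step Gaussian noise draw of the
#' GTVp channel. With `lambda = 0`, or with no prompts, the trajectory is
#' bit-identical to unconditional sampling at the same seed. The final
#' continuous output is thresholded at 0 into GTVp/GTVnd labels; overlaps
#' go to the larger channel, ties to GTVp.
#'
#' @param model a trained [ddpm_train()] object.
#' @param ct source CT [volume3d] (normalized) on the training grid.
#' @param prompts a [prompt_set()] or `NULL` for unconditional sampling.
#' @param lambda prompt strength override (defaults to `prompts$lambda`).
#' @param seed integer seed.
#' @param inject `"noise"` adds prompts to the noise draw (default);
#'   `"xt"` adds them directly to the intermediate state.
#' @param variance per-step sampler variance: `"beta"` uses
#'   `sigma_t^2 = beta_t`, `"posterior"` the forward-posterior variance
#'   `beta_t (1 - alpha_bar_{t-1}) / (1 - alpha_bar_t)`; both are standard.
#' @param quiet suppress the note about modalities without prompts.
#' @return list with `gtvp`, `gtvnd` ([label_mask]s), and `continuous`
#'   (the raw two-channel output array).
#' @export
sample_conditional <- function(model, ct, prompts = NULL, lambda = NULL,
                               seed = 1, inject = c("noise", "xt"),
                               variance = c("beta", "posterior"),
                               quiet = FALSE) {
  if (!inherits(model, "ddpm")) stop("model must be a trained ddpm")
  inject <- match.arg(inject)
  variance <- match.arg(variance)
  sched <- model$schedule
  ctarr <- if (inherits(ct, "volume3d")) ct$data else ct
  d <- dim(ctarr)
  if (!identical(as.integer(d), model$spec$in_shape))
    stop("CT grid does not match the trained model")
  if (is.null(lambda)) lambda <- if (is.null(prompts)) 0 else prompts$lambda
  if (!is.null(prompts)) {
    for (m in names(prompts$images))
      if (!identical(dim(prompts$images[[m]]), d[1:2]))
        stop("prompt image shape mismatch for ", m)
    missing_m <- setdiff(sched$windows$modality, names(prompts$images))
    if (length(missing_m) && !quiet)
      message("no prompt for ", paste(missing_m, collapse = ", "),
              "; those windows run unprompted")
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  x <- array(stats::rnorm(prod(d) * 2), c(d, 2))
  spacing <- if (inherits(ct, "volume3d")) ct$spacing else c(1, 1, 1)
  for (s in seq_len(sched$T)) {
    t <- sched$T - s + 1L
    eps_hat <- unet_forward(model$params, x, ctarr, t, sched$T, model$spec)$eps
    beta_t <- sched$beta[t]
    ab <- sched$alpha_bar[t]
    mean_x <- (x - beta_t / sqrt(1 - ab) * eps_hat) / sqrt(1 - beta_t)
    pimg <- NULL
    if (lambda > 0 && !is.null(prompts)) {
      m <- window_modality(sched, s)
      if (!is.null(prompts$images[[m]]))
        pimg <- lambda * prompts$signs[[m]] * prompts$images[[m]]
    }
    if (t > 1L) {
      sig2 <- if (variance == "beta") beta_t
              else beta_t * (1 - sched$alpha_bar[t - 1]) / (1 - ab)
      z <- array(stats::rnorm(prod(d) * 2), c(d, 2))
      if (!is.null(pimg) && inject == "noise")
        z[, , , 1] <- z[, , , 1] + array(pimg, d)
      x <- mean_x + sqrt(sig2) * z
    } else x <- mean_x
    if (!is.null(pimg) && inject == "xt")
      x[, , , 1] <- x[, , , 1] + array(pimg, d)
  }
  c1 <- x[, , , 1]; c2 <- x[, , , 2]
  fg1 <- c1 > 0; fg2 <- c2 > 0
  gtvp <- fg1 & (!fg2 | c1 >= c2)
  gtvnd <- fg2 & !gtvp
  list(gtvp = label_mask(array(as.integer(gtvp), d), spacing, "GTVp"),
       gtvnd = label_mask(array(as.integer(gtvnd), d), spacing, "GTVnd"),
       continuous = x)
}

#' Draw segmentation samples from a trained diffusion model
#'
#' @param object a `ddpm` model.
#' @param nsim number of samples.
#' @param seed base seed; sample `k` uses `seed + k - 1`.
#' @param ct source CT volume.
#' @param prompts optional [prompt_set()].
#' @param ... passed to [sample_conditional()].
#' @return list of `nsim` sample lists.
#' @export
simulate.ddpm <- function(object, nsim = 1, seed = 1, ct, prompts = NULL, ...) {
  lapply(seq_len(nsim) - 1L, function(k)
    sample_conditional(object, ct, prompts, seed = seed + k, quiet = TRUE, ...))
}

#' Modality-ablation experiment over prompt configurations
#'
#' Mirrors the step-wise prompting ablation: sampling is repeated with only
#' the listed modalities' windows prompted (none, then T1-ce, then
#' T1-ce+T2, then all three by default), and GTVp segmentation quality is
#' scored against the reference masks.
#'
#' @param cases list of `case_bundle`s on the model grid.
#' @param prompt_sets list (parallel to `cases`) of full [prompt_set()]s.
#' @param model trained `ddpm`.
#' @param configs list of character vectors, each a subset of
#'   `c("t1ce", "t2", "ct")` (empty = unprompted).
#' @param seeds integer vector of sampling seeds per case/config.
#' @param lambda prompt strength.
#' @param ... further arguments passed to [sample_conditional()].
#' @return data frame with one row per configuration x case: mean GTVp
#'   DSC/ASSD/HD95 over the seeds (surface metrics `NA` when a prediction
#'   is empty) and mean GTVnd DSC.
#' @export
ablation_run <- function(cases, prompt_sets, model,
                         configs = list(character(0), "t1ce",
                                        c("t1ce", "t2"),
                                        c("t1ce", "t2", "ct")),
                         seeds = 1:5, lambda = 0.5, ...) {
  rows <- list()
  for (cfg_i in seq_along(configs)) {
    cfg <- configs[[cfg_i]]
    cfg_name <- if (length(cfg)) paste(cfg, collapse = "+") else "none"
    for (ci in seq_along(cases)) {
      ps <- prompt_sets[[ci]]
      sub <- if (length(cfg)) {
        structure(list(images = ps$images[intersect(cfg, names(ps$images))],
                       lambda = lambda, signs = ps$signs),
                  class = "prompt_set")
      } else NULL
      dscs <- dsc_nd <- assds <- hds <- numeric(length(seeds))
      for (si in seq_along(seeds)) {
        sm <- sample_conditional(model, cases[[ci]]$ct, sub, lambda = lambda,
                                 seed = seeds[si], quiet = TRUE, ...)
        dscs[si] <- dsc(sm$gtvp, cases[[ci]]$gtvp)
        dsc_nd[si] <- dsc(sm$gtvnd, cases[[ci]]$gtvnd)
        sd_ok <- sum(sm$gtvp$data) > 0 && sum(cases[[ci]]$gtvp$data) > 0
        assds[si] <- if (sd_ok) assd(sm$gtvp, cases[[ci]]$gtvp) else NA_real_
        hds[si] <- if (sd_ok) hd95(sm$gtvp, cases[[ci]]$gtvp) else NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        config = cfg_name, case = ci, n_seeds = length(seeds),
        dsc_gtvp = mean(dscs), dsc_gtvnd = mean(dsc_nd),
        assd_gtvp = mean(assds, na.rm = TRUE),
        hd95_gtvp = mean(hds, na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Save / load a trained diffusion model
#'
#' Weights go to an RDS file; a JSON sidecar records the schedule, the
#' architecture and the training seed.
#'
#' @param model a `ddpm`.
#' @param path base path; writes `<path>.rds` and `<path>.json`.
#' @return base path (write) or the model (read).
#' @export
write_ddpm <- function(model, path) {
  saveRDS(model, paste0(path, ".rds"))
  jsonlite::write_json(list(
    T = model$schedule$T, beta_range = range(model$schedule$beta),
    windows = model$schedule$windows, base_channels = model$spec$base_channels,
    in_shape = model$spec$in_shape, epochs = model$epochs, seed = model$seed),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ddpm
#' @export
read_ddpm <- function(path) readRDS(paste0(path, ".rds"))
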