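# Relation-encoding denoiser: a small 3D U-Net (one down/up level) whose
# input is the noisy two-channel mask concatenated with the source CT, with
# an additional CT feature branch added at the bottleneck and a sinusoidal
# time embedding projected to per-channel biases. All convolutions are
# 3x3x3 same-padded (im2col + GEMM in C++); pooling is 2x average,
# upsampling nearest-neighbour.

relu <- function(x) { x[x < 0] <- 0; x }

avgpool2 <- function(x) {
  d <- dim(x)
  o1 <- seq(1, d[1], 2); o2 <- seq(1, d[2], 2); o3 <- seq(1, d[3], 2)
  (x[o1, o2, o3, , drop = FALSE] + x[o1 + 1, o2, o3, , drop = FALSE] +
   x[o1, o2 + 1, o3, , drop = FALSE] + x[o1 + 1, o2 + 1, o3, , drop = FALSE] +
   x[o1, o2, o3 + 1, , drop = FALSE] + x[o1 + 1, o2, o3 + 1, , drop = FALSE] +
   x[o1, o2 + 1, o3 + 1, , drop = FALSE] +
   x[o1 + 1, o2 + 1, o3 + 1, , drop = FALSE]) / 8
}

upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2),
    rep(seq_len(d[3]), each = 2), , drop = FALSE]
}

# adjoints: average-pool spreads gradient evenly; nearest upsample sums
avgpool2_bwd <- function(dy) upsample2(dy) / 8
upsample2_bwd <- function(dy) avgpool2(dy) * 8

time_embed <- function(t, T, n_freq = 8) {
  ang <- 2 * pi * seq_len(n_freq) * t / T
  c(sin(ang), cos(ang))
}

# broadcast a per-channel bias vector over all voxels of a 4D tensor
add_chan_bias <- function(x, bias) {
  d <- dim(x)
  x + array(rep(bias, each = prod(d[1:3])), d)
}

chan_sum <- function(dy) {
  d <- dim(dy)
  colSums(matrix(dy, prod(d[1:3]), d[4]))
}

#' Denoiser architecture specification
#'
#' @param base_channels channels at full resolution (the bottleneck uses
#'   twice as many).
#' @param depth number of down/up levels; this implementation realizes one.
#' @param conditioning conditioning pathway; `"REB_CONCAT"` concatenates
#'   the CT as an input channel and adds a CT feature branch at the
#'   bottleneck.
#' @param in_shape integer triple; every axis must be divisible by
#'   `2^depth`.
#' @return an object of class `denoiser_spec`.
#' @export
denoiser_spec <- function(base_channels = 8, depth = 1,
                          conditioning = "REB_CONCAT",
                          in_shape = c(32, 32, 8)) {
  if (depth != 1)
    stop("this denoiser realizes depth = 1 (one down/up level)")
  in_shape <- as.integer(in_shape)
  if (any(in_shape %% 2L^depth != 0L))
    stop("in_shape must be divisible by 2^depth per axis")
  if (!identical(conditioning, "REB_CONCAT"))
    stop("unsupported conditioning: ", conditioning)
  structure(list(base_channels = as.integer(base_channels), depth = depth,
                 conditioning = conditioning, in_shape = in_shape,
                 n_freq = 8L),
            class = "denoiser_spec")
}

unet_init <- function(spec, seed = 1) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  C <- spec$base_channels; E <- 2L * spec$n_freq
  he <- function(k_in, k_out)
    matrix(stats::rnorm(k_in * k_out, 0, sqrt(2 / k_in)), k_in, k_out)
  list(W_in = he(27 * 3, C), b_in = numeric(C), Wt1 = he(E, C) * 0.1,
       W_ct = he(27 * 1, 2 * C), b_ct = numeric(2 * C),
       W_m1 = he(27 * C, 2 * C), b_m1 = numeric(2 * C), Wt2 = he(E, 2 * C) * 0.1,
       W_m2 = he(27 * 2 * C, 2 * C), b_m2 = numeric(2 * C),
       W_up = he(27 * 2 * C, C), b_up = numeric(C),
       W_out = he(27 * C, 2) * 0.1, b_out = numeric(2))
}

unet_forward <- function(params, xt, ct, t, T, spec, keep_cache = FALSE) {
  d <- dim(xt)[1:3]
  inp <- array(0, c(d, 3))
  inp[, , , 1:2] <- xt
  inp[, , , 3] <- ct
  tfeat <- time_embed(t, T, spec$n_freq)
  pre0 <- conv3d_forward_cpp(inp, dim(inp), params$W_in, params$b_in)
  pre0 <- add_chan_bias(pre0, drop(tfeat %*% params$Wt1))
  h0 <- relu(pre0)
  p1 <- avgpool2(h0)
  ctp <- avgpool2(array(ct, c(d, 1)))
  ctf <- conv3d_forward_cpp(ctp, dim(ctp), params$W_ct, params$b_ct)
  pre1 <- conv3d_forward_cpp(p1, dim(p1), params$W_m1, params$b_m1) + ctf
  pre1 <- add_chan_bias(pre1, drop(tfeat %*% params$Wt2))
  h1 <- relu(pre1)
  pre2 <- conv3d_forward_cpp(h1, dim(h1), params$W_m2, params$b_m2)
  h2 <- relu(pre2)
  # up-convolution at the coarse level, then nearest-neighbour upsampling
  # (ReLU commutes with nearest upsampling, and the conv is 8x cheaper)
  pre3 <- conv3d_forward_cpp(h2, dim(h2), params$W_up, params$b_up)
  h3 <- upsample2(relu(pre3))
  h4 <- h3 + h0
  eps <- conv3d_forward_cpp(h4, dim(h4), params$W_out, params$b_out)
  if (!keep_cache) return(list(eps = eps))
  list(eps = eps, cache = list(inp = inp, tfeat = tfeat, pre0 = pre0,
       h0 = h0, p1 = p1, ctp = ctp, pre1 = pre1, h1 = h1, pre2 = pre2,
       h2 = h2, pre3 = pre3, h4 = h4))
}

unet_backward <- function(params, cache, deps) {
  bk_out <- conv3d_backward_cpp(cache$h4, dim(cache$h4), params$W_out, deps)
  dh4 <- bk_out$dx
  dpre3 <- upsample2_bwd(dh4) * (cache$pre3 > 0)
  bk_up <- conv3d_backward_cpp(cache$h2, dim(cache$h2), params$W_up, dpre3)
  dh2 <- bk_up$dx
  dpre2 <- dh2 * (cache$pre2 > 0)
  bk_m2 <- conv3d_backward_cpp(cache$h1, dim(cache$h1), params$W_m2, dpre2)
  dpre1 <- bk_m2$dx * (cache$pre1 > 0)
  bk_m1 <- conv3d_backward_cpp(cache$p1, dim(cache$p1), params$W_m1, dpre1)
  bk_ct <- conv3d_backward_cpp(cache$ctp, dim(cache$ctp), params$W_ct, dpre1)
  dWt2 <- cache$tfeat %o% chan_sum(dpre1)
  dh0 <- avgpool2_bwd(bk_m1$dx) + dh4
  dpre0 <- dh0 * (cache$pre0 > 0)
  bk_in <- conv3d_backward_cpp(cache$inp, dim(cache$inp), params$W_in, dpre0)
  dWt1 <- cache$tfeat %o% chan_sum(dpre0)
  list(W_in = bk_in$dW, b_in = bk_in$db, Wt1 = dWt1,
       W_ct = bk_ct$dW, b_ct = bk_ct$db,
       W_m1 = bk_m1$dW, b_m1 = bk_m1$db, Wt2 = dWt2,
       W_m2 = bk_m2$dW, b_m2 = bk_m2$db,
       W_up = bk_up$dW, b_up = bk_up$db,
       W_out = bk_out$dW, b_out = bk_out$db)
}

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (k in names(params)) {
    state$m[[k]] <- b1 * state$m[[k]] + (1 - b1) * grads[[k]]
    state$v[[k]] <- b2 * state$v[[k]] + (1 - b2) * grads[[k]]^2
    mh <- state$m[[k]] / (1 - b1^state$t)
    vh <- state$v[[k]] / (1 - b2^state$t)
    params[[k]] <- params[[k]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

# --- small learned decoder for gsfit: a 2-layer convolutional refiner that
# maps the analytic render towards the target (residual form) -------------

train_decoder <- function(fit, iterations = 60, lr = 1e-2, seed = 1,
                          channels = 4) {
  render <- predict(fit, type = "analytic")$data
  target <- fit$target$data
  d <- dim(render)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  he <- function(k_in, k_out)
    matrix(stats::rnorm(k_in * k_out, 0, sqrt(2 / k_in)), k_in, k_out)
  params <- list(W1 = he(27, channels), b1 = numeric(channels),
                 W2 = he(27 * channels, 1) * 0.1, b2 = numeric(1))
  st <- adam_state(params)
  x <- array(render, c(d, 1))
  for (it in seq_len(iterations)) {
    pre <- conv3d_forward_cpp(x, dim(x), params$W1, params$b1)
    h <- relu(pre)
    out <- render + drop(conv3d_forward_cpp(h, dim(h), params$W2, params$b2))
    dout <- array(2 * (out - target) / length(target), c(d, 1))
    bk2 <- conv3d_backward_cpp(h, dim(h), params$W2, dout)
    dpre <- bk2$dx * (pre > 0)
    bk1 <- conv3d_backward_cpp(x, dim(x), params$W1, dpre)
    upd <- adam_step(params, list(W1 = bk1$dW, b1 = bk1$db,
                                  W2 = bk2$dW, b2 = bk2$db), st, lr)
    params <- upd$params; st <- upd$state
  }
  list(params = params, channels = channels)
}

decoder_apply <- function(decoder, render) {
  d <- dim(render)
  x <- array(render, c(d, 1))
  pre <- conv3d_forward_cpp(x, dim(x), decoder$params$W1, decoder$params$b1)
  h <- relu(pre)
  render + drop(conv3d_forward_cpp(h, dim(h), decoder$params$W2,
                                   decoder$params$b2))
}
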