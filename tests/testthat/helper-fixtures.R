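# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# default-scale phantom (64x64x16), memoised by seed
phantom64 <- function(seed = 1) {
  key <- paste0("p64_", seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generate_case(phantom_config(seed = seed))
  .fixtures[[key]]
}

# small training-scale phantom (32x32x8)
phantom32 <- function(seed = 1) {
  key <- paste0("p32_", seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generate_case(
      phantom_config(grid_shape = c(32, 32, 8), tumor_radius_range = c(3, 5),
                     seed = seed))
  .fixtures[[key]]
}

# random SPD-parameterized gaussian point
random_point <- function(dims = c(16, 16, 16)) {
  gaussian_point(runif(3, 4, dims - 3), runif(3, 0.6, 2.5), rnorm(4),
                 runif(1, 0.2, 1))
}

# independent quadratic-form oracle for eval_point: builds the rotation by
# quaternion-vector conjugation (q v q*) rather than the matrix formula,
# and evaluates the exponent through an explicit inverse
oracle_eval <- function(x, mu, scale, q, intensity) {
  q <- q / sqrt(sum(q^2))
  rot_vec <- function(v) {
    w <- q[1]; u <- q[2:4]
    v + 2 * pracma::cross(u, pracma::cross(u, v) + w * v)
  }
  R <- sapply(list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)), rot_vec)
  S <- R %*% diag(scale^2) %*% t(R)
  d <- x - mu
  intensity * exp(-0.5 * drop(t(d) %*% solve(S) %*% d))
}

# brute-force all-pairs surface-distance oracle (slow, small masks only)
oracle_surface_metrics <- function(pred, ref, spacing = c(1, 1, 1)) {
  surf <- function(m) {
    d <- dim(m)
    out <- NULL
    for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
      if (m[x, y, z] != 1) next
      nb <- c(
        if (x > 1) m[x - 1, y, z] else 0, if (x < d[1]) m[x + 1, y, z] else 0,
        if (y > 1) m[x, y - 1, z] else 0, if (y < d[2]) m[x, y + 1, z] else 0,
        if (z > 1) m[x, y, z - 1] else 0, if (z < d[3]) m[x, y, z + 1] else 0)
      if (length(nb) < 6 || any(nb == 0)) out <- rbind(out, c(x, y, z))
    }
    out
  }
  sp <- sweep(surf(pred), 2, spacing, `*`)
  sr <- sweep(surf(ref), 2, spacing, `*`)
  d_ab <- apply(sp, 1, function(p) min(sqrt(colSums((t(sr) - p)^2))))
  d_ba <- apply(sr, 1, function(p) min(sqrt(colSums((t(sp) - p)^2))))
  list(assd = mean(c(d_ab, d_ba)),
       hd95 = max(quantile(d_ab, 0.95, names = FALSE),
                  quantile(d_ba, 0.95, names = FALSE)),
       hd = max(c(d_ab, d_ba)))
}

# random small blob mask for metric oracle comparisons; `clearance` keeps
# the blob away from the grid border (for translation tests)
random_blob_mask <- function(dims = c(12, 12, 6), clearance = 0) {
  repeat {
    rad <- runif(3, 1.0, pmin(2.4, (dims - 2 - 2 * clearance) / 2 - 0.1))
    ctr <- runif(3, rad + 1 + clearance, dims - rad - 1 - clearance)
    g <- expand.grid(x = 1:dims[1], y = 1:dims[2], z = 1:dims[3])
    q <- ((g$x - ctr[1]) / rad[1])^2 + ((g$y - ctr[2]) / rad[2])^2 +
         ((g$z - ctr[3]) / rad[3])^2
    m <- array(as.integer(q <= 1), dims)
    if (sum(m) > 0) return(label_mask(m))
  }
}
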