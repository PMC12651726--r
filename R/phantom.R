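#' Configuration for the synthetic multimodal head phantom
#'
#' The phantom emulates the three modality contrasts the segmentation
#' method exploits: a combined hyperintense cancer+vessel region on
#' contrast-enhanced T1 MRI, persistent vessel hyperintensity with
#' heterogeneous (bimodal) tumor signal on T2 MRI, and high-contrast bone
#' on CT with reduced intensity where the tumor destroys bone.
#'
#' @param grid_shape integer triple, voxels per axis (all >= 8).
#' @param spacing positive numeric triple, voxel spacing in mm.
#' @param n_vessels non-negative integer, number of vessel tubes.
#' @param tumor_radius_range positive pair, primary-tumor ellipsoid radius
#'   range in voxels (in-plane; the z radius is capped to fit the grid).
#' @param bone_thickness positive integer, skull-base shell thickness (voxels).
#' @param noise_sigma non-negative scalar, additive Gaussian image noise in
#'   post-normalization units.
#' @param bone_destruction_factor CT intensity multiplier (< 1) applied to
#'   bone invaded by tumor.
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(64, 64, 16), spacing = c(1, 1, 1),
                           n_vessels = 3, tumor_radius_range = c(4, 7),
                           bone_thickness = 2, noise_sigma = 0.02,
                           bone_destruction_factor = 0.4, seed = 1) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    stop("grid_shape must be a triple with all components >= 8")
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (n_vessels < 0) stop("n_vessels must be non-negative")
  tumor_radius_range <- sort(as.numeric(tumor_radius_range))
  if (any(tumor_radius_range <= 0)) stop("tumor radii must be positive")
  if (2 * tumor_radius_range[2] >= min(grid_shape[1:2]))
    stop("config infeasible: tumor (max radius ", tumor_radius_range[2],
         " voxels) cannot fit inside grid ",
         paste(grid_shape, collapse = "x"))
  if (bone_thickness < 1) stop("bone_thickness must be >= 1")
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  structure(list(grid_shape = grid_shape, spacing = as.numeric(spacing),
                 n_vessels = as.integer(n_vessels),
                 tumor_radius_range = tumor_radius_range,
                 bone_thickness = as.integer(bone_thickness),
                 noise_sigma = noise_sigma,
                 bone_destruction_factor = bone_destruction_factor,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# axis-aligned ellipsoid rasterized at voxel centres
rasterize_ellipsoid <- function(dims, center, radii) {
  g <- voxel_grid(dims)
  q <- ((g[, 1] - center[1]) / radii[1])^2 +
       ((g[, 2] - center[2]) / radii[2])^2 +
       ((g[, 3] - center[3]) / radii[3])^2
  array(as.integer(q <= 1), dim = dims)
}

# 3x3x3 box blur with edge replication
box_blur3 <- function(arr) {
  d <- dim(arr)
  out <- array(0, d); cnt <- 0
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    ix <- pmin(pmax(seq_len(d[1]) + dx, 1), d[1])
    iy <- pmin(pmax(seq_len(d[2]) + dy, 1), d[2])
    iz <- pmin(pmax(seq_len(d[3]) + dz, 1), d[3])
    out <- out + arr[ix, iy, iz]
    cnt <- cnt + 1
  }
  out / cnt
}

#' Generate one synthetic multimodal head phantom case
#'
#' Builds a head ellipsoid in air, a partial cylindrical "skull base" bone
#' shell, a primary tumor (GTVp) ellipsoid overlapping the bone, a separate
#' nodal lesion (GTVnd) away from bone, and vessel tubes, then synthesizes
#' CT (Hounsfield units, clipped and scaled), T1-ce and T2 volumes through
#' the preprocessing contract so all intensities end in [0, 1].
#'
#' @param config a [phantom_config].
#' @param seed optional integer overriding `config$seed`.
#' @return an object of class `case_bundle`: volumes `ct`, `t1ce`, `t2`,
#'   masks `gtvp`, `gtvnd`, `vessel_truth`, `bone_truth`, plus `spacing`,
#'   `seed` and a `meta` list with the generating geometry and contrast
#'   levels.
#' @export
generate_case <- function(config, seed = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  d <- config$grid_shape
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  ctr <- (d + 1) / 2
  head_radii <- c(0.46 * d[1], 0.46 * d[2], 0.62 * d[3])
  head <- rasterize_ellipsoid(d, ctr, head_radii)

  # skull base: posterior partial cylindrical shell around the z axis
  rb <- 0.32 * min(d[1:2])
  g <- voxel_grid(d)
  rho <- sqrt((g[, 1] - ctr[1])^2 + (g[, 2] - ctr[2])^2)
  zlo <- max(1, round(0.2 * d[3])); zhi <- round(0.85 * d[3])
  bone <- array(as.integer(
    rho <= rb & rho >= rb - config$bone_thickness &
    g[, 2] >= ctr[2] & g[, 3] >= zlo & g[, 3] <= zhi), dim = d)
  bone <- bone * head

  # GTVp: ellipsoid anchored near the nasopharynx, reaching into the shell
  rr <- config$tumor_radius_range
  rx <- runif(1, rr[1], rr[2]); ry <- runif(1, rr[1], rr[2])
  rz <- min(runif(1, rr[1], rr[2]), 0.35 * d[3])
  theta <- runif(1, 70, 110) * pi / 180          # posterior sector
  dist <- rb - 0.5 * mean(c(rx, ry))
  tc <- c(ctr[1] + dist * cos(theta), ctr[2] + dist * sin(theta),
          ctr[3] + runif(1, -1, 1))
  tc[1] <- min(max(tc[1], rx + 2), d[1] - rx - 1)
  tc[2] <- min(max(tc[2], ry + 2), d[2] - ry - 1)
  tc[3] <- min(max(tc[3], rz + 1), d[3] - rz)
  gtvp <- rasterize_ellipsoid(d, tc, c(rx, ry, rz))

  # GTVnd: smaller "lymph node", anterolateral, away from the bone shell
  nr <- pmax(0.6 * c(rx, ry, rz), c(2, 2, 1.5))
  side <- sample(c(-1, 1), 1)
  nc <- c(ctr[1] + side * 0.27 * d[1], ctr[2] - 0.2 * d[2],
          ctr[3] + runif(1, -1, 1))
  nc[3] <- min(max(nc[3], nr[3] + 1), d[3] - nr[3])
  gtvnd <- rasterize_ellipsoid(d, nc, nr) * head
  gtvnd[gtvp == 1] <- 0L                          # disjoint labels

  # vessels: near-vertical tubes with a slight tilt, excluded from GTV
  vessel <- array(0L, d)
  if (config$n_vessels > 0) {
    for (v in seq_len(config$n_vessels)) {
      vr <- runif(1, 1, 2)
      bx <- ctr[1] + sample(c(-1, 1), 1) * runif(1, 0.12, 0.3) * d[1]
      by <- ctr[2] + runif(1, -0.1, 0.25) * d[2]
      tilt <- runif(2, -0.4, 0.4)
      for (z in seq_len(d[3])) {
        cx <- bx + tilt[1] * (z - 1); cy <- by + tilt[2] * (z - 1)
        sel <- (g[, 3] == z) &
               ((g[, 1] - cx)^2 + (g[, 2] - cy)^2 <= vr^2)
        vessel[sel] <- 1L
      }
    }
    vessel <- vessel * head
    vessel[gtvp == 1 | gtvnd == 1] <- 0L
  }

  lv <- list(air = 0.02, tissue = 0.30, enhanced = 0.85, enhanced_in_bone = 0.62,
             node_t1ce = 0.40, vessel_t2 = 0.90, tumor_t2_lo = 0.35,
             tumor_t2_hi = 0.75, node_t2 = 0.60,
             hu_tissue = 0, hu_tumor = 40, hu_bone = 1100)

  # CT in HU -> clip -> [0,1]; air and clipped cortical bone pin the scale
  hu <- array(-1000, d)
  hu[head == 1] <- lv$hu_tissue
  hu[gtvp == 1 | gtvnd == 1] <- lv$hu_tumor
  hu[bone == 1] <- lv$hu_bone
  destroyed <- bone == 1 & gtvp == 1
  hu[destroyed] <- lv$hu_bone * config$bone_destruction_factor
  ct <- clip_hu(volume3d(hu, config$spacing, modality = "CT"))
  ct <- normalize_volume(ct, fit_scaling(list(ct)))

  # T1-ce in arbitrary scanner units: tumor + vessels enhanced; the
  # bone-invaded tumor portion enhances more weakly (tumor within bone
  # matrix), so its full extent is a CT-specific finding
  t1 <- array(lv$air, d)
  t1[head == 1] <- lv$tissue
  t1[gtvnd == 1] <- lv$node_t1ce
  t1[gtvp == 1 | vessel == 1] <- lv$enhanced
  t1[destroyed] <- lv$enhanced_in_bone

  # T2: vessels uniformly bright; tumor signal bimodal via smoothed noise
  t2 <- array(lv$air, d)
  t2[head == 1] <- lv$tissue
  t2[gtvnd == 1] <- lv$node_t2
  mix <- box_blur3(array(runif(prod(d)), d))
  tmask <- gtvp == 1
  hi <- mix > stats::median(mix[tmask])
  t2[tmask & hi] <- lv$tumor_t2_hi
  t2[tmask & !hi] <- lv$tumor_t2_lo
  t2[vessel == 1] <- lv$vessel_t2

  add_noise <- function(a) {
    if (config$noise_sigma > 0)
      a <- a + array(stats::rnorm(prod(d), 0, config$noise_sigma), d)
    pmin(pmax(a, 0), 1)
  }
  mri_units <- function(a, mod) {   # arbitrary scanner units, renormalized
    v <- volume3d(a * 600 + 20, config$spacing, modality = mod)
    normalize_volume(v, fit_scaling(list(v)))
  }
  ct$data[] <- add_noise(ct$data)
  t1ce <- mri_units(t1, "T1CE"); t1ce$data[] <- add_noise(t1ce$data)
  t2v <- mri_units(t2, "T2");    t2v$data[]  <- add_noise(t2v$data)

  structure(list(
    ct = ct, t1ce = t1ce, t2 = t2v,
    gtvp = label_mask(gtvp, config$spacing, "GTVp"),
    gtvnd = label_mask(gtvnd, config$spacing, "GTVnd"),
    vessel_truth = label_mask(vessel, config$spacing, "vessels"),
    bone_truth = label_mask(bone, config$spacing, "bone"),
    spacing = config$spacing, seed = seed,
    meta = list(tumor_center = tc, tumor_radii = c(rx, ry, rz),
                node_center = nc, node_radii = nr, bone_radius = rb,
                levels = lv, config = config)),
    class = "case_bundle")
}

#' @export
print.case_bundle <- function(x, ...) {
  d <- dim(x$ct$data)
  cat(sprintf(
    "<case_bundle> %dx%dx%d, seed %d: GTVp %d vox, GTVnd %d vox, vessels %d vox, bone %d vox\n",
    d[1], d[2], d[3], x$seed, sum(x$gtvp$data), sum(x$gtvnd$data),
    sum(x$vessel_truth$data), sum(x$bone_truth$data)))
  invisible(x)
}

#' Generate a reproducible cohort of phantom cases
#'
#' Per-case seeds are drawn deterministically from `base_seed`, so the
#' cohort is reproducible while geometry varies across cases.
#'
#' @param config a [phantom_config].
#' @param n_cases positive integer.
#' @param base_seed integer.
#' @return list of [generate_case()] bundles.
#' @export
generate_cohort <- function(config, n_cases, base_seed = config$seed) {
  if (n_cases < 1) stop("n_cases must be >= 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(base_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_cases)
  lapply(seeds, function(s) generate_case(config, seed = s))
}

#' Contrast statistics of a phantom case
#'
#' Summarises the three modality-prior contrasts the generator encodes:
#' T1-ce enhancement margin of cancer+vessels over background, T2 variance
#' inside tumor vs inside vessels, and CT bone intensity in intact vs
#' tumor-invaded bone.
#'
#' @param bundle a `case_bundle`.
#' @return named numeric vector of contrast statistics.
#' @export
case_contrasts <- function(bundle) {
  enh <- bundle$gtvp$data == 1 | bundle$vessel_truth$data == 1
  bg <- !(enh | bundle$gtvnd$data == 1)
  tum <- bundle$gtvp$data == 1
  ves <- bundle$vessel_truth$data == 1
  intact <- bundle$bone_truth$data == 1 & bundle$gtvp$data == 0
  invaded <- bundle$bone_truth$data == 1 & bundle$gtvp$data == 1
  c(t1ce_margin = mean(bundle$t1ce$data[enh]) - mean(bundle$t1ce$data[bg]),
    t2_var_tumor = stats::var(bundle$t2$data[tum]),
    t2_var_vessel = if (any(ves)) stats::var(bundle$t2$data[ves]) else NA_real_,
    ct_bone_intact = mean(bundle$ct$data[intact]),
    ct_bone_invaded = if (any(invaded)) mean(bundle$ct$data[invaded]) else NA_real_)
}

#' Write a phantom case to a directory of NIfTI files
#'
#' @param bundle a `case_bundle`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_case <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(bundle$ct, file.path(dir, "ct.nii.gz"))
  write_volume(bundle$t1ce, file.path(dir, "t1ce.nii.gz"))
  write_volume(bundle$t2, file.path(dir, "t2.nii.gz"))
  write_volume(bundle$gtvp, file.path(dir, "gtvp.nii.gz"))
  write_volume(bundle$gtvnd, file.path(dir, "gtvnd.nii.gz"))
  write_volume(bundle$vessel_truth, file.path(dir, "vessels.nii.gz"))
  write_volume(bundle$bone_truth, file.path(dir, "bone.nii.gz"))
  invisible(dir)
}

#' Read a phantom case written by [write_case()]
#' @param dir case directory.
#' @return a `case_bundle` (without generator metadata).
#' @export
read_case <- function(dir) {
  structure(list(
    ct = read_volume(file.path(dir, "ct.nii.gz"), "CT"),
    t1ce = read_volume(file.path(dir, "t1ce.nii.gz"), "T1CE"),
    t2 = read_volume(file.path(dir, "t2.nii.gz"), "T2"),
    gtvp = read_volume(file.path(dir, "gtvp.nii.gz"), as_mask = TRUE, label = "GTVp"),
    gtvnd = read_volume(file.path(dir, "gtvnd.nii.gz"), as_mask = TRUE, label = "GTVnd"),
    vessel_truth = read_volume(file.path(dir, "vessels.nii.gz"), as_mask = TRUE, label = "vessels"),
    bone_truth = read_volume(file.path(dir, "bone.nii.gz"), as_mask = TRUE, label = "bone"),
    spacing = read_volume(file.path(dir, "ct.nii.gz"), "CT")$spacing,
    seed = NA_integer_, meta = NULL), class = "case_bundle")
}

# save/restore the global RNG state so seeded generators do not disturb
# the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
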