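#' Clip CT intensities to the Hounsfield window
#'
#' Values below -1000 HU or above +1000 HU are replaced by the respective
#' bound; shape and spacing are unchanged. Idempotent.
#'
#' @param volume a CT [volume3d] in Hounsfield units.
#' @param lo,hi clipping bounds (HU).
#' @return the clipped CT volume.
#' @export
clip_hu <- function(volume, lo = -1000, hi = 1000) {
  if (!inherits(volume, "volume3d")) stop("`volume` must be a volume3d")
  if (volume$modality != "CT")
    stop("clip_hu expects a CT volume, got modality ", volume$modality)
  volume$data[] <- pmin(pmax(volume$data, lo), hi)
  volume
}

#' Fit intensity scaling factors over a cohort
#'
#' CT scaling uses the pooled min/max over all CT volumes in the cohort
#' (which should already be HU-clipped); MRI scaling uses a min/max per
#' imaging series. By default a series is a modality pooled over the cohort
#' (`per_case = FALSE`); with `per_case = TRUE` each volume is its own
#' series, keyed `"<modality>.<index>"`.
#'
#' @param cohort list of [volume3d] objects.
#' @param per_case logical; fit MRI min/max per individual volume.
#' @return an object of class `scaling_factors` with elements `ct`
#'   (numeric `c(min, max)` or `NULL`) and `series` (named list of
#'   `c(min, max)`).
#' @export
fit_scaling <- function(cohort, per_case = FALSE) {
  if (length(cohort) == 0) stop("cohort is empty")
  is_ct <- vapply(cohort, function(v) v$modality == "CT", logical(1))
  ct <- NULL
  if (any(is_ct)) {
    vals <- range(unlist(lapply(cohort[is_ct], function(v) range(v$data))))
    if (diff(vals) <= 0)
      stop("constant CT cohort (max == min); cannot fit scaling")
    ct <- vals
  }
  series <- list()
  mri <- cohort[!is_ct]
  if (length(mri)) {
    keys <- vapply(seq_along(mri), function(i) {
      if (per_case) paste0(mri[[i]]$modality, ".", i) else mri[[i]]$modality
    }, character(1))
    for (k in unique(keys)) {
      vals <- range(unlist(lapply(mri[keys == k], function(v) range(v$data))))
      if (diff(vals) <= 0)
        stop("constant series '", k, "' (max == min); cannot fit scaling")
      series[[k]] <- vals
    }
  }
  structure(list(ct = ct, series = series, per_case = per_case),
            class = "scaling_factors")
}

#' @export
print.scaling_factors <- function(x, ...) {
  cat("<scaling_factors>\n")
  if (!is.null(x$ct))
    cat(sprintf("  CT: [%.4g, %.4g]\n", x$ct[1], x$ct[2]))
  for (k in names(x$series))
    cat(sprintf("  %s: [%.4g, %.4g]\n", k, x$series[[k]][1], x$series[[k]][2]))
  invisible(x)
}

#' Scale a volume to [0, 1] with fitted factors
#'
#' Applies `v -> (v - min) / (max - min)` with the CT or series min/max
#' stored in `factors`, then clamps to `[0, 1]` (values beyond the fitted
#' range at inference are clipped).
#'
#' @param volume a [volume3d].
#' @param factors a `scaling_factors` object from [fit_scaling()].
#' @param series series key for MRI volumes; defaults to the modality.
#' @return the normalized volume, values in `[0, 1]`.
#' @export
normalize_volume <- function(volume, factors, series = NULL) {
  if (!inherits(factors, "scaling_factors")) stop("`factors` not fitted")
  if (volume$modality == "CT") {
    if (is.null(factors$ct)) stop("no CT scaling fitted")
    mm <- factors$ct
  } else {
    key <- if (is.null(series)) volume$modality else series
    if (is.null(factors$series[[key]]))
      stop("unknown series '", key, "' in scaling factors")
    mm <- factors$series[[key]]
  }
  volume$data[] <- pmin(pmax((volume$data - mm[1]) / (mm[2] - mm[1]), 0), 1)
  volume
}

#' Serialize / restore scaling factors as JSON
#' @param factors a `scaling_factors` object.
#' @param path file path.
#' @return `path` (write) or the restored object (read).
#' @export
write_scaling <- function(factors, path) {
  jsonlite::write_json(unclass(factors), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scaling
#' @export
read_scaling <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$ct <- if (length(x$ct)) as.numeric(x$ct) else NULL
  x$series <- lapply(as.list(x$series), as.numeric)
  structure(x, class = "scaling_factors")
}

#' Resample a volume or mask to isotropic spacing
#'
#' Images are interpolated trilinearly; masks use nearest-neighbour so the
#' label set is preserved. The output grid covers the same physical extent:
#' new dimension `round(dim * spacing / target)` per axis (minimum 1), with
#' voxel centres aligned so the first voxel centre maps to the first input
#' voxel centre.
#'
#' @param x a [volume3d] or [label_mask].
#' @param target_spacing positive scalar, target isotropic spacing (mm).
#' @return resampled object of the same class.
#' @export
resample_isotropic <- function(x, target_spacing = 1) {
  if (!is.numeric(target_spacing) || target_spacing <= 0)
    stop("target spacing must be positive")
  is_mask <- inherits(x, "label_mask")
  arr <- if (is_mask) x$data else x$data
  d <- dim(arr)
  newd <- pmax(1L, as.integer(round(d * x$spacing / target_spacing)))
  # source (fractional, 1-based) coordinates of each output voxel centre
  src <- lapply(1:3, function(a) 1 + (seq_len(newd[a]) - 1) * target_spacing / x$spacing[a])
  if (is_mask) {
    idx <- lapply(1:3, function(a) pmin(pmax(round(src[[a]]), 1L), d[a]))
    out <- arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    dim(out) <- newd
    return(label_mask(out, rep(target_spacing, 3), x$label))
  }
  out <- trilinear_resample(arr, src[[1]], src[[2]], src[[3]])
  volume3d(out, rep(target_spacing, 3), x$origin, x$modality)
}

# separable trilinear interpolation at a tensor-product grid of fractional
# source coordinates (clamped to the array bounds)
trilinear_resample <- function(arr, sx, sy, sz) {
  d <- dim(arr)
  interp_axis <- function(a, s, dn) {
    s <- pmin(pmax(s, 1), dn)
    i0 <- pmin(floor(s), dn - ifelse(dn > 1, 1, 0))
    w <- s - i0
    list(lo = as.integer(i0), hi = as.integer(pmin(i0 + 1, dn)), w = w)
  }
  ax <- interp_axis(1, sx, d[1]); ay <- interp_axis(2, sy, d[2])
  az <- interp_axis(3, sz, d[3])
  # interpolate axis by axis
  a1 <- arr[ax$lo, , , drop = FALSE] * (1 - ax$w) +
        arr[ax$hi, , , drop = FALSE] * ax$w
  wy <- rep(ay$w, each = length(sx))
  a2 <- a1[, ay$lo, , drop = FALSE] * (1 - wy) +
        a1[, ay$hi, , drop = FALSE] * wy
  wz <- rep(az$w, each = length(sx) * length(sy))
  a3 <- a2[, , az$lo, drop = FALSE] * (1 - wz) +
        a2[, , az$hi, drop = FALSE] * wz
  dim(a3) <- c(length(sx), length(sy), length(sz))
  a3
}
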