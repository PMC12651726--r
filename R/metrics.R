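#' Dice similarity coefficient
#'
#' `2|P ∩ R| / (|P| + |R|)`. When both masks are empty the agreement is
#' perfect by convention and 1 is returned (with a message), avoiding
#' silent NaN propagation in cohort averages.
#'
#' @param pred,ref [label_mask]s on the same grid.
#' @return scalar in `[0, 1]`.
#' @export
dsc <- function(pred, ref) {
  stop_if_grid_mismatch(pred, ref)
  np <- sum(pred$data); nr <- sum(ref$data)
  if (np + nr == 0) {
    message("both masks empty: DSC defined as 1")
    return(1)
  }
  2 * sum(pred$data == 1L & ref$data == 1L) / (np + nr)
}

# surface voxels: foreground with at least one background 6-neighbour,
# the grid border counting as background
surface_voxels <- function(mask) {
  d <- dim(mask$data)
  pad <- array(0L, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask$data
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  nb_min <- pmin(
    pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)],
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)],
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)],
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)],
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]],
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)])
  which(core == 1L & nb_min == 0L, arr.ind = FALSE)
}

idx_to_mm <- function(idx, dims, spacing) {
  z <- (idx - 1L) %/% (dims[1] * dims[2]) + 1L
  y <- ((idx - 1L) %/% dims[1]) %% dims[2] + 1L
  x <- (idx - 1L) %% dims[1] + 1L
  cbind(x * spacing[1], y * spacing[2], z * spacing[3])
}

# chunked nearest-neighbour distances from each row of a to the set b (mm)
nearest_dists <- function(a, b, chunk = 512L) {
  out <- numeric(nrow(a))
  bb <- rowSums(b^2)
  for (i0 in seq(1L, nrow(a), by = chunk)) {
    ii <- i0:min(i0 + chunk - 1L, nrow(a))
    cross <- a[ii, , drop = FALSE] %*% t(b)
    d2 <- outer(rowSums(a[ii, , drop = FALSE]^2), bb, `+`) - 2 * cross
    out[ii] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Bidirectional surface distances between two masks
#'
#' Surface voxels are foreground voxels with at least one background
#' 6-neighbour (the grid border counts as background). Distances are
#' spacing-weighted Euclidean, voxel centre to voxel centre, from each
#' surface voxel of one mask to the nearest surface voxel of the other;
#' both directions are returned.
#'
#' @param pred,ref nonempty [label_mask]s on the same grid.
#' @param spacing voxel spacing (mm); defaults to the masks' spacing.
#' @return list with numeric vectors `pred_to_ref` and `ref_to_pred`.
#' @export
surface_distances <- function(pred, ref, spacing = pred$spacing) {
  stop_if_grid_mismatch(pred, ref)
  if (sum(pred$data) == 0 || sum(ref$data) == 0)
    stop("surface distances undefined for an empty mask")
  d <- dim(pred$data)
  sp <- idx_to_mm(surface_voxels(pred), d, spacing)
  sr <- idx_to_mm(surface_voxels(ref), d, spacing)
  list(pred_to_ref = nearest_dists(sp, sr),
       ref_to_pred = nearest_dists(sr, sp))
}

#' Average symmetric surface distance (mm)
#'
#' Mean of the pooled bidirectional surface-distance multiset.
#'
#' @inheritParams surface_distances
#' @return scalar distance in mm.
#' @export
assd <- function(pred, ref, spacing = pred$spacing) {
  sd <- surface_distances(pred, ref, spacing)
  mean(c(sd$pred_to_ref, sd$ref_to_pred))
}

#' 95th-percentile Hausdorff distance (mm)
#'
#' Maximum of the two directional 95th percentiles (linear-interpolation
#' percentile).
#'
#' @inheritParams surface_distances
#' @return scalar distance in mm.
#' @export
hd95 <- function(pred, ref, spacing = pred$spacing) {
  sd <- surface_distances(pred, ref, spacing)
  max(stats::quantile(sd$pred_to_ref, 0.95, names = FALSE, type = 7),
      stats::quantile(sd$ref_to_pred, 0.95, names = FALSE, type = 7))
}

#' All three segmentation metrics at once
#'
#' @inheritParams surface_distances
#' @return an object of class `metric_result` with `dsc`, `assd_mm`,
#'   `hd95_mm` (surface metrics `NA` when either mask is empty), and the
#'   voxel counts `n_pred`, `n_ref`.
#' @export
metric_result <- function(pred, ref, spacing = pred$spacing) {
  np <- sum(pred$data); nr <- sum(ref$data)
  res <- list(dsc = suppressMessages(dsc(pred, ref)),
              assd_mm = NA_real_, hd95_mm = NA_real_,
              n_pred = np, n_ref = nr)
  if (np > 0 && nr > 0) {
    sd <- surface_distances(pred, ref, spacing)
    res$assd_mm <- mean(c(sd$pred_to_ref, sd$ref_to_pred))
    res$hd95_mm <- max(stats::quantile(sd$pred_to_ref, 0.95, names = FALSE),
                       stats::quantile(sd$ref_to_pred, 0.95, names = FALSE))
  }
  structure(res, class = "metric_result")
}

#' @export
print.metric_result <- function(x, ...) {
  cat(sprintf("DSC %.4f | ASSD %.3f mm | HD95 %.3f mm (pred %d, ref %d voxels)\n",
              x$dsc, x$assd_mm, x$hd95_mm, x$n_pred, x$n_ref))
  invisible(x)
}

#' Per-case and summary metric table for a cohort
#'
#' Emits one row per case and label (GTVp, GTVnd) plus mean and deviation
#' summary rows per label and for their average.
#'
#' @param preds list of predictions (lists with `gtvp`, `gtvnd` masks).
#' @param refs list of reference `case_bundle`s (or lists with the masks).
#' @return data frame with columns `case`, `label`, `dsc`, `assd_mm`,
#'   `hd95_mm` (summary rows have `case = NA`).
#' @export
evaluate_cases <- function(preds, refs) {
  rows <- list()
  for (ci in seq_along(preds)) {
    for (lab in c("gtvp", "gtvnd")) {
      m <- metric_result(preds[[ci]][[lab]], refs[[ci]][[lab]])
      rows[[length(rows) + 1L]] <- data.frame(
        case = ci, label = toupper(lab), dsc = m$dsc, assd_mm = m$assd_mm,
        hd95_mm = m$hd95_mm, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  summ <- lapply(c("GTVP", "GTVND", "Average"), function(lab) {
    sub <- if (lab == "Average") tab else tab[tab$label == lab, ]
    data.frame(case = NA_integer_, label = paste0(lab, ".mean"),
               dsc = mean(sub$dsc), assd_mm = mean(sub$assd_mm, na.rm = TRUE),
               hd95_mm = mean(sub$hd95_mm, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  rbind(tab, do.call(rbind, summ))
}
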