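#' Otsu threshold of a numeric sample
#'
#' Histogram-based Otsu threshold (maximal between-class variance) over a
#' fixed number of bins, computed on values above `floor` so that an air
#' background does not dominate the histogram.
#'
#' @param x numeric vector of normalized intensities in `[0, 1]`.
#' @param floor values `<= floor` are excluded before thresholding.
#' @param n_bins histogram bins.
#' @return scalar threshold in `(0, 1)`.
#' @export
otsu_threshold <- function(x, floor = 0.05, n_bins = 256) {
  x <- x[x > floor & is.finite(x)]
  if (!length(x)) stop("no foreground voxels above floor")
  h <- tabulate(pmin(pmax(ceiling(x * n_bins), 1L), n_bins), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(n_bins) - 0.5) / n_bins)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  (which.max(sigma_b)) / n_bins
}

resolve_threshold <- function(volume, threshold, floor = 0.05) {
  if (identical(threshold, "auto")) return(otsu_threshold(volume$data, floor))
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1) or \"auto\"")
  threshold
}

#' Contrast-enhanced region of a T1-ce volume
#'
#' The combined cancer+vessel region, recognized by thresholding the
#' normalized contrast-enhanced T1 volume. `threshold = "auto"` uses
#' [otsu_threshold()] on the foreground histogram.
#'
#' @param t1ce normalized T1-ce [volume3d].
#' @param threshold scalar in `(0, 1)` or `"auto"`.
#' @return a [label_mask] with the threshold used stored in
#'   `attr(, "threshold")`.
#' @export
enhanced_region <- function(t1ce, threshold = "auto") {
  thr <- resolve_threshold(t1ce, threshold)
  m <- label_mask(array(as.integer(t1ce$data >= thr), dim = dim(t1ce$data)),
                  t1ce$spacing, "enhanced_t1ce")
  attr(m, "threshold") <- thr
  m
}

#' Vessel region from enhancement and GTV
#'
#' The vessels persist as hyperintense on T2 while tumor signal is mixed;
#' as a training target they are taken as the set difference between the
#' intensity-enhanced region and the clinically annotated GTV.
#'
#' @param enhanced enhanced-region [label_mask].
#' @param gtv GTV [label_mask] on the same grid.
#' @return a [label_mask], `enhanced \ gtv`.
#' @export
vessel_region <- function(enhanced, gtv) {
  stop_if_grid_mismatch(enhanced, gtv)
  m <- enhanced$data
  m[gtv$data == 1] <- 0L
  label_mask(m, enhanced$spacing, "vessel_t2")
}

#' Bone mask from normalized CT
#'
#' High-contrast bone by thresholding; the default 0.65 corresponds to
#' about +300 HU under pooled (-1000, 1000) scaling, a standard bone
#' threshold.
#'
#' @param ct normalized CT [volume3d].
#' @param threshold scalar in `(0, 1)` or `"auto"` (foreground Otsu).
#' @return a [label_mask] with `attr(, "threshold")`.
#' @export
bone_mask <- function(ct, threshold = 0.65) {
  thr <- resolve_threshold(ct, threshold)
  m <- label_mask(array(as.integer(ct$data >= thr), dim = dim(ct$data)),
                  ct$spacing, "bone")
  attr(m, "threshold") <- thr
  m
}

#' Bone-destruction region
#'
#' The overlap between GTV annotations and bone: the CT prior target.
#'
#' @param gtv GTV [label_mask].
#' @param bone bone [label_mask] on the same grid.
#' @return a [label_mask], `gtv` intersected with `bone`.
#' @export
bone_destruction <- function(gtv, bone) {
  stop_if_grid_mismatch(gtv, bone)
  label_mask(gtv$data * bone$data, gtv$spacing, "bone_destruction_ct")
}

#' Construct all clinical-prior targets for a case
#'
#' Builds the three per-modality supervision regions: the T1-ce enhanced
#' region (cancer + vessels), the T2 vessel region (enhanced minus GTV),
#' and the CT bone-destruction region (GTV intersect bone). By default the
#' GTV used is `gtvp` union `gtvnd` (`gtv_labels` switches this).
#'
#' @param bundle a `case_bundle`.
#' @param t1ce_threshold threshold for [enhanced_region()].
#' @param bone_threshold threshold for [bone_mask()].
#' @param gtv_labels subset of `c("gtvp", "gtvnd")` forming the GTV.
#' @param min_component if `> 0`, connected components smaller than this
#'   many voxels are removed from the thresholded masks (6-connectivity).
#' @return an object of class `prior_targets` with masks
#'   `enhanced_t1ce`, `vessel_t2`, `bone`, `bone_destruction_ct`, the GTV
#'   used, and `thresholds_used`.
#' @export
prior_targets <- function(bundle, t1ce_threshold = "auto",
                          bone_threshold = 0.65,
                          gtv_labels = c("gtvp", "gtvnd"),
                          min_component = 0) {
  gtv_labels <- match.arg(gtv_labels, c("gtvp", "gtvnd"), several.ok = TRUE)
  gtv_data <- Reduce(`|`, lapply(gtv_labels, function(l) bundle[[l]]$data == 1))
  gtv <- label_mask(array(as.integer(gtv_data), dim = dim(bundle$gtvp$data)),
                    bundle$spacing, "GTV")
  enh <- enhanced_region(bundle$t1ce, t1ce_threshold)
  bone <- bone_mask(bundle$ct, bone_threshold)
  if (min_component > 0) {
    enh <- remove_small_components(enh, min_component)
    bone <- remove_small_components(bone, min_component)
  }
  structure(list(
    enhanced_t1ce = enh,
    vessel_t2 = vessel_region(enh, gtv),
    bone = bone,
    bone_destruction_ct = bone_destruction(gtv, bone),
    gtv = gtv,
    thresholds_used = c(t1ce = attr(enh, "threshold"),
                        bone = attr(bone, "threshold"))),
    class = "prior_targets")
}

#' @export
print.prior_targets <- function(x, ...) {
  cat("<prior_targets>\n")
  for (k in c("enhanced_t1ce", "vessel_t2", "bone", "bone_destruction_ct"))
    cat(sprintf("  %-20s %d voxels\n", k, sum(x[[k]]$data)))
  cat(sprintf("  thresholds: t1ce %.4g, bone %.4g\n",
              x$thresholds_used["t1ce"], x$thresholds_used["bone"]))
  invisible(x)
}

# flood-fill small 6-connected components out of a mask
remove_small_components <- function(mask, min_voxels) {
  d <- dim(mask$data)
  lab <- array(0L, d)
  cur <- 0L
  idx_of <- function(x, y, z) x + d[1] * (y - 1L + d[2] * (z - 1L))
  fg <- which(mask$data == 1L)
  for (start in fg) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start; lab[start] <- cur
    comp <- start
    while (length(queue)) {
      v <- queue[length(queue)]; queue <- queue[-length(queue)]
      z <- (v - 1L) %/% (d[1] * d[2]) + 1L
      y <- ((v - 1L) %/% d[1]) %% d[2] + 1L
      x <- (v - 1L) %% d[1] + 1L
      for (nb in list(c(-1L,0L,0L), c(1L,0L,0L), c(0L,-1L,0L),
                      c(0L,1L,0L), c(0L,0L,-1L), c(0L,0L,1L))) {
        xx <- x + nb[1]; yy <- y + nb[2]; zz <- z + nb[3]
        if (xx < 1L || yy < 1L || zz < 1L || xx > d[1] || yy > d[2] || zz > d[3]) next
        w <- idx_of(xx, yy, zz)
        if (mask$data[w] == 1L && lab[w] == 0L) {
          lab[w] <- cur; queue <- c(queue, w); comp <- c(comp, w)
        }
      }
    }
    if (length(comp) < min_voxels) mask$data[comp] <- 0L
  }
  mask
}

#' Jaccard index of two masks
#' @param a,b [label_mask]s on the same grid.
#' @return scalar in `[0, 1]` (1 when both are empty).
#' @export
jaccard <- function(a, b) {
  stop_if_grid_mismatch(a, b)
  u <- sum(a$data == 1 | b$data == 1)
  if (u == 0) return(1)
  sum(a$data == 1 & b$data == 1) / u
}
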