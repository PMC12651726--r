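#' 3D scalar volume with physical spacing
#'
#' The universal image carrier used throughout the package: a numeric 3D
#' array indexed `[x, y, z]` (z is the slice axis), with per-axis voxel
#' spacing in millimetres and a physical origin. Voxel centres sit at
#' integer coordinates `1..dim` in voxel space.
#'
#' @param data numeric 3D array.
#' @param spacing positive numeric triple, voxel spacing in mm.
#' @param origin numeric triple, physical position of voxel (1,1,1) in mm.
#' @param modality one of `"CT"`, `"T1CE"`, `"T2"`, `"OTHER"`.
#' @return an object of class `volume3d`.
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     modality = c("OTHER", "CT", "T1CE", "T2")) {
  modality <- match.arg(toupper(modality[1]), c("OTHER", "CT", "T1CE", "T2"))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be a positive numeric triple")
  structure(
    list(data = data, spacing = spacing, origin = as.numeric(origin),
         modality = modality),
    class = "volume3d")
}

#' Binary label mask aligned to a volume
#'
#' @param data 3D array coercible to 0/1 integers.
#' @param spacing positive numeric triple (mm).
#' @param label short name of the structure the mask delineates.
#' @return an object of class `label_mask`.
#' @export
label_mask <- function(data, spacing = c(1, 1, 1), label = "mask") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  vals <- unique(as.vector(data))
  if (!all(vals %in% c(0, 1)))
    stop("mask values must be 0/1")
  storage.mode(data) <- "integer"
  structure(
    list(data = data, spacing = as.numeric(spacing), label = label),
    class = "label_mask")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d %s> %d x %d x %d voxels, spacing %s mm, range [%.4g, %.4g]\n",
              x$modality, d[1], d[2], d[3],
              paste(format(x$spacing), collapse = " x "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.label_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<label_mask '%s'> %d x %d x %d voxels, %d foreground\n",
              x$label, d[1], d[2], d[3], sum(x$data)))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

#' @export
dim.label_mask <- function(x) dim(x$data)

stop_if_grid_mismatch <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("grid mismatch: ", paste(dim(a$data), collapse = "x"), " vs ",
         paste(dim(b$data), collapse = "x"))
  invisible(TRUE)
}

#' Read a NIfTI file as a volume or mask
#'
#' Spacing is taken from the NIfTI pixdim; data are read as a plain array.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param modality modality tag to attach.
#' @param as_mask if `TRUE` return a [label_mask] (values binarised at 0.5).
#' @param label label name when `as_mask = TRUE`.
#' @return a [volume3d] or [label_mask].
#' @export
read_volume <- function(path, modality = "OTHER", as_mask = FALSE,
                        label = "mask") {
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  arr <- array(as.numeric(img), dim = dim(img)[1:3])
  if (as_mask)
    label_mask(array(as.integer(arr > 0.5), dim = dim(arr)), spacing, label)
  else
    volume3d(arr, spacing, modality = modality)
}

#' Write a volume or mask to NIfTI
#'
#' Masks are written as unsigned 8-bit 0/1; the affine encodes the spacing.
#'
#' @param x a [volume3d] or [label_mask].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  is_mask <- inherits(x, "label_mask")
  img <- RNifti::asNifti(x$data + 0)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path, datatype = if (is_mask) "uint8" else "auto")
  invisible(path)
}

# voxel-centre coordinate grids as an n x 3 matrix (1-based, x fastest)
voxel_grid <- function(dims) {
  cbind(
    x = rep.int(seq_len(dims[1]), dims[2] * dims[3]),
    y = rep.int(rep(seq_len(dims[2]), each = dims[1]), dims[3]),
    z = rep(seq_len(dims[3]), each = dims[1] * dims[2]))
}
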