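#' 3D scalar volume with voxel geometry
#'
#' Lightweight container for a 3D scalar field: a numeric array indexed
#' `(x, y, z)` (z is the slice axis) plus voxel spacing in mm and geometry
#' metadata that is passed through I/O untouched. All processing in this
#' package happens in voxel index space; spacing is recorded, not resampled.
#'
#' @param data 3D numeric array of intensities.
#' @param spacing numeric length-3, voxel size per axis in mm (all > 0).
#' @param origin numeric length-3, physical position of the first voxel.
#' @param meta optional list of format-specific header metadata, passed
#'   through unchanged by [write_volume()].
#' @return An object of class `vol3d`.
#' @examples
#' v <- volume3d(array(rnorm(8^3), c(8, 8, 8)))
#' dim(v)
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume3d: `data` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("volume3d: `spacing` must be 3 strictly positive numbers", call. = FALSE)
  structure(list(data = data, spacing = spacing,
                 origin = as.numeric(origin), meta = meta),
            class = "vol3d")
}

#' @export
dim.vol3d <- function(x) dim(x$data)

#' @export
print.vol3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<vol3d> %d x %d x %d voxels, spacing %s mm, range [%g, %g]\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x "),
              min(x$data), max(x$data)))
  invisible(x)
}

is_vol3d <- function(x) inherits(x, "vol3d")

as_vol3d <- function(x) {
  if (is_vol3d(x)) return(x)
  if (is.array(x) && length(dim(x)) == 3L) return(volume3d(x))
  stop("expected a `vol3d` or a 3D array", call. = FALSE)
}

#' Binary label volume
#'
#' A `vol3d` whose data contains only 0 (background) and 1 (vessel).
#'
#' @inheritParams volume3d
#' @return A `vol3d` with additional class `labelvol`.
#' @export
label_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         meta = list()) {
  storage.mode(data) <- "integer"
  if (!all(data %in% c(0L, 1L)))
    stop("label_volume: labels must be 0 (background) or 1 (vessel)",
         call. = FALSE)
  v <- volume3d(data, spacing, origin, meta)
  class(v) <- c("labelvol", class(v))
  v
}

#' Read a 3D volume from NIfTI or MetaImage
#'
#' Supported formats are NIfTI-1 (`.nii`, `.nii.gz`) and uncompressed
#' MetaImage (`.mha`, `.mhd` + `.raw`), selected by file extension.
#' Intensities are returned unchanged (no rescaling); spacing and header
#' metadata are preserved.
#'
#' @param path path to the image file.
#' @return A [volume3d()] object.
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop(sprintf("read_volume: file not found: %s", path), call. = FALSE)
  ext <- volume_format(path)
  vol <- switch(ext,
    nifti = read_nifti_volume(path),
    metaimage = read_metaimage(path),
    stop(sprintf("read_volume: unsupported format for %s (use .nii, .nii.gz, .mha or .mhd)",
                 path), call. = FALSE)
  )
  vol
}

volume_format <- function(path) {
  p <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", p)) return("nifti")
  if (grepl("\\.(mha|mhd)$", p)) return("metaimage")
  "unknown"
}

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (is.null(d) || length(d) != 3L)
    stop(sprintf("read_volume: %s is not a 3D image (dims: %s)",
                 path, paste(d, collapse = "x")), call. = FALSE)
  hdr <- RNifti::niftiHeader(img)
  arr <- array(as.numeric(img), dim = d)
  volume3d(arr,
           spacing = abs(RNifti::pixdim(img)[1:3]),
           origin = c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z),
           meta = list(format = "nifti", nifti_header = hdr))
}

#' Write a 3D volume to NIfTI or MetaImage
#'
#' The format is chosen by the extension of `path`. A written file re-reads
#' to an identical volume (data and spacing); geometry metadata from a
#' previously read file is carried through.
#'
#' @param vol a [volume3d()] (or `labelvol`).
#' @param path output path ending in `.nii`, `.nii.gz`, `.mha` or `.mhd`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  vol <- as_vol3d(vol)
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop(sprintf("write_volume: directory does not exist: %s", dir), call. = FALSE)
  ext <- volume_format(path)
  if (ext == "nifti") {
    img <- RNifti::asNifti(vol$data)
    RNifti::pixdim(img) <- vol$spacing
    ok <- tryCatch({ RNifti::writeNifti(img, path); TRUE },
                   error = function(e) FALSE)
    if (!ok || !file.exists(path))
      stop(sprintf("write_volume: could not write %s", path), call. = FALSE)
  } else if (ext == "metaimage") {
    write_metaimage(vol, path)
  } else {
    stop(sprintf("write_volume: unsupported format for %s", path), call. = FALSE)
  }
  invisible(path)
}

#' Z-axis projection of a volume
#'
#' Collapses the slice axis (axis 3) to a 2D image: `mode = "max"` is the
#' maximum intensity projection (MIP) used for qualitative vessel
#' inspection, `mode = "sum"` the sum projection.
#'
#' @param vol a [volume3d()] or 3D array.
#' @param mode `"max"` or `"sum"`.
#' @return A 2D matrix of shape `(nx, ny)`.
#' @export
z_projection <- function(vol, mode = c("max", "sum")) {
  mode <- match.arg(mode)
  a <- as_vol3d(vol)$data
  nz <- dim(a)[3]
  out <- a[, , 1]
  if (nz > 1) {
    for (k in 2:nz) {
      out <- if (mode == "max") pmax(out, a[, , k]) else out + a[, , k]
    }
  }
  out
}
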