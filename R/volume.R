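#' 3D image volume
#'
#' A minimal container for a 3D scalar grid with physical geometry: voxel
#' values, per-axis voxel spacing and origin (mm), an imaging modality tag
#' and the physical units of the values.
#'
#' @param values 3D numeric or logical array.
#' @param spacing_mm numeric length-3, positive voxel size per axis (mm).
#' @param origin_mm numeric length-3, physical position of voxel (1,1,1).
#' @param modality one of `"PET"`, `"CT"`, `"T1"`, `"T2FS"`, `"MASK"`,
#'   `"OTHER"`.
#' @param units one of `"SUV"`, `"HU"`, `"NORMALIZED"`, `"ARBITRARY"`,
#'   `"BINARY"`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(values, spacing_mm = c(1, 1, 1), origin_mm = c(0, 0, 0),
                         modality = "OTHER", units = "ARBITRARY") {
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (any(spacing_mm <= 0)) stop("spacing must be positive", call. = FALSE)
  modality <- match.arg(modality, c("PET", "CT", "T1", "T2FS", "MASK", "OTHER"))
  units <- match.arg(units, c("SUV", "HU", "NORMALIZED", "ARBITRARY", "BINARY"))
  structure(
    list(values = values, spacing_mm = as.numeric(spacing_mm),
         origin_mm = as.numeric(origin_mm), modality = modality, units = units),
    class = "image_volume"
  )
}

#' @export
dim.image_volume <- function(x) dim(x$values)

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s [%s]  %s voxels @ %s mm\n",
              x$modality, x$units,
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing_mm, 4), collapse = "x")))
  invisible(x)
}

#' @rdname image_volume
#' @param x an `image_volume`.
#' @export
is_mask <- function(x) {
  is.logical(x$values) || x$units == "BINARY"
}

mask_array <- function(x) {
  if (inherits(x, "image_volume")) x <- x$values
  if (!is.logical(x)) x <- x > 0.5
  x
}

voxel_volume_ml <- function(vol) prod(vol$spacing_mm) / 1000

check_same_grid <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)) ||
      max(abs(a$spacing_mm - b$spacing_mm)) > 1e-6 ||
      max(abs(a$origin_mm - b$origin_mm)) > 1e-6)
    stop("volumes are not defined on the same grid", call. = FALSE)
  invisible(TRUE)
}

#' Read / write NIfTI-1 volumes
#'
#' Thin wrappers over [RNifti] attaching/recovering the spacing and origin.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param vol an `image_volume`.
#' @param modality,units passed to [image_volume()] on read.
#' @return `read_volume()` returns an `image_volume`; `write_volume()`
#'   returns `path` invisibly.
#' @export
read_volume <- function(path, modality = "OTHER", units = "ARBITRARY") {
  img <- RNifti::readNifti(path)
  spc <- RNifti::pixdim(img)[1:3]
  image_volume(array(as.numeric(img), dim = dim(img)[1:3]),
               spacing_mm = spc, origin_mm = c(0, 0, 0),
               modality = modality, units = units)
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$values * 1)
  RNifti::pixdim(img) <- vol$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}
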