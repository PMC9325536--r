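#' Resample a volume to isotropic voxels
#'
#' Images are interpolated with order-3 (cubic) B-splines after the standard
#' coefficient prefilter; masks use nearest-neighbour interpolation so the
#' output stays binary. The output grid keeps the input origin and covers
#' the same physical extent.
#'
#' @param img an `image_volume`.
#' @param target_spacing_mm positive scalar, output voxel size on all axes.
#' @param is_mask force nearest-neighbour (default: auto-detected).
#' @return An `image_volume` on the isotropic grid.
#' @export
resample_isotropic <- function(img, target_spacing_mm,
                               is_mask = NULL) {
  stopifnot(inherits(img, "image_volume"))
  if (!is.numeric(target_spacing_mm) || target_spacing_mm <= 0)
    stop("target spacing must be positive", call. = FALSE)
  if (is.null(is_mask)) is_mask <- is_mask(img)
  d <- dim(img$values)
  extent <- (d - 1) * img$spacing_mm
  nd <- pmax(1L, floor(extent / target_spacing_mm + 1e-9) + 1L)
  # continuous input indices (0-based) of the output voxel centres
  tpos <- lapply(1:3, function(a)
    (seq_len(nd[a]) - 1) * target_spacing_mm / img$spacing_mm[a])
  vals <- img$values * 1
  if (is_mask) {
    out <- cpp_resample_nearest(as.numeric(vals), d,
                                tpos[[1]], tpos[[2]], tpos[[3]])
    out <- array(out > 0.5, nd)
  } else {
    out <- array(cpp_resample_bspline(as.numeric(vals), d,
                                      tpos[[1]], tpos[[2]], tpos[[3]]), nd)
  }
  image_volume(out, rep(target_spacing_mm, 3), img$origin_mm,
               img$modality, img$units)
}

#' Fat-reference intensity normalization for T1 images
#'
#' Linearly rescales a T1 volume against fat as a reference tissue: voxels
#' become `(I - mu_fat) / sigma_fat`, where the statistics are pooled over
#' all supplied fat-sphere masks (population SD). After the transform the
#' pooled fat voxels have mean 0 and SD 1, and inter-patient intensity
#' ordering is preserved because the map is affine with positive slope.
#'
#' @param img a T1 `image_volume` (bias-field-corrected input is accepted
#'   as-is; correction itself is a preprocessing hook outside this package).
#' @param fat_masks list of binary mask volumes on the same grid as `img`.
#' @return A list with `volume` (normalized `image_volume`, units
#'   `NORMALIZED`) and `stats` (tibble: `mu_fat`, `sigma_fat`,
#'   `n_reference_voxels`).
#' @export
normalize_fat_reference <- function(img, fat_masks) {
  stopifnot(inherits(img, "image_volume"))
  if (length(fat_masks) == 0) stop("empty fat masks", call. = FALSE)
  pooled <- unlist(lapply(fat_masks, function(m) {
    check_same_grid(img, m)
    img$values[mask_array(m)]
  }))
  if (length(pooled) < 2) stop("need at least 2 pooled fat voxels", call. = FALSE)
  mu <- mean(pooled)
  sigma <- pop_sd(pooled)
  if (sigma <= the_eps) stop("zero fat-reference variance", call. = FALSE)
  out <- image_volume((img$values - mu) / sigma, img$spacing_mm, img$origin_mm,
                      img$modality, "NORMALIZED")
  list(volume = out,
       stats = tibble(mu_fat = mu, sigma_fat = sigma,
                      n_reference_voxels = length(pooled)))
}

#' Tumor-ROI z-score normalization for fat-suppressed T2 images
#'
#' `(I - mu_tum) / sigma_tum` with the mean and population SD computed over
#' the tumor ROI, so the ROI has mean 0 and SD 1 afterwards. Unlike the
#' fat-reference normalization this removes inter-patient intensity scale.
#'
#' @param img an `image_volume`.
#' @param roi binary mask volume on the same grid.
#' @return The normalized `image_volume` (units `NORMALIZED`).
#' @export
normalize_zscore_roi <- function(img, roi) {
  stopifnot(inherits(img, "image_volume"))
  check_same_grid(img, roi)
  m <- mask_array(roi)
  v <- img$values[m]
  if (length(v) < 2) stop("ROI must contain at least 2 voxels", call. = FALSE)
  sigma <- pop_sd(v)
  if (sigma <= the_eps) stop("constant ROI intensities", call. = FALSE)
  image_volume((img$values - mean(v)) / sigma, img$spacing_mm, img$origin_mm,
               img$modality, "NORMALIZED")
}

#' Restrict a CT ROI to a Hounsfield band
#'
#' Drops ROI voxels outside the closed interval `[lo_hu, hi_hu]` (defaults
#' -230 and 600 HU), limiting air and bone voxels while keeping tumor
#' hypodensities and calcifications.
#'
#' @param roi binary mask volume.
#' @param ct CT `image_volume` on the same grid.
#' @param lo_hu,hi_hu band limits (kept voxels satisfy `lo <= HU <= hi`).
#' @return The clipped mask volume.
#' @export
clip_ct_roi <- function(roi, ct, lo_hu = -230, hi_hu = 600) {
  check_same_grid(roi, ct)
  keep <- mask_array(roi) & ct$values >= lo_hu & ct$values <= hi_hu
  if (!any(keep)) stop("CT clipping produced an empty ROI", call. = FALSE)
  image_volume(keep, roi$spacing_mm, roi$origin_mm, "MASK", "BINARY")
}

#' Gray-level discretization scheme
#'
#' Either a fixed bin size (bins anchored on multiples of the width, the
#' convention of the imaging biomarker standardization effort) or a fixed
#' bin count over a cohort-wide intensity range with an inclusive top edge.
#'
#' @param mode `"FIXED_BIN_SIZE"` or `"FIXED_BIN_COUNT"`.
#' @param bin_width bin width in intensity units (size mode).
#' @param n_bins,cohort_min,cohort_max count-mode parameters.
#' @return A list of class `discretization_scheme`.
#' @export
discretization_scheme <- function(mode = c("FIXED_BIN_SIZE", "FIXED_BIN_COUNT"),
                                  bin_width = NULL, n_bins = NULL,
                                  cohort_min = NULL, cohort_max = NULL) {
  mode <- match.arg(mode)
  if (mode == "FIXED_BIN_SIZE") {
    if (is.null(bin_width) || bin_width <= 0)
      stop("bin_width must be positive", call. = FALSE)
  } else {
    if (is.null(n_bins) || n_bins < 2)
      stop("n_bins must be >= 2", call. = FALSE)
    if (is.null(cohort_min) || is.null(cohort_max) || cohort_max <= cohort_min)
      stop("cohort_max must exceed cohort_min", call. = FALSE)
  }
  structure(list(mode = mode, bin_width = bin_width, n_bins = n_bins,
                 cohort_min = cohort_min, cohort_max = cohort_max),
            class = "discretization_scheme")
}

#' Discretize an image into 1-based gray levels within a ROI
#'
#' Fixed-bin-size mode assigns `floor(v / w) - floor(min_roi / w) + 1`, i.e.
#' bins anchored at multiples of the width; fixed-bin-count mode uses
#' `n_bins` equal-width bins over `[cohort_min, cohort_max]` with the top
#' edge inclusive. Values outside the cohort range are clamped with a
#' warning. Discretization is monotone in the input value.
#'
#' @param img an `image_volume`.
#' @param roi binary mask volume on the same grid.
#' @param scheme a [discretization_scheme()].
#' @return An `image_volume` of integer gray levels (NA outside the ROI),
#'   with attributes `n_levels` and `scheme`.
#' @export
discretize <- function(img, roi, scheme) {
  stopifnot(inherits(scheme, "discretization_scheme"))
  check_same_grid(img, roi)
  m <- mask_array(roi)
  v <- img$values[m]
  if (scheme$mode == "FIXED_BIN_SIZE") {
    w <- scheme$bin_width
    lev <- floor(v / w) - floor(min(v) / w) + 1L
  } else {
    lo <- scheme$cohort_min; hi <- scheme$cohort_max; nb <- scheme$n_bins
    if (any(v < lo) || any(v > hi)) {
      warning("values outside the cohort range were clamped", call. = FALSE)
      v <- pmin(pmax(v, lo), hi)
    }
    lev <- pmin(floor((v - lo) / (hi - lo) * nb) + 1L, nb)
  }
  out <- array(NA_integer_, dim(img$values))
  out[m] <- as.integer(lev)
  res <- image_volume(out, img$spacing_mm, img$origin_mm, img$modality,
                      "ARBITRARY")
  attr(res, "n_levels") <- max(lev)
  attr(res, "scheme") <- scheme
  res
}
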