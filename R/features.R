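#' Extract voxel-wise feature maps with a 3D sliding window
#'
#' For every ROI voxel `v` a cubic window (default 9 voxels per axis) is
#' centred on `v`, intersected with the ROI, and the catalog features are
#' computed on that voxel set; the values are assigned to `v` in the
#' resulting maps. Windows holding fewer than 2 in-ROI voxels inherit the
#' values of the nearest computable voxel so that every ROI voxel carries a
#' finite value in every map.
#'
#' @param discrete_img integer gray-level volume from [discretize()].
#' @param raw_img raw-intensity `image_volume` on the same grid (used by
#'   the first-order intensity statistics).
#' @param roi binary mask volume.
#' @param window odd window width in voxels (>= 3), default 9.
#' @param catalog feature catalog; the full 77-feature catalog by default.
#' @param masked if `TRUE` (default) only in-ROI voxels inside the window
#'   contribute; if `FALSE` the window uses every voxel with a defined gray
#'   level (requires discretizing with a whole-image ROI).
#' @return A list of class `feature_map_set`: `patient_id`, `modality`,
#'   `maps` (named list of 3D arrays, NA outside the ROI), `roi`, `window`,
#'   `spacing_mm`, `origin_mm`.
#' @export
extract_feature_maps <- function(discrete_img, raw_img, roi, window = 9,
                                 catalog = feature_catalog(), masked = TRUE) {
  check_same_grid(discrete_img, raw_img)
  check_same_grid(discrete_img, roi)
  if (window %% 2 == 0 || window < 3)
    stop("window must be an odd integer >= 3", call. = FALSE)
  m <- mask_array(roi)
  if (!any(m)) stop("empty ROI", call. = FALSE)
  lev <- discrete_img$values
  n_levels <- attr(discrete_img, "n_levels")
  if (is.null(n_levels)) n_levels <- max(lev[m], na.rm = TRUE)
  include <- if (masked) m else !is.na(lev)
  res <- cpp_extract_maps(as.integer(lev), as.numeric(raw_img$values),
                          as.logical(include), as.logical(m), dim(lev),
                          as.integer(window), as.integer(n_levels),
                          prod(discrete_img$spacing_mm))
  vals <- res$values
  bad <- which(res$n_in_window < 2)
  if (length(bad) > 0) {
    ok <- which(res$n_in_window >= 2)
    if (length(ok) == 0) stop("no window holds 2 in-ROI voxels", call. = FALSE)
    co <- arrayInd(res$index, dim(lev)) *
      rep(discrete_img$spacing_mm, each = length(res$index))
    for (b in bad) {
      d2 <- rowSums((co[ok, , drop = FALSE] -
                       rep(co[b, ], each = length(ok)))^2)
      vals[b, ] <- vals[ok[which.min(d2)], ]
    }
  }
  nm <- catalog_names(feature_catalog())
  maps <- lapply(seq_len(77), function(j) {
    a <- array(NA_real_, dim(lev))
    a[res$index] <- vals[, j]
    a
  })
  names(maps) <- nm
  keep_cols <- feature_catalog()$column %in% catalog$column
  maps <- maps[keep_cols]
  structure(list(patient_id = NA_character_, modality = raw_img$modality,
                 maps = maps, roi = roi, window = as.integer(window),
                 spacing_mm = discrete_img$spacing_mm,
                 origin_mm = discrete_img$origin_mm),
            class = "feature_map_set")
}

#' @export
print.feature_map_set <- function(x, ...) {
  cat(sprintf("<feature_map_set> %s: %d maps, window %d, %d ROI voxels\n",
              x$modality, length(x$maps), x$window,
              sum(mask_array(x$roi))))
  invisible(x)
}

#' Texture matrices of a gray-level region
#'
#' The four texture matrices computed over a masked gray-level array:
#' symmetric distance-1 GLCM accumulated over the 13 unique 3D directions,
#' GLRLM accumulated over the same directions, GLDM with dependence
#' threshold 0, and the NGTDM sums `s_i` with counts `n_i`. Matrices count
#' only masked voxels and pairs.
#'
#' @param levels integer array of 1-based gray levels.
#' @param mask logical array of the same shape.
#' @param n_levels number of gray levels (matrix rows); defaults to the
#'   maximum masked level.
#' @return A list with `glcm` (counts), `glrlm`, `gldm` and `ngtdm`
#'   (`list(s, n)`).
#' @export
texture_matrices <- function(levels, mask, n_levels = NULL) {
  stopifnot(length(dim(levels)) == 3, identical(dim(levels), dim(mask)))
  if (is.null(n_levels)) n_levels <- max(levels[mask], na.rm = TRUE)
  cpp_texture_matrices(as.integer(levels), as.logical(mask), dim(levels),
                       as.integer(n_levels))
}

#' Aggregate feature maps into ROI features by the mean
#'
#' The per-patient ROI feature is the arithmetic mean of the voxel-wise map
#' over all ROI voxels. This is the aggregation the logistic models consume,
#' and the linearity that makes decision-map backprojection exact.
#'
#' @param mapset a `feature_map_set`.
#' @param roi optional mask (defaults to the set's ROI).
#' @return A tibble: `modality`, `family`, `feature`, `name`, `value`,
#'   `n_roi_voxels`.
#' @export
aggregate_mean <- function(mapset, roi = NULL) {
  stopifnot(inherits(mapset, "feature_map_set"))
  if (is.null(roi)) roi <- mapset$roi
  m <- mask_array(roi)
  if (!any(m)) stop("empty ROI", call. = FALSE)
  vals <- vapply(mapset$maps, function(a) mean(a[m]), numeric(1))
  if (any(!is.finite(vals)))
    stop("feature maps contain non-finite values inside the ROI", call. = FALSE)
  parts <- strsplit(names(vals), "_", fixed = TRUE)
  tibble(
    modality = mapset$modality,
    family = vapply(parts, `[`, "", 1),
    feature = vapply(parts, function(p) paste(p[-1], collapse = "_"), ""),
    name = paste(mapset$modality, names(vals), sep = "_"),
    value = unname(vals),
    n_roi_voxels = sum(m)
  )
}

#' Mask-derived shape and volume features
#'
#' The 14 standard 3D shape descriptors of a binary segmentation mask:
#' mesh volume and surface area from a closed marching-tetrahedra surface,
#' voxel volume (the anatomical tumor volume, ATV), surface/volume ratio,
#' sphericity, maximum 3D diameter and the three maximum in-plane 2D
#' diameters over surface voxels, and the axis lengths / elongation /
#' flatness from the principal components of the voxel coordinates. These
#' have no voxel-level counterpart and enter models as non-mappable
#' features.
#'
#' @param roi binary mask volume.
#' @param spacing_mm optional spacing override (mm).
#' @return A tibble: `feature`, `name` (prefixed `SHAPE_`), `value`.
#'   Volumes in mm^3, areas in mm^2, lengths in mm.
#' @export
shape_features <- function(roi, spacing_mm = NULL) {
  m <- mask_array(roi)
  if (!any(m)) stop("empty mask", call. = FALSE)
  spc <- if (is.null(spacing_mm)) roi$spacing_mm else rep(spacing_mm, length.out = 3)
  d <- dim(m)
  # level-set surface: mesh the 0.5 iso-level of the box-smoothed, padded
  # indicator so masks touching the border still yield a closed surface
  pd <- d + 4L
  padded <- array(0, pd)
  padded[3:(d[1] + 2), 3:(d[2] + 2), 3:(d[3] + 2)] <- m * 1
  smoothed <- cpp_box_smooth(as.numeric(padded), pd)
  mesh <- cpp_surface_mesh(smoothed, pd, spc)
  if (mesh$volume <= 0)  # mask too small to survive smoothing: mesh it raw
    mesh <- cpp_surface_mesh(as.numeric(padded), pd, spc)
  nvox <- sum(m)
  voxvol <- nvox * prod(spc)
  idx <- which(m)
  ijk <- arrayInd(idx, d)
  xyz <- (ijk - 1) * rep(spc, each = nrow(ijk))
  # principal axes of the voxel-centre cloud (physical coordinates)
  if (nrow(xyz) > 1) {
    cv <- stats::cov(xyz) * (nrow(xyz) - 1) / nrow(xyz)
    ev <- sort(pmax(eigen(cv, symmetric = TRUE, only.values = TRUE)$values, 0),
               decreasing = TRUE)
  } else ev <- c(0, 0, 0)
  axes <- 4 * sqrt(ev)
  # surface voxels: at least one 6-neighbour outside the mask
  surf <- m & !erode6(m)
  sidx <- which(surf)
  sijk <- arrayInd(sidx, d)
  sxyz <- (sijk - 1) * rep(spc, each = nrow(sijk))
  dia <- if (nrow(sxyz) > 1)
    cpp_max_diameters(sxyz, sijk) else c(0, 0, 0, 0)
  mv <- mesh$volume
  sa <- mesh$area
  sph <- if (sa > 0) (pi^(1 / 3) * (6 * mv)^(2 / 3)) / sa else NA_real_
  vals <- c(
    MeshVolume = mv, VoxelVolume = voxvol, SurfaceArea = sa,
    SurfaceVolumeRatio = if (mv > 0) sa / mv else NA_real_,
    Sphericity = sph,
    Maximum3DDiameter = dia[1], Maximum2DDiameterSlice = dia[2],
    Maximum2DDiameterColumn = dia[3], Maximum2DDiameterRow = dia[4],
    MajorAxisLength = axes[1], MinorAxisLength = axes[2],
    LeastAxisLength = axes[3],
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0
  )
  tibble(feature = names(vals), name = paste0("SHAPE_", names(vals)),
         value = unname(vals))
}

erode6 <- function(m) {
  d <- dim(m)
  p <- array(FALSE, d + 2)
  p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  i <- 2:(d[1] + 1); j <- 2:(d[2] + 1); k <- 2:(d[3] + 1)
  p[i, j, k] & p[i - 1, j, k] & p[i + 1, j, k] &
    p[i, j - 1, k] & p[i, j + 1, k] & p[i, j, k - 1] & p[i, j, k + 1]
}

#' Resample feature maps onto a common isotropic grid
#'
#' Maps are defined only inside the ROI; before the order-3 B-spline
#' interpolation each map is extended outward with the nearest in-ROI value
#' (so the spline is not driven by the undefined background), and the
#' result is re-masked by the nearest-neighbour-resampled ROI.
#'
#' @param mapsets list of `feature_map_set` objects (or a single one).
#' @param spacing_mm target isotropic spacing, default 1 mm.
#' @return The resampled `feature_map_set` list (or single object).
#' @export
resample_maps_common_grid <- function(mapsets, spacing_mm = 1) {
  single <- inherits(mapsets, "feature_map_set")
  if (single) mapsets <- list(mapsets)
  out <- lapply(mapsets, function(ms) {
    d <- dim(ms$roi$values)
    roi_new <- resample_isotropic(ms$roi, spacing_mm, is_mask = TRUE)
    m_new <- mask_array(roi_new)
    extent <- (d - 1) * ms$spacing_mm
    nd <- dim(roi_new$values)
    tpos <- lapply(1:3, function(a)
      (seq_len(nd[a]) - 1) * spacing_mm / ms$spacing_mm[a])
    ms$maps <- lapply(ms$maps, function(a) {
      filled <- array(cpp_fill_nearest(as.numeric(a), d), d)
      r <- array(cpp_resample_bspline(as.numeric(filled), d,
                                      tpos[[1]], tpos[[2]], tpos[[3]]), nd)
      r[!m_new] <- NA_real_
      r
    })
    ms$roi <- roi_new
    ms$spacing_mm <- rep(spacing_mm, 3)
    ms
  })
  if (single) out[[1]] else out
}

#' Per-patient ROI feature vector for a set of modalities
#'
#' Convenience wrapper running discretization, sliding-window extraction
#' and mean aggregation per modality, then concatenating the mask-derived
#' shape features: the `77 * n_modalities + 14` vector the cohort models
#' consume.
#'
#' @param case a `multimodal_case`.
#' @param modalities modality names to include.
#' @param schemes named list of [discretization_scheme()] per modality.
#' @param window sliding-window width.
#' @return A wide one-row tibble: `label`, then one column per feature.
#' @export
case_features <- function(case, modalities = c("PET", "CT"),
                          schemes = default_schemes(case, modalities),
                          window = 9) {
  rows <- purrr::map(modalities, function(mod) {
    img <- case$images[[mod]]
    roi <- case$roi
    if (mod == "CT") roi <- clip_ct_roi(roi, img)
    disc <- discretize(img, roi, schemes[[mod]])
    ms <- extract_feature_maps(disc, img, roi, window = window)
    aggregate_mean(ms)
  })
  agg <- dplyr::bind_rows(rows)
  shp <- shape_features(case$roi)
  wide <- tibble(label = case$label)
  for (i in seq_len(nrow(agg))) wide[[agg$name[i]]] <- agg$value[i]
  for (i in seq_len(nrow(shp))) wide[[shp$name[i]]] <- shp$value[i]
  wide
}

#' Default per-modality discretization for phantom work
#'
#' Fixed bin sizes for PET (0.3125 SUV) and CT (10 HU); fixed bin count
#' (128 bins over the observed ROI range) for the two MRI channels.
#'
#' @param case a `multimodal_case`.
#' @param modalities modalities to cover.
#' @return Named list of schemes.
#' @export
default_schemes <- function(case, modalities = c("PET", "CT", "T1", "T2FS")) {
  out <- list()
  for (mod in modalities) {
    out[[mod]] <- switch(mod,
      PET = discretization_scheme("FIXED_BIN_SIZE", bin_width = 0.3125),
      CT = discretization_scheme("FIXED_BIN_SIZE", bin_width = 10),
      {
        v <- case$images[[mod]]$values[mask_array(case$roi)]
        discretization_scheme("FIXED_BIN_COUNT", n_bins = 128,
                              cohort_min = min(v), cohort_max = max(v))
      })
  }
  out
}

#' Build the cohort feature table
#'
#' Stacks [case_features()] over a cohort into the patients-by-features
#' table used by the multicollinearity reduction and modeling stages.
#'
#' @param cases list from [generate_cohort()] (or equivalent).
#' @param ... passed to [case_features()].
#' @return A tibble: `patient_id`, `label`, one column per feature.
#' @export
cohort_feature_table <- function(cases, ...) {
  rows <- purrr::imap(cases, function(cs, id)
    dplyr::bind_cols(tibble(patient_id = id), case_features(cs, ...)))
  dplyr::bind_rows(rows)
}
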