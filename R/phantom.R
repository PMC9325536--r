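#' Parameters of the multimodal tumor phantom generator
#'
#' The generator emulates a soft-tissue tumor imaged in four co-registered
#' modalities: an ellipsoidal tumor with a metabolically active rim and a
#' central necrotic core that is PET-cold, CT-hypodense, dark on T1 and
#' bright on fat-suppressed T2. Outcome class 1 tumors have (on average) a
#' larger necrotic volume fraction and a higher peak uptake than class 0
#' tumors, which is the effect structure the downstream models are expected
#' to recover.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param spacing_mm voxel size per axis (mm); all modalities share this
#'   grid and are declared co-registered.
#' @param tumor_radius_mm largest tumor semi-axis (mm).
#' @param axis_ratios length-3 multipliers of `tumor_radius_mm` giving the
#'   ellipsoid semi-axes, so shape descriptors (elongation, flatness) are
#'   informative.
#' @param tumor_radius_sd SD of the per-case radius draw (mm).
#' @param axis_ratio_jitter SD of the per-case multiplicative (log-normal)
#'   jitter applied to each axis ratio, so shape features vary across the
#'   cohort.
#' @param necrotic_fraction_mean_by_class length-2 (class 0, class 1) mean
#'   necrotic volume fraction in `[0, 1]`; class 1 mean must be >= class 0.
#' @param necrotic_fraction_sd SD of the per-case draw (truncated to
#'   `[0, 0.8]`).
#' @param suvmax_mean_by_class length-2 mean rim uptake (SUV) per class.
#' @param suvmax_sd SD of the per-case rim uptake draw.
#' @param noise_sd_by_modality named numeric, additive Gaussian noise SD per
#'   modality in native units (SUV, HU, arbitrary MRI intensity).
#' @param necrotic_ct_hu,rim_ct_hu HU assigned to the necrotic core and the
#'   viable rim; defaults 10 HU (inside the 0-20 HU hypodense band) and
#'   60 HU so that <20 and <30 HU thresholds segment the core.
#' @param core_suv uptake assigned to the necrotic core (SUV).
#' @param n_fat_spheres,fat_sphere_volume_mm3 fat-reference spheres drawn
#'   outside the tumor on the T1 grid (defaults: 20 spheres of ~240 mm^3).
#' @param seed default cohort seed.
#' @return A list of class `phantom_params`.
#' @export
phantom_params <- function(grid_shape = c(40, 40, 40),
                           spacing_mm = c(2, 2, 2),
                           tumor_radius_mm = 24,
                           tumor_radius_sd = 1.5,
                           axis_ratios = c(1, 0.8, 0.65),
                           axis_ratio_jitter = 0.08,
                           necrotic_fraction_mean_by_class = c(0.12, 0.35),
                           necrotic_fraction_sd = 0.06,
                           suvmax_mean_by_class = c(5, 9),
                           suvmax_sd = 0.8,
                           noise_sd_by_modality = c(PET = 0.15, CT = 6,
                                                    T1 = 15, T2FS = 10),
                           necrotic_ct_hu = 10, rim_ct_hu = 60,
                           core_suv = 1,
                           n_fat_spheres = 20,
                           fat_sphere_volume_mm3 = 240,
                           seed = 1L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 4),
            all(spacing_mm > 0), tumor_radius_mm > 0,
            length(necrotic_fraction_mean_by_class) == 2,
            all(necrotic_fraction_mean_by_class >= 0),
            all(necrotic_fraction_mean_by_class <= 1),
            all(suvmax_mean_by_class > 0), necrotic_fraction_sd >= 0)
  if (necrotic_fraction_mean_by_class[2] < necrotic_fraction_mean_by_class[1])
    stop("class-1 necrotic fraction mean must be >= class-0 mean", call. = FALSE)
  structure(as.list(environment()), class = "phantom_params")
}

# axis coordinate grids (voxel centres, mm)
axis_coords <- function(shape, spacing) {
  lapply(1:3, function(a) (seq_len(shape[a]) - 1) * spacing[a])
}

rtrunc_norm <- function(mean, sd, lo, hi) {
  if (sd == 0) return(min(max(mean, lo), hi))
  for (i in 1:1000) {
    x <- rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(max(mean, lo), hi)
}

ellipsoid_mask <- function(shape, spacing, center, semi) {
  cc <- axis_coords(shape, spacing)
  dx2 <- ((cc[[1]] - center[1]) / semi[1])^2
  dy2 <- ((cc[[2]] - center[2]) / semi[2])^2
  dz2 <- ((cc[[3]] - center[3]) / semi[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
}

#' Generate one multimodal phantom case
#'
#' Deterministic given `(params, label, seed)`. The necrotic volume fraction
#' is drawn around the class mean and realized as a central sub-ellipsoid
#' scaled by the cube root of the fraction; the rim uptake is drawn around
#' the class SUVmax mean. The drawn values are recorded in `$truth` together
#' with the voxel-measured necrotic fraction.
#'
#' @param params a [phantom_params()] object.
#' @param label outcome class, 0 or 1.
#' @param seed integer seed for this case.
#' @return A list of class `multimodal_case` with elements `images` (named
#'   list of `image_volume`: PET, CT, T1, T2FS), `roi` (mask volume),
#'   `fat_masks` (list of mask volumes on the T1 grid), `label`, `truth`.
#' @export
generate_case <- function(params, label, seed) {
  stopifnot(inherits(params, "phantom_params"), label %in% c(0, 1))
  p <- params
  shape <- p$grid_shape; spc <- p$spacing_mm
  fov <- shape * spc
  semi_max <- (p$tumor_radius_mm + 3 * p$tumor_radius_sd) *
    p$axis_ratios * exp(2 * p$axis_ratio_jitter)
  if (any(2 * semi_max > fov - 2 * spc))
    stop("degenerate grid: tumor larger than the field of view", call. = FALSE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  cls <- label + 1L
  radius <- rtrunc_norm(p$tumor_radius_mm, p$tumor_radius_sd,
                        max(2 * max(spc), p$tumor_radius_mm - 3 * p$tumor_radius_sd),
                        p$tumor_radius_mm + 3 * p$tumor_radius_sd)
  ratios <- p$axis_ratios *
    exp(pmin(pmax(rnorm(3, 0, p$axis_ratio_jitter), -2 * p$axis_ratio_jitter),
             2 * p$axis_ratio_jitter))
  semi <- radius * ratios
  frac <- rtrunc_norm(p$necrotic_fraction_mean_by_class[cls],
                      p$necrotic_fraction_sd, 0, 0.8)
  suv_rim <- max(1.5, rnorm(1, p$suvmax_mean_by_class[cls], p$suvmax_sd))
  center <- fov / 2
  roi <- ellipsoid_mask(shape, spc, center, semi)
  if (!any(roi)) stop("degenerate grid: empty ROI", call. = FALSE)
  core <- if (frac > 0)
    ellipsoid_mask(shape, spc, center, semi * frac^(1 / 3)) & roi
  else array(FALSE, shape)

  nz <- p$noise_sd_by_modality
  noise <- function(sd) if (sd > 0) array(rnorm(prod(shape), 0, sd), shape)
           else array(0, shape)
  fill <- function(bg, rim, core_val) {
    v <- array(bg, shape); v[roi] <- rim; v[core] <- core_val; v
  }
  pet <- fill(0.5, suv_rim, p$core_suv) + noise(nz[["PET"]])
  ct  <- fill(-100, p$rim_ct_hu, p$necrotic_ct_hu) + noise(nz[["CT"]])
  t1  <- fill(150, 300, 120)
  t2  <- fill(30, 120, 320) + noise(nz[["T2FS"]])

  # fat-reference spheres outside the tumor, textured, on the T1 grid
  r_fat <- (3 * p$fat_sphere_volume_mm3 / (4 * pi))^(1 / 3)
  fat_masks <- list()
  tries <- 0
  while (length(fat_masks) < p$n_fat_spheres && tries < 2000) {
    tries <- tries + 1
    ctr <- runif(3, r_fat + spc, fov - r_fat - spc)
    d_rel <- sum(((ctr - center) / (semi + r_fat + max(spc)))^2)
    if (d_rel <= 1) next
    sph <- ellipsoid_mask(shape, spc, ctr, rep(r_fat, 3))
    if (!any(sph)) next
    t1[sph] <- rnorm(sum(sph), 500, 40)
    fat_masks[[length(fat_masks) + 1L]] <-
      image_volume(sph, spc, modality = "MASK", units = "BINARY")
  }
  t1 <- t1 + noise(nz[["T1"]])

  mk <- function(v, mod, un) image_volume(v, spc, modality = mod, units = un)
  structure(list(
    images = list(PET = mk(pet, "PET", "SUV"), CT = mk(ct, "CT", "HU"),
                  T1 = mk(t1, "T1", "ARBITRARY"),
                  T2FS = mk(t2, "T2FS", "ARBITRARY")),
    roi = image_volume(roi, spc, modality = "MASK", units = "BINARY"),
    fat_masks = fat_masks,
    label = as.integer(label),
    truth = list(necrotic_fraction = frac,
                 necrotic_fraction_measured = sum(core) / sum(roi),
                 suvmax = suv_rim)
  ), class = "multimodal_case")
}

#' Generate a phantom cohort
#'
#' `floor(n * prevalence)` class-1 cases and the rest class 0, with per-case
#' seeds derived deterministically from the cohort seed. The default cohort
#' composition (51 patients, prevalence 19/51) mirrors a typical small
#' sarcoma cohort with 19 events.
#'
#' @param n number of cases (>= 4).
#' @param prevalence class-1 fraction, in (0, 1).
#' @param params a [phantom_params()] object.
#' @param seed cohort seed.
#' @return A named list of `multimodal_case` ("case_01", ...).
#' @export
generate_cohort <- function(n = 51, prevalence = 19 / 51,
                            params = phantom_params(), seed = 1L) {
  stopifnot(n >= 4, prevalence > 0, prevalence < 1)
  n1 <- floor(n * prevalence)
  n0 <- n - n1
  if (n1 < 2 || n0 < 2)
    stop("each class needs at least 2 members for stratified CV", call. = FALSE)
  labels <- c(rep(1L, n1), rep(0L, n0))
  set.seed(as.integer(seed %% .Machine$integer.max))
  case_seeds <- sample.int(.Machine$integer.max - 1L, n)
  cases <- purrr::map2(labels, case_seeds,
                       function(l, s) generate_case(params, l, s))
  names(cases) <- sprintf("case_%02d", seq_len(n))
  cases
}

#' Write a phantom cohort to disk
#'
#' NIfTI-1 volumes per case plus a manifest CSV (case id, label, file paths,
#' truth fields).
#'
#' @param cases list returned by [generate_cohort()].
#' @param outdir output directory (created if missing).
#' @return The manifest as a tibble, invisibly.
#' @export
write_cohort <- function(cases, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  rows <- purrr::imap(cases, function(cs, id) {
    paths <- purrr::imap_chr(cs$images, function(img, mod) {
      fp <- file.path(outdir, sprintf("%s_%s.nii.gz", id, mod))
      write_volume(img, fp)
      fp
    })
    roi_fp <- file.path(outdir, sprintf("%s_roi.nii.gz", id))
    write_volume(cs$roi, roi_fp)
    tibble(case_id = id, label = cs$label,
           pet = paths[["PET"]], ct = paths[["CT"]],
           t1 = paths[["T1"]], t2fs = paths[["T2FS"]], roi = roi_fp,
           necrotic_fraction = cs$truth$necrotic_fraction,
           suvmax = cs$truth$suvmax)
  })
  manifest <- dplyr::bind_rows(rows)
  write.csv(manifest, file.path(outdir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
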