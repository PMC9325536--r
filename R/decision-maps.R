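#' Cohort feature-map normalizer
#'
#' The cohort mean and population SD of each selected ROI feature, used to
#' normalize the corresponding voxel-wise feature maps of every patient so
#' that backprojected coefficients apply in the same standardized space
#' the model was fitted in.
#'
#' @param cohort_table cohort feature table.
#' @param selected_features features entering the final model.
#' @return A tibble of class `feature_normalizer`: `feature`, `mu`,
#'   `sigma`.
#' @export
fit_normalizer <- function(cohort_table, selected_features) {
  miss <- setdiff(selected_features, names(cohort_table))
  if (length(miss))
    stop("features missing from the cohort table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  out <- tibble(
    feature = selected_features,
    mu = vapply(selected_features, function(f) mean(cohort_table[[f]]),
                numeric(1), USE.NAMES = FALSE),
    sigma = vapply(selected_features, function(f) pop_sd(cohort_table[[f]]),
                   numeric(1), USE.NAMES = FALSE))
  if (any(out$sigma <= the_eps))
    stop("zero cohort SD for: ",
         paste(out$feature[out$sigma <= the_eps], collapse = ", "),
         call. = FALSE)
  class(out) <- c("feature_normalizer", class(out))
  out
}

#' Normalize feature maps with cohort statistics
#'
#' Voxel-wise affine transform `z = (x - mu) / sigma` per feature. Because
#' the transform is affine and aggregation is the mean, the ROI mean of a
#' normalized map equals the patient's z-scored ROI feature.
#'
#' @param mapset a `feature_map_set`.
#' @param normalizer a [fit_normalizer()] result. Map names are matched by
#'   stripping the modality prefix from the normalizer's feature names.
#' @return A `feature_map_set` containing only the normalized maps (named
#'   by the normalizer's feature names).
#' @export
normalize_maps <- function(mapset, normalizer) {
  stopifnot(inherits(mapset, "feature_map_set"))
  prefix <- paste0(mapset$modality, "_")
  wanted <- normalizer$feature[startsWith(normalizer$feature, prefix)]
  local_names <- sub(prefix, "", wanted, fixed = TRUE)
  miss <- setdiff(local_names, names(mapset$maps))
  if (length(miss))
    stop("maps missing for features: ", paste(miss, collapse = ", "),
         call. = FALSE)
  maps <- purrr::map2(local_names, wanted, function(ln, fn) {
    row <- normalizer[normalizer$feature == fn, ]
    (mapset$maps[[ln]] - row$mu) / row$sigma
  })
  names(maps) <- wanted
  mapset$maps <- maps
  mapset$normalized <- TRUE
  mapset
}

#' Backproject model coefficients into a Radiomic Decision Map
#'
#' The per-voxel decision value is the linear decision function applied to
#' the normalized voxel-wise features: `DV(v) = sum_p beta_p z_p(v) +
#' beta0`. Because the ROI feature is the mean of the map and the decision
#' function is linear, the ROI mean of the decision map equals the
#' decision function of the aggregated features exactly (on the
#' aggregation grid), so the map preserves the model's probabilistic
#' output. Coefficients of non-mappable (shape) features contribute a
#' per-patient scalar offset.
#'
#' @param model a `logistic_model_spec` (after [split_mappable()] if it
#'   contains shape features).
#' @param zmaps normalized maps from [normalize_maps()] — a single
#'   `feature_map_set` or a list covering all mappable model features
#'   (multi-modality models).
#' @param roi optional mask volume (defaults to the map set's ROI).
#' @param g_prime named numeric vector of the patient's non-mappable
#'   feature values, already z-scored with the model scaling.
#' @param patient_id identifier stored in the map.
#' @return An object of class `decision_map`: `values` (3D array, NA
#'   outside the ROI), `mean_dv`, `nonmappable_offset`, `probability`,
#'   `spacing_mm`, `origin_mm`, `patient_id`.
#' @export
backproject <- function(model, zmaps, roi = NULL,
                        g_prime = setNames(numeric(0), character(0)),
                        patient_id = NA_character_) {
  stopifnot(inherits(model, "logistic_model_spec"))
  if (inherits(zmaps, "feature_map_set")) zmaps <- list(zmaps)
  all_maps <- do.call(c, lapply(zmaps, `[[`, "maps"))
  feats <- names(model$beta)
  miss <- setdiff(feats, names(all_maps))
  if (length(miss))
    stop("no normalized map for model feature(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(all_maps), feats)
  if (is.null(roi)) roi <- zmaps[[1]]$roi
  m <- mask_array(roi)
  dv <- array(model$beta0, dim(m))
  for (f in feats) dv <- dv + model$beta[[f]] * all_maps[[f]]
  dv[!m] <- NA_real_
  if (length(model$beta_prime)) {
    miss_p <- setdiff(names(model$beta_prime), names(g_prime))
    if (length(miss_p))
      stop("g_prime missing: ", paste(miss_p, collapse = ", "),
           call. = FALSE)
    offset <- sum(model$beta_prime * g_prime[names(model$beta_prime)])
  } else offset <- 0
  mean_dv <- mean(dv[m])
  structure(list(
    patient_id = patient_id,
    values = dv,
    spacing_mm = zmaps[[1]]$spacing_mm,
    origin_mm = zmaps[[1]]$origin_mm,
    mean_dv = mean_dv,
    nonmappable_offset = offset,
    probability = logistic(mean_dv + offset),
    model_features = feats
  ), class = "decision_map")
}

#' @export
print.decision_map <- function(x, ...) {
  cat(sprintf(
    "<decision_map> %s: mean DV %.4f, offset %.4f, probability %.4f\n",
    x$patient_id, x$mean_dv, x$nonmappable_offset, x$probability))
  invisible(x)
}

#' Class-1 probability encoded by a decision map
#'
#' The logistic transform of the ROI-mean decision value plus the
#' non-mappable offset; equal (to numerical precision) to the tabular
#' model's predicted probability when map aggregation and model share the
#' same grid.
#'
#' @param dmap a `decision_map`.
#' @return A probability in (0, 1).
#' @export
probability_from_map <- function(dmap) {
  stopifnot(inherits(dmap, "decision_map"))
  logistic(dmap$mean_dv + dmap$nonmappable_offset)
}

#' Write a decision map as NIfTI with a JSON sidecar
#'
#' Voxels outside the ROI are written as NaN (the decision value is
#' undefined there). The sidecar records the mean decision value, the
#' non-mappable offset and the encoded probability.
#'
#' @param dmap a `decision_map`.
#' @param path output `.nii.gz` path; the sidecar replaces the extension
#'   with `.json`.
#' @return `path`, invisibly.
#' @export
write_decision_map <- function(dmap, path) {
  vol <- image_volume(dmap$values, dmap$spacing_mm, dmap$origin_mm,
                      "OTHER", "ARBITRARY")
  write_volume(vol, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(patient_id = dmap$patient_id, mean_dv = dmap$mean_dv,
         nonmappable_offset = dmap$nonmappable_offset,
         probability = dmap$probability,
         model_features = dmap$model_features),
    side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
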