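test_that("the feature catalog conserves the family counts", {
  cat_all <- feature_catalog()
  expect_equal(nrow(cat_all), 77)
  counts <- table(cat_all$family)
  expect_equal(unname(counts[c("FIRSTORDER", "GLCM", "GLDM", "GLRLM",
                               "NGTDM")]),
               c(18L, 24L, 14L, 16L, 5L), ignore_attr = TRUE)
  expect_false(any(duplicated(catalog_names(cat_all))))
})

test_that("a constant ROI yields zero contrast and skewness maps", {
  v <- array(2.5, c(9, 9, 9))
  m <- array(FALSE, c(9, 9, 9)); m[3:7, 3:7, 3:7] <- TRUE
  img <- image_volume(v)
  roi <- image_volume(m, modality = "MASK", units = "BINARY")
  disc <- discretize(img, roi,
                     discretization_scheme("FIXED_BIN_SIZE", bin_width = 1))
  ms <- extract_feature_maps(disc, img, roi, window = 3)
  expect_equal(length(ms$maps), 77)
  expect_true(all(ms$maps$GLCM_Contrast[m] == 0))
  expect_true(all(ms$maps$FIRSTORDER_Skewness[m] == 0))
  expect_error(extract_feature_maps(disc, img, roi, window = 4), "odd")
})

test_that("window features match the single-region oracle on random windows", {
  sm <- small_pet_maps()
  lev <- sm$disc$values
  raw <- sm$case$images$PET$values
  roi <- sm$case$roi$values
  L <- attr(sm$disc, "n_levels")
  vox <- which(roi)
  withr::with_seed(4, sel <- sample(vox, 25))
  for (v in sel) {
    ctr <- arrayInd(v, dim(roi))[1, ]
    reg <- oracle_window_region(lev, raw, roi, ctr, 5)
    ofe <- oracle_features(reg$lev, reg$raw, L, prod(sm$case$roi$spacing_mm))
    eng <- vapply(sm$maps$maps, function(a) a[v], numeric(1))
    expect_equal(unname(eng), unname(ofe), tolerance = 1e-6)
  }
})

test_that("texture matrices match hand-enumerated counts", {
  # 1D strip [1,2,1,2]: ordered neighbour pairs (1,2) x3 and (2,1) x3
  lev <- array(c(1L, 2L, 1L, 2L), c(4, 1, 1))
  m <- array(TRUE, c(4, 1, 1))
  tm <- texture_matrices(lev, m, n_levels = 2)
  expect_equal(tm$glcm[1, 2], 3)
  expect_equal(tm$glcm[2, 1], 3)
  expect_equal(tm$glcm[1, 1], 0)
  expect_equal(tm$glcm[2, 2], 0)
  # along the strip each voxel is a maximal run of length 1; the 12
  # off-axis directions cut every voxel into a length-1 run as well
  expect_equal(tm$glrlm[1, 1], 2 * 13)
  expect_equal(tm$glrlm[2, 1], 2 * 13)

  # constant 2x2x1 block, one gray level: a single nonzero GLCM cell;
  # runs of length 2 along x, y and the two in-plane diagonals
  levc <- array(1L, c(2, 2, 1))
  mc <- array(TRUE, c(2, 2, 1))
  tmc <- texture_matrices(levc, mc, n_levels = 1)
  expect_equal(sum(tmc$glcm > 0), 1)
  expect_equal(tmc$glcm[1, 1], sum(tmc$glcm))
  expect_equal(tmc$glrlm[1, 2], 2 + 2 + 1 + 1)
  expect_equal(tmc$glrlm[1, 1], 2 + 2 + 9 * 4)
})

test_that("NGTDM of a single-voxel-different cube matches the oracle", {
  lev <- array(1L, c(3, 3, 3))
  lev[2, 2, 2] <- 2L
  m <- array(TRUE, c(3, 3, 3))
  tm <- texture_matrices(lev, m, n_levels = 2)
  # centre voxel: 26 neighbours all level 1 -> s_2 = |2 - 1| = 1
  expect_equal(tm$ngtdm$s[2], 1)
  expect_equal(tm$ngtdm$n[2], 1)
  # busyness/contrast of the engine match the exhaustive neighbour-sum
  # oracle on the same cube
  raw <- array(as.numeric(lev), dim(lev))
  ofe <- oracle_features(lev, raw, 2, 1)
  eng <- rdmap:::cpp_region_features(as.integer(lev), as.numeric(raw),
                                     as.logical(m), dim(lev), 2L, 1)
  expect_equal(eng[73:77], unname(ofe[73:77]), tolerance = 1e-12)
})

test_that("map ROI means reproduce the aggregation identity", {
  sm <- small_pet_maps()
  agg <- aggregate_mean(sm$maps)
  expect_equal(nrow(agg), 77)
  m <- sm$case$roi$values
  # independent arithmetic mean
  direct <- vapply(sm$maps$maps, function(a) sum(a[m]) / sum(m), numeric(1))
  expect_equal(agg$value, unname(direct), tolerance = 1e-12)

  # constant map aggregates to the constant; single-voxel ROI to the voxel
  ms1 <- sm$maps
  ms1$maps <- list(FIRSTORDER_Mean = array(4.2, dim(m)))
  expect_equal(aggregate_mean(ms1)$value, 4.2)
  single <- array(FALSE, dim(m))
  single[which(m)[1]] <- TRUE
  roi1 <- image_volume(single, sm$case$roi$spacing_mm, modality = "MASK",
                       units = "BINARY")
  a1 <- aggregate_mean(sm$maps, roi1)
  expect_equal(a1$value[1], sm$maps$maps[[1]][which(single)])
})

test_that("windows with fewer than 2 in-ROI voxels inherit a neighbour", {
  v <- array(rnorm(13^3), c(13, 13, 13))
  m <- array(FALSE, c(13, 13, 13))
  m[2:6, 2:6, 2:6] <- TRUE
  m[12, 12, 12] <- TRUE  # isolated voxel: its 3-window holds only itself
  img <- image_volume(v)
  roi <- image_volume(m, modality = "MASK", units = "BINARY")
  disc <- discretize(img, roi,
                     discretization_scheme("FIXED_BIN_SIZE", bin_width = 1))
  ms <- extract_feature_maps(disc, img, roi, window = 3)
  for (a in ms$maps) expect_true(all(is.finite(a[m])))
})

test_that("shape features return the 14 standard descriptors", {
  cs <- small_case()
  s <- shape_features(cs$roi)
  expect_equal(nrow(s), 14)
  expect_true(all(startsWith(s$name, "SHAPE_")))
  expect_equal(s$value[s$feature == "VoxelVolume"],
               sum(cs$roi$values) * prod(cs$roi$spacing_mm))
})

test_that("a digital ball is nearly spherical and isotropic", {
  n <- 25; r <- 10; c0 <- (n - 1) / 2
  co <- (0:(n - 1))
  ball <- outer(outer((co - c0)^2, (co - c0)^2, `+`), (co - c0)^2, `+`) <=
    r^2
  s <- shape_features(image_volume(ball, c(1, 1, 1), modality = "MASK",
                                   units = "BINARY"))
  val <- function(f) s$value[s$feature == f]
  expect_gte(val("Sphericity"), 0.95)
  expect_lte(val("Sphericity"), 1.0)
  expect_gte(val("Elongation"), 0.95)
  expect_lte(val("Elongation"), 1.0)
  expect_equal(val("Maximum3DDiameter"), 20, tolerance = 0.05)
  expect_equal(val("MeshVolume"), 4 / 3 * pi * r^3, tolerance = 0.05)
})

test_that("a one-voxel mask degenerates without error", {
  m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
  s <- shape_features(image_volume(m, c(2, 2, 2), modality = "MASK",
                                   units = "BINARY"))
  val <- function(f) s$value[s$feature == f]
  expect_equal(val("VoxelVolume"), 8)
  expect_equal(val("Maximum3DDiameter"), 0)
  expect_equal(val("MajorAxisLength"), 0)
})

test_that("masks touching the grid border still yield a closed surface", {
  # internal padding: a block in the grid corner must mesh identically to
  # the same block centred in a larger grid (no truncated faces)
  m_corner <- array(FALSE, c(8, 8, 8))
  m_corner[1:4, 1:4, 1:4] <- TRUE
  m_center <- array(FALSE, c(12, 12, 12))
  m_center[5:8, 5:8, 5:8] <- TRUE
  s1 <- shape_features(image_volume(m_corner, c(1, 1, 1),
                                    modality = "MASK", units = "BINARY"))
  s2 <- shape_features(image_volume(m_center, c(1, 1, 1),
                                    modality = "MASK", units = "BINARY"))
  val <- function(s, f) s$value[s$feature == f]
  expect_gt(val(s1, "SurfaceArea"), 0)
  expect_gt(val(s1, "MeshVolume"), 0)
  expect_equal(val(s1, "SurfaceArea"), val(s2, "SurfaceArea"),
               tolerance = 1e-9)
  expect_equal(val(s1, "MeshVolume"), val(s2, "MeshVolume"),
               tolerance = 1e-9)
})

test_that("feature maps resample onto a common grid consistently", {
  sm <- small_pet_maps()
  ms <- sm$maps
  ms$maps <- ms$maps[c("FIRSTORDER_Mean", "GLCM_Contrast")]
  out <- resample_maps_common_grid(ms, spacing_mm = 2)
  # native grid already 2 mm: unchanged inside the ROI
  expect_equal(out$maps$FIRSTORDER_Mean[out$roi$values],
               ms$maps$FIRSTORDER_Mean[ms$roi$values], tolerance = 1e-9)

  fine <- resample_maps_common_grid(ms, spacing_mm = 1)
  expect_equal(fine$spacing_mm, c(1, 1, 1))
  m_new <- fine$roi$values
  expect_true(all(is.na(fine$maps$FIRSTORDER_Mean[!m_new])))
  # smooth phantom: ROI mean preserved within 2%
  for (f in names(ms$maps)) {
    old_mean <- mean(ms$maps[[f]][ms$roi$values])
    new_mean <- mean(fine$maps[[f]][m_new])
    expect_lt(abs(new_mean - old_mean) / max(abs(old_mean), 1e-8), 0.02)
  }
  # constant map survives resampling exactly
  msc <- ms
  msc$maps <- list(FIRSTORDER_Mean = ifelse(ms$roi$values, 1.5, NA_real_))
  finec <- resample_maps_common_grid(msc, spacing_mm = 1)
  expect_equal(unique(finec$maps$FIRSTORDER_Mean[finec$roi$values]), 1.5,
               tolerance = 1e-9)
})

test_that("a four-modality case yields 308 maps and a 168-long vector", {
  cs <- small_case()
  tab2 <- case_features(cs, modalities = c("PET", "CT"), window = 5)
  expect_equal(ncol(tab2) - 1, 2 * 77 + 14)  # label column excluded
})
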