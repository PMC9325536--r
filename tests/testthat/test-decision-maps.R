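# shared pipeline fixture: small PET cohort, fitted spec, normalized maps
dm_fixture <- function() {
  fixture("dm_fixture", function() {
    sc <- small_cohort_tab()
    feats <- c("PET_FIRSTORDER_Mean", "PET_GLCM_JointEntropy",
               "PET_NGTDM_Busyness", "SHAPE_Elongation")
    spec <- split_mappable(fit_lasso_logistic(sc$tab, features = feats,
                                              C = 10))
    normalizer <- fit_normalizer(sc$tab, names(spec$beta))
    list(cases = sc$cases, tab = sc$tab, spec = spec,
         normalizer = normalizer)
  })
}

case_zmaps <- function(fx, i) {
  cs <- fx$cases[[i]]
  disc <- discretize(cs$images$PET, cs$roi, default_schemes(cs, "PET")$PET)
  ms <- extract_feature_maps(disc, cs$images$PET, cs$roi, window = 5)
  normalize_maps(ms, fx$normalizer)
}

g_prime_scaled <- function(fx, i) {
  sc <- fx$spec$scaling
  row <- sc[sc$feature == "SHAPE_Elongation", ]
  setNames((fx$tab$SHAPE_Elongation[i] - row$mean) / row$sd,
           "SHAPE_Elongation")
}

test_that("the normalizer computes cohort statistics with population SD", {
  tb <- tibble::tibble(patient_id = c("a", "b"), label = c(0L, 1L),
                       f = c(0, 2))
  nz <- fit_normalizer(tb, "f")
  expect_equal(nz$mu, 1)
  expect_equal(nz$sigma, 1)  # population SD of {0, 2}
  tb$flat <- 5
  expect_error(fit_normalizer(tb, "flat"), "zero cohort SD")
  expect_error(fit_normalizer(tb, "missing"), "missing")
})

test_that("the normalizer reproduces cohort z-scores exactly", {
  sc <- small_cohort_tab()
  feats <- c("PET_FIRSTORDER_Mean", "PET_GLCM_Contrast")
  nz <- fit_normalizer(sc$tab, feats)
  for (f in feats) {
    z <- (sc$tab[[f]] - nz$mu[nz$feature == f]) / nz$sigma[nz$feature == f]
    expect_lt(abs(mean(z)), 1e-10)
    expect_equal(sqrt(mean((z - mean(z))^2)), 1, tolerance = 1e-10)
  }
})

test_that("normalized map means equal the z-scored ROI features", {
  fx <- dm_fixture()
  zm <- case_zmaps(fx, 1)
  m <- zm$roi$values
  for (f in names(fx$spec$beta)) {
    g <- fx$tab[[f]][1]
    row <- fx$normalizer[fx$normalizer$feature == f, ]
    expect_equal(mean(zm$maps[[f]][m]), unname((g - row$mu) / row$sigma),
                 tolerance = 1e-10)
  }
})

test_that("map normalization is affine, not idempotent", {
  fx <- dm_fixture()
  cs <- fx$cases[[1]]
  disc <- discretize(cs$images$PET, cs$roi, default_schemes(cs, "PET")$PET)
  ms <- extract_feature_maps(disc, cs$images$PET, cs$roi, window = 5)
  z1 <- normalize_maps(ms, fx$normalizer)
  # constant map at mu maps to zero
  f <- fx$normalizer$feature[1]
  row <- fx$normalizer[1, ]
  msc <- ms
  msc$maps[[sub("^PET_", "", f)]][] <- row$mu
  zc <- normalize_maps(msc, fx$normalizer)
  expect_true(all(zc$maps[[f]][cs$roi$values] == 0))
  # applying the transform twice is not the identity
  z2 <- z1
  z2$maps[[f]] <- (z1$maps[[f]] - row$mu) / row$sigma
  expect_false(isTRUE(all.equal(z2$maps[[f]][cs$roi$values],
                                z1$maps[[f]][cs$roi$values])))
})

test_that("backprojection is the linear decision function at every voxel", {
  fx <- dm_fixture()
  zm <- case_zmaps(fx, 2)
  m <- zm$roi$values
  dm <- backproject(fx$spec, zm, g_prime = g_prime_scaled(fx, 2),
                    patient_id = "case_02")
  # beta = 0: map constant at the intercept
  spec0 <- fx$spec
  spec0$beta[] <- 0
  dm0 <- backproject(spec0, zm, g_prime = g_prime_scaled(fx, 2))
  expect_true(all(dm0$values[m] == spec0$beta0))
  # a single unit coefficient reproduces the z-map
  spec1 <- fx$spec
  spec1$beta[] <- 0
  spec1$beta[[1]] <- 1
  spec1$beta0 <- 0
  spec1$beta_prime <- setNames(numeric(0), character(0))
  dm1 <- backproject(spec1, zm)
  f1 <- names(spec1$beta)[1]
  expect_equal(dm1$values[m], zm$maps[[f1]][m], tolerance = 1e-12)
  # feature-name mismatch is an error
  bad <- fx$spec
  names(bad$beta)[1] <- "PET_GLCM_DoesNotExist"
  expect_error(backproject(bad, zm), "no normalized map")
})

test_that("the ROI mean of the map equals the tabular decision function", {
  fx <- dm_fixture()
  for (i in c(1, 3, 5)) {
    zm <- case_zmaps(fx, i)
    dm <- backproject(fx$spec, zm, g_prime = g_prime_scaled(fx, i))
    sc <- fx$spec$scaling[match(names(fx$spec$beta),
                                fx$spec$scaling$feature), ]
    zg <- (as.numeric(fx$tab[i, names(fx$spec$beta)]) - sc$mean) / sc$sd
    expect_lt(abs(dm$mean_dv - (sum(fx$spec$beta * zg) + fx$spec$beta0)),
              1e-6)
    # probability identity against the tabular model
    p_tab <- predict(fx$spec, fx$tab[i, ])
    expect_lt(abs(probability_from_map(dm) - p_tab), 1e-6)
  }
})

test_that("probability_from_map is the logistic of mean DV plus offset", {
  dm <- structure(list(mean_dv = 0, nonmappable_offset = 0),
                  class = "decision_map")
  expect_equal(probability_from_map(dm), 0.5)
  dm$mean_dv <- 10
  expect_gt(probability_from_map(dm), 0.9999)
  dm$mean_dv <- -3; dm$nonmappable_offset <- 3
  expect_equal(probability_from_map(dm), 0.5)
})

test_that("decision maps are linear in the model coefficients", {
  fx <- dm_fixture()
  zm <- case_zmaps(fx, 4)
  m <- zm$roi$values
  s1 <- fx$spec; s1$beta_prime <- setNames(numeric(0), character(0))
  s2 <- s1
  withr::with_seed(3, s2$beta[] <- rnorm(length(s2$beta)))
  s12 <- s1
  s12$beta <- s1$beta + s2$beta
  d1 <- backproject(s1, zm); d2 <- backproject(s2, zm)
  d12 <- backproject(s12, zm)
  expect_equal(d12$values[m], d1$values[m] + d2$values[m] - s1$beta0,
               tolerance = 1e-10)
})

test_that("perturbing one voxel moves DV by beta / sigma exactly", {
  fx <- dm_fixture()
  cs <- fx$cases[[1]]
  disc <- discretize(cs$images$PET, cs$roi, default_schemes(cs, "PET")$PET)
  ms <- extract_feature_maps(disc, cs$images$PET, cs$roi, window = 5)
  f <- names(fx$spec$beta)[1]
  fl <- sub("^PET_", "", f)
  v <- which(cs$roi$values)[10]
  delta <- 0.37
  ms2 <- ms
  ms2$maps[[fl]][v] <- ms$maps[[fl]][v] + delta
  z1 <- normalize_maps(ms, fx$normalizer)
  z2 <- normalize_maps(ms2, fx$normalizer)
  gp <- g_prime_scaled(fx, 1)
  d1 <- backproject(fx$spec, z1, g_prime = gp)
  d2 <- backproject(fx$spec, z2, g_prime = gp)
  sigma <- fx$normalizer$sigma[fx$normalizer$feature == f]
  expect_equal(d2$values[v] - d1$values[v],
               fx$spec$beta[[f]] * delta / sigma, tolerance = 1e-10)
})

test_that("outside-ROI voxels are NaN in exported decision maps", {
  fx <- dm_fixture()
  zm <- case_zmaps(fx, 1)
  dm <- backproject(fx$spec, zm, g_prime = g_prime_scaled(fx, 1),
                    patient_id = "case_01")
  expect_true(all(is.na(dm$values[!zm$roi$values])))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "rdm.nii.gz")
  write_decision_map(dm, path)
  expect_true(file.exists(path))
  side <- jsonlite::read_json(file.path(dir, "rdm.json"))
  expect_equal(side$probability, dm$probability, tolerance = 1e-8)
  back <- read_volume(path)
  expect_equal(back$values[zm$roi$values], dm$values[zm$roi$values],
               tolerance = 1e-5)
})

test_that("model specs survive a JSON round trip", {
  fx <- dm_fixture()
  dir <- withr::local_tempdir()
  path <- file.path(dir, "model.json")
  write_model_spec(fx$spec, path)
  back <- read_model_spec(path)
  expect_equal(back$beta, fx$spec$beta, tolerance = 1e-12)
  expect_equal(back$beta_prime, fx$spec$beta_prime, tolerance = 1e-12)
  expect_equal(back$beta0, fx$spec$beta0, tolerance = 1e-12)
  expect_equal(back$scaling$mean, fx$spec$scaling$mean, tolerance = 1e-12)
  p1 <- predict(fx$spec, fx$tab)
  p2 <- predict(back, fx$tab)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("tidy and glance summarize fitted objects coherently", {
  fx <- dm_fixture()
  td <- tidy(fx$spec)
  expect_equal(nrow(td), 1 + length(fx$spec$beta) +
                 length(fx$spec$beta_prime))
  expect_true(all(c("term", "estimate", "mappable") %in% names(td)))
  gl <- glance(fx$spec)
  expect_equal(gl$n_features, 4)
  tb <- gaussian_table(n = 30, k = 3, informative = 1, effect = 2,
                       seed = 61)
  bm <- bag(tb, c("f1", "f2"), C = 1, n_boot = 20, seed = 2)
  expect_s3_class(tidy(bm), "tbl_df")
  expect_s3_class(glance(bm), "tbl_df")
  expect_s3_class(autoplot(bm), "ggplot")
  cvc <- cv_config(n_repeats = 3, n_folds = 5, seed = 1)
  gs <- grid_search(tb, cv = cvc, grid_C = 1, max_k = 1)
  expect_s3_class(autoplot(gs), "ggplot")
  fxm <- dm_fixture()
  zm <- case_zmaps(fxm, 1)
  dmp <- backproject(fxm$spec, zm, g_prime = g_prime_scaled(fxm, 1))
  expect_s3_class(autoplot(dmp), "ggplot")
})
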