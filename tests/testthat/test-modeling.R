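test_that("ASB reproduces its closed-form anchor values", {
  y <- c(rep(1L, 19), rep(0L, 32))
  expect_equal(asb(y, rep(0.5, 51))$asb, 0.75)
  expect_equal(asb(y, as.numeric(y))$asb, 1)
  expect_equal(asb(y, 1 - y)$asb, 0)
  expect_equal(asb(y, rep(0, 51))$asb, 0.5)  # majority class is 0
  res <- asb(y, rep(0.5, 51))
  expect_equal(res$sb_c1, 0.25)
  expect_equal(res$sb_c0, 0.25)
  expect_error(asb(rep(1L, 5), rep(0.5, 5)), "both classes")
  expect_error(asb(c(0L, 1L), c(0.5, 1.2)), "probabilities")
})

test_that("the LASSO fit recovers a separating feature with the right sign", {
  tb <- gaussian_table(n = 30, k = 3, informative = 1, effect = 4,
                       prevalence = 0.5, seed = 21)
  spec <- fit_lasso_logistic(tb, C = 10)
  expect_gt(spec$beta[["f1"]], 0)
  p <- predict(spec, tb)
  expect_gt(asb(tb$label, p)$asb, 0.9)
})

test_that("extreme regularization shrinks every coefficient to zero", {
  tb <- gaussian_table(n = 30, k = 4, informative = 2, effect = 2,
                       seed = 23)
  spec <- fit_lasso_logistic(tb, C = 1e-6)
  expect_true(all(spec$beta == 0))
})

test_that("the solver agrees with an independent penalized optimizer", {
  tb <- gaussian_table(n = 20, k = 3, informative = 1, effect = 1.5,
                       seed = 25)
  C <- 2
  spec <- fit_lasso_logistic(tb, C = C)
  # independent route: proximal gradient descent on the same objective
  X <- as.matrix(tb[paste0("f", 1:3)])
  X <- sweep(sweep(X, 2, colMeans(X)),
             2, apply(X, 2, function(v) sqrt(mean((v - mean(v))^2))), "/")
  y <- tb$label
  n <- length(y)
  w <- ifelse(y == 1, n / (2 * sum(y == 1)), n / (2 * sum(y == 0)))
  alpha <- 1 / C
  beta <- rep(0, 3); b0 <- 0; step <- 0.05
  for (it in 1:20000) {
    eta <- drop(X %*% beta) + b0
    pr <- 1 / (1 + exp(-eta))
    g <- drop(t(X) %*% (w * (pr - y)))
    g0 <- sum(w * (pr - y))
    beta_new <- beta - step * g
    beta_new <- sign(beta_new) * pmax(abs(beta_new) - step * alpha, 0)
    b0 <- b0 - step * g0
    if (max(abs(beta_new - beta)) < 1e-10) { beta <- beta_new; break }
    beta <- beta_new
  }
  expect_equal(unname(spec$beta), unname(beta), tolerance = 1e-4)
  expect_equal(spec$beta0, unname(b0), tolerance = 1e-4)
})

test_that("the solver agrees with glmnet at matched regularization", {
  tb <- gaussian_table(n = 40, k = 4, informative = 2, effect = 1.5,
                       seed = 27)
  for (C in c(0.5, 5)) {
    spec <- fit_lasso_logistic(tb, C = C)
    X <- as.matrix(tb[paste0("f", 1:4)])
    Xs <- sweep(sweep(X, 2, colMeans(X)), 2,
                apply(X, 2, function(v) sqrt(mean((v - mean(v))^2))), "/")
    y <- tb$label
    n <- length(y)
    w <- ifelse(y == 1, n / (2 * sum(y == 1)), n / (2 * sum(y == 0)))
    g <- glmnet::glmnet(Xs, y, family = "binomial", alpha = 1,
                        lambda = 1 / (C * n), weights = w,
                        standardize = FALSE, thresh = 1e-12)
    expect_equal(unname(spec$beta), as.numeric(g$beta), tolerance = 1e-3)
    expect_equal(spec$beta0, as.numeric(g$a0), tolerance = 1e-3)
  }
})

test_that("forward selection finds the informative feature first", {
  cv <- cv_config(n_repeats = 5, n_folds = 5, seed = 1)
  hits <- vapply(1:12, function(s) {
    tb <- gaussian_table(n = 40, k = 10, informative = 1, effect = 2.5,
                         prevalence = 0.45, seed = 100 + s)
    path <- forward_select(tb, C = 1, cv = cv, max_k = 1)
    path$feature[1] == "f1"
  }, logical(1))
  expect_gte(sum(hits), 11)
})

test_that("forward selection on pure noise stays near the 0.75 baseline", {
  tb <- gaussian_table(n = 40, k = 6, informative = 0, seed = 31)
  cv <- cv_config(n_repeats = 10, n_folds = 5, seed = 2)
  path <- forward_select(tb, C = 1, cv = cv, max_k = 1)
  expect_equal(nrow(path), 1)
  expect_lt(abs(path$mean_asb[1] - 0.75), 0.1)
})

test_that("feature scaling inside CV matters: a deliberate leak shifts scores", {
  tb <- gaussian_table(n = 30, k = 2, informative = 1, effect = 1.5,
                       seed = 33)
  y <- as.integer(tb$label)
  X <- as.matrix(tb[c("f1", "f2")])
  cv <- cv_config(n_repeats = 5, n_folds = 5, seed = 4)
  folds <- rdmap:::make_folds(y, cv)
  proper <- rdmap:::cv_asb_subset(X, y, C = 1, folds)
  # leak: scale once with the full-cohort statistics, then "rescale" inside
  # folds (centring/SD of pre-scaled columns uses test-fold information)
  leak_vals <- numeric(0)
  for (fold in folds) {
    for (k in sort(unique(fold))) {
      test <- which(fold == k); train <- setdiff(seq_along(y), test)
      mu <- colMeans(X); s <- apply(X, 2, function(v) sqrt(mean((v - mean(v))^2)))
      Xs <- sweep(sweep(X, 2, mu), 2, s, "/")
      w <- ifelse(y[train] == 1,
                  length(train) / (2 * sum(y[train] == 1)),
                  length(train) / (2 * sum(y[train] == 0)))
      fit <- rdmap:::cpp_lasso_logistic(Xs[train, , drop = FALSE],
                                        as.numeric(y[train]), w, 1, 1e-4,
                                        100L)
      p <- 1 / (1 + exp(-(drop(Xs[test, , drop = FALSE] %*% fit$beta) +
                            fit$beta0)))
      leak_vals <- c(leak_vals, rdmap:::asb_value(y[test], p))
    }
  }
  expect_false(isTRUE(all.equal(mean(proper), mean(leak_vals),
                                tolerance = 1e-10)))
})

test_that("the default C grid spans 0.1 to 100 in ten log-spaced values", {
  g <- default_c_grid()
  expect_length(g, 10)
  expect_equal(g[1], 0.1)
  expect_equal(g[10], 100)
  expect_equal(diff(log10(g)), rep(diff(log10(g))[1], 9), tolerance = 1e-12)
})

test_that("grid search picks a dominating configuration and is reproducible", {
  tb <- gaussian_table(n = 40, k = 5, informative = 1, effect = 3,
                       seed = 35)
  cv <- cv_config(n_repeats = 5, n_folds = 5, seed = 6)
  gs1 <- grid_search(tb, cv = cv, grid_C = c(0.5, 5), max_k = 2)
  gs2 <- grid_search(tb, cv = cv, grid_C = c(0.5, 5), max_k = 2)
  expect_identical(gs1$results, gs2$results)
  expect_identical(gs1$selected$C, gs2$selected$C)
  # the strong single feature dominates: selected k = 1 with f1
  expect_equal(gs1$selected$k, 1)
  expect_equal(gs1$selected$features[[1]], "f1")
  expect_true(gs1$selected$mean_asb >=
                gs1$best_mean_asb - gs1$results$sd_asb[
                  which.max(gs1$results$mean_asb)])
})

test_that("the permutation p-value follows the add-one estimator", {
  tb <- gaussian_table(n = 24, k = 3, informative = 1, effect = 4,
                       prevalence = 0.5, seed = 37)
  cv <- cv_config(n_repeats = 3, n_folds = 4, seed = 8)
  gs <- grid_search(tb, cv = cv, grid_C = 1, max_k = 1)
  pt <- permutation_test(tb, cv = cv, grid_C = 1, max_k = 1, n_perm = 9,
                         seed = 9, observed = gs)
  expect_equal(pt$p_value,
               (1 + sum(pt$null_scores >= pt$observed)) / (1 + 9))
  expect_length(pt$null_scores, 9)
  expect_gt(pt$p_value, 0)
  expect_lte(pt$p_value, 1)
  # a strongly separable observed score beats most null permutations
  expect_lt(pt$p_value, 0.5)
})

test_that("bagging without resampling reduces to a single deterministic fit", {
  tb <- gaussian_table(n = 30, k = 3, informative = 1, effect = 2,
                       seed = 41)
  bm <- bag(tb, c("f1", "f2"), C = 1, n_boot = 1, seed = 1,
            resample = FALSE)
  single <- fit_lasso_logistic(tb, c("f1", "f2"), C = 1)
  expect_equal(bm$mean_spec$beta, single$beta, tolerance = 1e-10)
  expect_equal(bm$mean_spec$beta0, single$beta0, tolerance = 1e-10)
  expect_true(all(bm$coef_summary$sd == 0))
})

test_that("the OOB fraction matches its closed-form expectation", {
  tb <- gaussian_table(n = 51, k = 2, informative = 1, effect = 1,
                       prevalence = 19 / 51, seed = 43)
  y <- as.integer(tb$label)
  boots <- rdmap:::stratified_boot_indices(y, 1000, seed = 3)
  oob_frac <- vapply(boots, function(ix)
    1 - length(unique(ix)) / length(y), numeric(1))
  # E[OOB fraction] = (1 - 1/n)^n ~ 0.366 at n = 51 (per stratum)
  expect_lt(abs(mean(oob_frac) - (1 - 1 / 51)^51), 0.03)
  # stratification preserves class counts in every resample
  expect_true(all(vapply(boots, function(ix) sum(y[ix] == 1), integer(1)) ==
                    19L))
})

test_that("bagged coefficients vary across bootstraps on noisy cohorts", {
  tb <- gaussian_table(n = 40, k = 3, informative = 2, effect = 1.2,
                       seed = 45)
  bm <- bag(tb, paste0("f", 1:3), C = 1, n_boot = 100, seed = 5)
  sds <- bm$coef_summary$sd[bm$coef_summary$term %in% c("f1", "f2")]
  expect_true(all(sds > 0))
  expect_true(all(bm$oob_auc_samples >= 0 & bm$oob_auc_samples <= 1,
                  na.rm = TRUE))
  g <- glance(bm)
  expect_equal(g$oob_auc_mean, mean(bm$oob_auc_samples, na.rm = TRUE))
})

test_that("biomarker OOB AUC behaves at its reference points", {
  tb <- gaussian_table(n = 40, k = 2, seed = 47)
  tb$perfect <- as.numeric(tb$label)
  res <- biomarker_oob_auc(tb, "perfect", n_boot = 50, seed = 7)
  expect_equal(res$oob_auc_mean, 1)
  # label-independent biomarkers: average over independent draws (a single
  # n = 40 draw carries ~0.09 sampling SD in its own AUC)
  null_means <- withr::with_seed(48, vapply(1:10, function(i) {
    tb$noise <- rnorm(40)
    biomarker_oob_auc(tb, "noise", n_boot = 50, seed = 7)$oob_auc_mean
  }, numeric(1)))
  expect_lt(abs(mean(null_means) - 0.5), 0.05)
  tb$flat <- 1
  expect_warning(res3 <- biomarker_oob_auc(tb, "flat", n_boot = 10,
                                           seed = 7), "degenerate")
  expect_equal(res3$oob_auc_mean, 0.5)
})

test_that("the internal rank-based AUC matches pROC, ties included", {
  withr::with_seed(49, {
    y <- rep(c(0L, 1L), c(20, 15))
    s <- round(rnorm(35), 1)  # rounding forces ties
  })
  expect_equal(rdmap:::cpp_auc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("PET biomarkers follow their definitions on a noise-free phantom", {
  p <- small_params(noise_sd_by_modality = c(PET = 0, CT = 0, T1 = 0,
                                             T2FS = 0))
  cs <- generate_case(p, 1, 51)
  bm <- pet_biomarkers(cs$images$PET, cs$roi)
  vv <- prod(cs$roi$spacing_mm) / 1000
  expect_equal(bm$ATV, sum(cs$roi$values) * vv)
  expect_equal(bm$SUVmax, cs$truth$suvmax)
  # the necrotic core (SUV 1) sits below 40% of SUVmax: MTV is the rim
  rim <- sum(cs$images$PET$values[cs$roi$values] == cs$truth$suvmax)
  expect_equal(bm$MTV, rim * vv)
  expect_equal(bm$TLG, bm$MTV * cs$truth$suvmax)
})

test_that("surrogate sub-volumes recover the necrotic compartment", {
  p <- small_params(noise_sd_by_modality = c(PET = 0, CT = 0, T1 = 0,
                                             T2FS = 0))
  cs <- generate_case(p, 1, 53)
  sf <- surrogate_features(cs$images$PET, cs$images$CT, cs$roi)
  expect_lt(abs(sf$HYPODENSE_20HU_UNION_INACTIVE_FDG_rV -
                  cs$truth$necrotic_fraction_measured), 0.05)
  # set algebra: union >= components >= intersection
  expect_gte(sf$HYPODENSE_20HU_UNION_INACTIVE_FDG_rV,
             max(sf$HYPODENSE_20HU_rV, sf$INACTIVE_FDG_rV))
  expect_lte(sf$HYPODENSE_20HU_INTERSECT_INACTIVE_FDG_rV,
             min(sf$HYPODENSE_20HU_rV, sf$INACTIVE_FDG_rV))
  expect_true(all(dplyr::select(sf, dplyr::ends_with("_rV")) >= 0 &
                    dplyr::select(sf, dplyr::ends_with("_rV")) <= 1))
})

test_that("a ROI entirely below the thresholds has relative volume 1", {
  v <- array(FALSE, c(8, 8, 8)); v[3:6, 3:6, 3:6] <- TRUE
  roi <- image_volume(v, c(2, 2, 2), modality = "MASK", units = "BINARY")
  pet <- image_volume(array(0.1, c(8, 8, 8)), c(2, 2, 2), modality = "PET",
                      units = "SUV")
  pet$values[4, 4, 4] <- 10  # SUVmax voxel; everything else is cold
  ct <- image_volume(array(-50, c(8, 8, 8)), c(2, 2, 2), modality = "CT",
                     units = "HU")
  sf <- surrogate_features(pet, ct, roi)
  expect_equal(sf$HYPODENSE_20HU_rV, 1)
  expect_equal(sf$HYPODENSE_30HU_rV, 1)
  expect_equal(sf$HYPODENSE_20HU_UNION_INACTIVE_FDG_rV, 1)
})

test_that("distillation reproduces a sparse teacher on its own features", {
  tb <- gaussian_table(n = 40, k = 4, informative = 1, effect = 3,
                       seed = 55)
  teacher <- fit_lasso_logistic(tb, features = "f1", C = 5)
  tp <- setNames(predict(teacher, tb), tb$patient_id)
  cv <- cv_config(n_repeats = 5, n_folds = 5, seed = 10)
  # the student sees all candidates, should recover the teacher's feature
  st <- distill(tp, tb, cv = cv, grid_C = c(1, 10), max_k = 2,
                n_boot = 50, seed = 11, target = "continuous")
  expect_true("f1" %in% st$selected$features[[1]])
  expect_gt(st$agreement, 0.99)
  stb <- distill(tp, tb, cv = cv, grid_C = c(1, 10), max_k = 2,
                 n_boot = 50, seed = 11)
  expect_gt(stb$agreement, 0.95)
  expect_equal(nrow(st$comparison), 40)
  expect_error(distill(setNames(rep(0.4, 40), tb$patient_id), tb),
               "one side")
})
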