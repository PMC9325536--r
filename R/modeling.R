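# The supervised pipeline: repeated stratified CV with the ASB metric,
# forward feature selection, C grid search, permutation testing, bootstrap
# aggregation with OOB AUC, conventional biomarkers, surrogate features and
# model distillation.

# run expr with a local RNG state (global .Random.seed restored on exit)
with_seed_local <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Cross-validation configuration
#'
#' Repeated stratified k-fold cross-validation settings (defaults:
#' 200 repeats of 5 folds).
#'
#' @param n_repeats number of CV repetitions.
#' @param n_folds folds per repetition (>= 2).
#' @param stratified stratify folds by class (default `TRUE`; required for
#'   small imbalanced cohorts so every fold contains both classes).
#' @param seed RNG seed for fold assignment.
#' @return A list of class `cv_config`.
#' @export
cv_config <- function(n_repeats = 200, n_folds = 5, stratified = TRUE,
                      seed = 1L) {
  stopifnot(n_repeats >= 1, n_folds >= 2)
  structure(list(n_repeats = as.integer(n_repeats),
                 n_folds = as.integer(n_folds),
                 stratified = isTRUE(stratified),
                 seed = as.integer(seed)),
            class = "cv_config")
}

# fold assignments: list (length n_repeats) of integer vectors in 1..n_folds
make_folds <- function(y, cv) {
  n <- length(y)
  with_seed_local(cv$seed, {
    lapply(seq_len(cv$n_repeats), function(r) {
      fold <- integer(n)
      if (cv$stratified) {
        for (cl in unique(y)) {
          ix <- sample(which(y == cl))
          fold[ix] <- rep_len(seq_len(cv$n_folds), length(ix))
        }
      } else {
        fold[sample.int(n)] <- rep_len(seq_len(cv$n_folds), n)
      }
      fold
    })
  })
}

# z-score columns with training-set statistics (population SD); columns that
# are constant in the training rows carry no information and map to zero
scale_train_test <- function(X, train, test) {
  mu <- colMeans(X[train, , drop = FALSE])
  s <- apply(X[train, , drop = FALSE], 2, pop_sd)
  s[s <= the_eps] <- Inf
  list(train = sweep(sweep(X[train, , drop = FALSE], 2, mu), 2, s, `/`),
       test = sweep(sweep(X[test, , drop = FALSE], 2, mu), 2, s, `/`))
}

# cross-validated ASB of one feature subset: per-fold ASB values pooled
# over repeats; scaling is refit inside every training fold
cv_asb_subset <- function(X, y, C, folds, tol = 1e-4, maxit = 100) {
  vals <- numeric(0)
  n <- length(y)
  wbase <- numeric(n)
  for (fold in folds) {
    for (k in sort(unique(fold))) {
      test <- which(fold == k)
      train <- setdiff(seq_len(n), test)
      ytr <- y[train]; yte <- y[test]
      if (length(unique(ytr)) < 2 || length(unique(yte)) < 2) next
      ss <- scale_train_test(X, train, test)
      w <- ifelse(ytr == 1, length(ytr) / (2 * sum(ytr == 1)),
                  length(ytr) / (2 * sum(ytr == 0)))
      fit <- cpp_lasso_logistic(ss$train, as.numeric(ytr), w,
                                alpha = 1 / C, tol = tol, maxit = maxit)
      p <- logistic(drop(ss$test %*% fit$beta) + fit$beta0)
      vals <- c(vals, asb_value(yte, p))
    }
  }
  vals
}

#' Forward sequential feature selection under repeated stratified CV
#'
#' Greedy wrapper: starting from the empty set, each step adds the
#' candidate that maximizes the mean cross-validated ASB of the grown
#' subset (feature scaling refit inside every training fold). The full
#' path up to `max_k` features is returned.
#'
#' @param table cohort feature table.
#' @param candidates candidate feature names (typically the output of
#'   [reduce_collinearity()]).
#' @param C inverse regularization strength for the inner LASSO fits.
#' @param cv a [cv_config()].
#' @param max_k maximum subset size.
#' @return A tibble path: `step`, `feature` (added), `features` (list
#'   column, subset so far), `mean_asb`, `sd_asb`.
#' @export
forward_select <- function(table, candidates = feature_cols(table), C = 1,
                           cv = cv_config(), max_k = 5) {
  y <- as.integer(table$label)
  X <- as.matrix(table[candidates])
  folds <- make_folds(y, cv)
  forward_select_impl(X, y, candidates, C, folds, max_k)
}

forward_select_impl <- function(X, y, candidates, C, folds, max_k) {
  selected <- character(0)
  path <- vector("list", min(max_k, length(candidates)))
  for (step in seq_along(path)) {
    remaining <- setdiff(candidates, selected)
    scores <- vapply(remaining, function(f) {
      cols <- match(c(selected, f), candidates)
      vals <- cv_asb_subset(X[, cols, drop = FALSE], y, C, folds)
      mean(vals)
    }, numeric(1))
    best <- remaining[which.max(scores)]
    selected <- c(selected, best)
    vals <- cv_asb_subset(X[, match(selected, candidates), drop = FALSE],
                          y, C, folds)
    path[[step]] <- tibble(step = step, feature = best,
                           features = list(selected),
                           mean_asb = mean(vals), sd_asb = sd(vals))
  }
  dplyr::bind_rows(path)
}

#' The default LASSO C grid
#'
#' Ten values from 0.1 to 100, equally spaced on a log10 scale.
#'
#' @return Numeric vector of length 10.
#' @export
default_c_grid <- function() 10^seq(log10(0.1), log10(100), length.out = 10)

#' Grid search over regularization strength and subset size
#'
#' For every C in the grid, the forward selection path is evaluated under
#' the same repeated stratified CV folds (shared across C values so
#' configurations are compared on identical resamples). The automatic pick
#' is the most parsimonious configuration within one standard deviation of
#' the best mean ASB: among all (C, k) with
#' `mean ASB >= best mean - 1 SD(best)`, the smallest k, then the
#' smallest C.
#'
#' @inheritParams forward_select
#' @param grid_C candidate C values, default [default_c_grid()].
#' @return An object of class `grid_search_result`: `results` (tibble with
#'   `C`, `k`, `features`, `mean_asb`, `sd_asb`), `selected` (one row),
#'   `best_mean_asb`.
#' @export
grid_search <- function(table, candidates = feature_cols(table),
                        cv = cv_config(), grid_C = default_c_grid(),
                        max_k = 5) {
  stopifnot(length(grid_C) >= 1)
  y <- as.integer(table$label)
  X <- as.matrix(table[candidates])
  folds <- make_folds(y, cv)
  res <- purrr::map(grid_C, function(C) {
    path <- forward_select_impl(X, y, candidates, C, folds, max_k)
    dplyr::mutate(path, C = C, k = .data$step, .before = 1)
  })
  results <- dplyr::select(dplyr::bind_rows(res), "C", "k", "features",
                           "mean_asb", "sd_asb")
  ibest <- which.max(results$mean_asb)
  thr <- results$mean_asb[ibest] - results$sd_asb[ibest]
  ok <- results[results$mean_asb >= thr, ]
  sel <- ok[order(ok$k, ok$C), ][1, ]
  structure(list(results = results, selected = sel,
                 best_mean_asb = results$mean_asb[ibest]),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  s <- x$selected
  cat(sprintf(
    "<grid_search_result> best mean ASB %.3f; selected C = %.3g, k = %d (ASB %.3f +/- %.3f)\n",
    x$best_mean_asb, s$C, s$k, s$mean_asb, s$sd_asb))
  cat("  features:", paste(s$features[[1]], collapse = ", "), "\n")
  invisible(x)
}

#' Label-permutation test of the whole selection pipeline
#'
#' The complete pipeline (forward selection and grid search) is re-run on
#' randomly permuted class labels; the best grid-search mean ASB of each
#' permutation forms the null distribution. The empirical p-value uses the
#' add-one estimator `p = (1 + #{null >= observed}) / (1 + n_perm)`.
#'
#' @inheritParams grid_search
#' @param n_perm number of permutations (default 200).
#' @param seed seed for the permutations.
#' @param observed optionally, a precomputed `grid_search_result` for the
#'   true labels (identical settings); computed when `NULL`.
#' @return An object of class `permutation_result`: `null_scores`,
#'   `observed`, `p_value`, `n_perm`.
#' @export
permutation_test <- function(table, candidates = feature_cols(table),
                             cv = cv_config(), grid_C = default_c_grid(),
                             max_k = 5, n_perm = 200, seed = 1L,
                             observed = NULL) {
  stopifnot(n_perm >= 1)
  if (is.null(observed))
    observed <- grid_search(table, candidates, cv, grid_C, max_k)
  obs <- observed$best_mean_asb
  perms <- with_seed_local(seed, {
    lapply(seq_len(n_perm), function(b) sample(table$label))
  })
  null_scores <- vapply(perms, function(yl) {
    tb <- table
    tb$label <- yl
    grid_search(tb, candidates, cv, grid_C, max_k)$best_mean_asb
  }, numeric(1))
  p <- (1 + sum(null_scores >= obs)) / (1 + n_perm)
  structure(list(null_scores = null_scores, observed = obs, p_value = p,
                 n_perm = n_perm),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> observed ASB %.3f vs %d null runs: p = %.4g\n",
              x$observed, x$n_perm, x$p_value))
  invisible(x)
}

# stratified bootstrap: list of n_boot index vectors (resample within each
# class with replacement, preserving class counts)
stratified_boot_indices <- function(y, n_boot, seed) {
  with_seed_local(seed, {
    lapply(seq_len(n_boot), function(b) {
      unlist(lapply(unique(y), function(cl) {
        ix <- which(y == cl)
        sample(ix, length(ix), replace = TRUE)
      }), use.names = FALSE)
    })
  })
}

#' Bootstrap aggregation of the final model with out-of-bag validation
#'
#' Draws stratified bootstrap resamples, z-scores the features on each
#' resample, fits the LASSO logistic model on the fixed selected subset and
#' records the standardized coefficients plus the ROC AUC on the out-of-bag
#' patients. The final decision function averages the per-bootstrap
#' coefficients (reported with their SD); full-cohort scaling statistics
#' are attached for deployment and decision-map normalization.
#'
#' @param table cohort feature table.
#' @param features the selected feature subset (fixed).
#' @param C inverse regularization strength.
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @param resample set `FALSE` to fit every replicate on the full cohort
#'   (no resampling; OOB AUC undefined).
#' @param y_override optional numeric target overriding `table$label` in
#'   the fits (used for continuous-target distillation).
#' @return An object of class `bagged_model`: `mean_spec`
#'   (a `logistic_model_spec` with averaged coefficients and full-cohort
#'   scaling), `coef_summary` (tibble `term`, `estimate`, `sd`),
#'   `oob_auc_samples`, `oob_auc_mean`, `oob_auc_sd`, `oob_auc_ci95`,
#'   `n_boot`.
#' @export
bag <- function(table, features, C = 1, n_boot = 1000, seed = 1L,
                resample = TRUE, y_override = NULL) {
  y <- as.integer(table$label)
  yfit <- if (is.null(y_override)) as.numeric(y) else as.numeric(y_override)
  X <- as.matrix(table[features])
  n <- length(y)
  boots <- if (resample) stratified_boot_indices(y, n_boot, seed)
           else replicate(n_boot, seq_len(n), simplify = FALSE)
  coefs <- matrix(NA_real_, n_boot, length(features),
                  dimnames = list(NULL, features))
  b0s <- numeric(n_boot)
  aucs <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    ix <- boots[[b]]
    oob <- setdiff(seq_len(n), unique(ix))
    ss <- scale_train_test(X, ix, if (length(oob)) oob else 1L)
    ytr <- yfit[ix]
    ybin <- y[ix]
    w <- ifelse(ybin == 1, length(ybin) / (2 * sum(ybin == 1)),
                length(ybin) / (2 * sum(ybin == 0)))
    fit <- cpp_lasso_logistic(ss$train, ytr, w, alpha = 1 / C,
                              tol = 1e-4, maxit = 100L)
    coefs[b, ] <- fit$beta
    b0s[b] <- fit$beta0
    if (resample && length(oob) > 0 && length(unique(y[oob])) == 2) {
      p <- drop(ss$test %*% fit$beta) + fit$beta0
      aucs[b] <- cpp_auc(p, y[oob])
    }
  }
  full_scaling <- tibble(feature = features,
                         mean = unname(apply(X, 2, mean)),
                         sd = unname(apply(X, 2, pop_sd)))
  mean_spec <- structure(list(
    beta0 = mean(b0s),
    beta = setNames(colMeans(coefs), features),
    beta_prime = setNames(numeric(0), character(0)),
    C = C, scaling = full_scaling, loss = "balanced_cross_entropy",
    converged = TRUE, n_iter = NA_integer_
  ), class = "logistic_model_spec")
  av <- aucs[!is.na(aucs)]
  structure(list(
    mean_spec = mean_spec,
    coef_summary = tibble(
      term = c("(Intercept)", features),
      estimate = c(mean(b0s), colMeans(coefs)),
      sd = c(pop_sd(b0s), apply(coefs, 2, pop_sd))),
    oob_auc_samples = aucs,
    oob_auc_mean = if (length(av)) mean(av) else NA_real_,
    oob_auc_sd = if (length(av)) sd(av) else NA_real_,
    oob_auc_ci95 = if (length(av))
      unname(quantile(av, c(0.025, 0.975))) else c(NA_real_, NA_real_),
    n_boot = n_boot, seed = seed
  ), class = "bagged_model")
}

#' @export
print.bagged_model <- function(x, ...) {
  cat(sprintf("<bagged_model> %d bootstraps; OOB AUC %.3f +/- %.3f\n",
              x$n_boot, x$oob_auc_mean, x$oob_auc_sd))
  invisible(x)
}

#' Out-of-bag ROC AUC of a conventional biomarker
#'
#' Computes the ROC AUC of a raw scalar biomarker on the out-of-bag
#' patients of each bootstrap resample. With the same `seed` and `n_boot`
#' as [bag()] the resamples are identical, giving a paired comparison
#' between the model and the biomarker.
#'
#' @param table cohort feature table containing the biomarker column.
#' @param biomarker column name (e.g. `"ATV"`, `"SUVmax"`, `"MTV"`,
#'   `"TLG"`).
#' @param n_boot,seed bootstrap settings (match the model's for pairing).
#' @return A tibble: `biomarker`, `oob_auc_mean`, `oob_auc_sd`, and the
#'   per-bootstrap AUCs in the `samples` list column.
#' @export
biomarker_oob_auc <- function(table, biomarker, n_boot = 1000, seed = 1L) {
  stopifnot(biomarker %in% names(table))
  y <- as.integer(table$label)
  v <- table[[biomarker]]
  if (pop_sd(v) <= the_eps) {
    warning("degenerate (constant) biomarker: AUC 0.5", call. = FALSE)
    return(tibble(biomarker = biomarker, oob_auc_mean = 0.5,
                  oob_auc_sd = 0, samples = list(rep(0.5, n_boot))))
  }
  boots <- stratified_boot_indices(y, n_boot, seed)
  aucs <- vapply(boots, function(ix) {
    oob <- setdiff(seq_along(y), unique(ix))
    if (length(oob) == 0 || length(unique(y[oob])) < 2) return(NA_real_)
    cpp_auc(v[oob], y[oob])
  }, numeric(1))
  av <- aucs[!is.na(aucs)]
  tibble(biomarker = biomarker, oob_auc_mean = mean(av),
         oob_auc_sd = sd(av), samples = list(aucs))
}

#' Conventional PET biomarkers of a case
#'
#' Anatomical tumor volume (ATV, ml), the maximum standardized uptake
#' value (SUVmax), the metabolic tumor volume (MTV, ml: ROI volume with
#' SUV at or above `threshold_frac` of SUVmax) and total lesion glycolysis
#' (TLG: MTV times its mean SUV).
#'
#' @param pet PET `image_volume` in SUV.
#' @param roi binary mask volume on the same grid.
#' @param threshold_frac MTV threshold as a fraction of SUVmax
#'   (default 0.4).
#' @return A one-row tibble: `ATV`, `SUVmax`, `MTV`, `TLG`.
#' @export
pet_biomarkers <- function(pet, roi, threshold_frac = 0.4) {
  check_same_grid(pet, roi)
  m <- mask_array(roi)
  if (!any(m)) stop("empty ROI", call. = FALSE)
  suv <- pet$values[m]
  vv <- voxel_volume_ml(pet)
  suvmax <- max(suv)
  hot <- suv >= threshold_frac * suvmax
  mtv <- sum(hot) * vv
  tibble(ATV = sum(m) * vv, SUVmax = suvmax, MTV = mtv,
         TLG = mtv * mean(suv[hot]))
}

#' Surrogate sub-volume features from PET and CT
#'
#' Simple interpretable descriptors of the necrotic compartment: the
#' absolute volume V (ml) and relative volume rV = V / ATV of the ROI
#' sub-regions defined by low metabolism (PET below 40% of SUVmax), a
#' hypodense CT signal (below 20 or 30 HU) and their unions and
#' intersections, plus the conventional biomarkers. log10 transforms of
#' every volume-like feature (with volumes floored at 0.01 ml) and of any
#' supplied shape features widen the set.
#'
#' @param pet,ct `image_volume`s on a common grid with `roi`.
#' @param roi binary mask volume.
#' @param shape optional tibble from [shape_features()] whose log10
#'   transforms are appended (negative or zero values are skipped).
#' @param suv_frac,hu_thresholds sub-volume thresholds.
#' @return A one-row wide tibble of surrogate features.
#' @export
surrogate_features <- function(pet, ct, roi, shape = NULL, suv_frac = 0.4,
                               hu_thresholds = c(20, 30)) {
  check_same_grid(pet, ct); check_same_grid(pet, roi)
  m <- mask_array(roi)
  if (!any(m)) stop("empty ROI", call. = FALSE)
  vv <- voxel_volume_ml(pet)
  atv <- sum(m) * vv
  suv <- pet$values[m]; hu <- ct$values[m]
  inactive <- suv < suv_frac * max(suv)
  subs <- list(INACTIVE_FDG = inactive)
  for (t in hu_thresholds) {
    hypo <- hu < t
    subs[[sprintf("HYPODENSE_%dHU", t)]] <- hypo
    subs[[sprintf("HYPODENSE_%dHU_UNION_INACTIVE_FDG", t)]] <- hypo | inactive
    subs[[sprintf("HYPODENSE_%dHU_INTERSECT_INACTIVE_FDG", t)]] <- hypo & inactive
  }
  out <- tibble(.rows = 1)
  for (nm in names(subs)) {
    V <- sum(subs[[nm]]) * vv
    out[[paste0(nm, "_V")]] <- V
    out[[paste0(nm, "_rV")]] <- V / atv
  }
  bm <- pet_biomarkers(pet, roi, threshold_frac = suv_frac)
  out <- dplyr::bind_cols(out, bm)
  logd <- function(x) log10(pmax(x, 0.01))
  for (nm in c(paste0(names(subs), "_V"), "ATV", "MTV", "TLG"))
    out[[paste0("LOG10_", nm)]] <- logd(out[[nm]])
  out$LOG10_SUVmax <- log10(out$SUVmax)
  if (!is.null(shape)) {
    for (i in seq_len(nrow(shape))) {
      out[[shape$name[i]]] <- shape$value[i]
      if (is.finite(shape$value[i]) && shape$value[i] > 0)
        out[[paste0("LOG10_", shape$name[i])]] <- log10(shape$value[i])
    }
  }
  out
}

#' Surrogate feature table for a cohort
#'
#' @param cases list of `multimodal_case` objects.
#' @return A tibble: `patient_id`, `label`, surrogate features.
#' @export
surrogate_table <- function(cases) {
  rows <- purrr::imap(cases, function(cs, id) {
    dplyr::bind_cols(
      tibble(patient_id = id, label = cs$label),
      surrogate_features(cs$images$PET, cs$images$CT, cs$roi,
                         shape = shape_features(cs$roi)))
  })
  dplyr::bind_rows(rows)
}

#' Distill a fitted model into a surrogate feature model
#'
#' Trains a simpler "student" logistic model to reproduce the predictions
#' of a fitted "teacher": the teacher's predicted probabilities are
#' binarized at 0.5 into pseudo-labels (the default; `target =
#' "continuous"` keeps the soft probabilities as the fit target while
#' stratifying resamples on the binarized labels) and the identical
#' selection / grid-search / bagging pipeline runs on the surrogate
#' feature set. The agreement between student and teacher probabilities is
#' reported.
#'
#' @param teacher_probs named numeric vector of teacher probabilities, one
#'   per patient (names matching `surrogate_tbl$patient_id`).
#' @param surrogate_tbl table from [surrogate_table()].
#' @inheritParams grid_search
#' @param n_boot,seed bagging settings.
#' @param target binarize the teacher output (default) or keep it
#'   continuous.
#' @return A list of class `distilled_model`: `model` (a `bagged_model`),
#'   `selected` (grid-search row), `agreement` (Pearson correlation),
#'   `comparison` (tibble `patient_id`, `teacher`, `student`).
#' @export
distill <- function(teacher_probs, surrogate_tbl,
                    candidates = feature_cols(surrogate_tbl),
                    cv = cv_config(), grid_C = default_c_grid(), max_k = 5,
                    n_boot = 1000, seed = 1L,
                    target = c("binary", "continuous")) {
  target <- match.arg(target)
  stopifnot(!is.null(names(teacher_probs)))
  tp <- teacher_probs[surrogate_tbl$patient_id]
  if (any(is.na(tp))) stop("teacher probabilities missing for some patients",
                           call. = FALSE)
  pseudo <- as.integer(tp > 0.5)
  if (length(unique(pseudo)) < 2)
    stop("teacher predictions are all on one side of 0.5", call. = FALSE)
  tb <- surrogate_tbl
  tb$label <- pseudo
  gs <- grid_search(tb, candidates, cv, grid_C, max_k)
  sel <- gs$selected
  bm <- bag(tb, sel$features[[1]], C = sel$C, n_boot = n_boot, seed = seed,
            y_override = if (target == "continuous") tp else NULL)
  student <- predict(bm$mean_spec, tb)
  structure(list(model = bm, selected = sel,
                 agreement = cor(tp, student),
                 comparison = tibble(patient_id = tb$patient_id,
                                     teacher = unname(tp), student = student)),
            class = "distilled_model")
}

#' @export
print.distilled_model <- function(x, ...) {
  cat(sprintf("<distilled_model> %d features; teacher-student correlation %.3f\n",
              length(x$selected$features[[1]]), x$agreement))
  invisible(x)
}
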