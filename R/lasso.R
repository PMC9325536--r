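#' Fit an L1-regularized logistic model with balanced loss
#'
#' LASSO logistic regression with cost-sensitive balanced cross-entropy:
#' each patient is weighted inversely to its class frequency, so both
#' classes carry equal total weight regardless of imbalance. `C` is the
#' inverse regularization strength (lower C, stronger shrinkage); the
#' solver is a deterministic proximal-Newton coordinate descent with
#' stopping tolerance `1e-4` and at most 100 iterations. Features are
#' z-scored with training statistics (population SD) before fitting and
#' the statistics are stored in the returned spec, so coefficients live in
#' the standardized space.
#'
#' @param table cohort feature table (`patient_id`, `label`, features).
#' @param features feature subset to use (default: all feature columns).
#' @param C inverse regularization strength (> 0), default 1.
#' @param scaling optional tibble (`feature`, `mean`, `sd`) of
#'   pre-computed standardization statistics; computed from `table` when
#'   `NULL`.
#' @param tol,maxit solver stopping criteria.
#' @return An object of class `logistic_model_spec`: `beta0`, `beta`
#'   (named, standardized space), `beta_prime` (non-mappable subset,
#'   filled by downstream helpers), `C`, `scaling`, `loss`, `converged`,
#'   `n_iter`.
#' @export
fit_lasso_logistic <- function(table, features = feature_cols(table), C = 1,
                               scaling = NULL, tol = 1e-4, maxit = 100) {
  stopifnot(C > 0, length(features) >= 1, all(features %in% names(table)))
  y <- as.integer(table$label)
  if (length(unique(y)) < 2) stop("both classes required", call. = FALSE)
  X <- as.matrix(table[features])
  if (is.null(scaling)) {
    scaling <- tibble(feature = features,
                      mean = unname(apply(X, 2, mean)),
                      sd = unname(apply(X, 2, pop_sd)))
  }
  sc <- scaling[match(features, scaling$feature), ]
  if (any(sc$sd <= the_eps))
    stop("zero-variance feature in the training data", call. = FALSE)
  Xs <- sweep(sweep(X, 2, sc$mean), 2, sc$sd, `/`)
  n <- length(y)
  w <- ifelse(y == 1, n / (2 * sum(y == 1)), n / (2 * sum(y == 0)))
  fit <- cpp_lasso_logistic(Xs, as.numeric(y), w, alpha = 1 / C,
                            tol = tol, maxit = as.integer(maxit))
  if (!fit$converged)
    warning(sprintf("solver did not converge in %d iterations", fit$iter),
            call. = FALSE)
  structure(list(
    beta0 = fit$beta0,
    beta = setNames(as.numeric(fit$beta), features),
    beta_prime = setNames(numeric(0), character(0)),
    C = C, scaling = sc, loss = "balanced_cross_entropy",
    converged = fit$converged, n_iter = fit$iter
  ), class = "logistic_model_spec")
}

#' @export
print.logistic_model_spec <- function(x, ...) {
  nz <- sum(x$beta != 0)
  cat(sprintf("<logistic_model_spec> C = %g, %d/%d nonzero coefficients\n",
              x$C, nz, length(x$beta)))
  invisible(x)
}

#' Predicted class-1 probabilities from a fitted spec
#'
#' @param object a `logistic_model_spec`.
#' @param newdata cohort feature table containing the model's features.
#' @param ... unused.
#' @return Numeric vector of probabilities.
#' @export
predict.logistic_model_spec <- function(object, newdata, ...) {
  beta <- c(object$beta, object$beta_prime)
  feats <- names(beta)
  miss <- setdiff(feats, names(newdata))
  if (length(miss))
    stop("missing features: ", paste(miss, collapse = ", "), call. = FALSE)
  X <- as.matrix(newdata[feats])
  sc <- object$scaling[match(feats, object$scaling$feature), ]
  Xs <- sweep(sweep(X, 2, sc$mean), 2, sc$sd, `/`)
  logistic(drop(Xs %*% beta) + object$beta0)
}

#' Serialize / restore a fitted model spec as JSON
#'
#' Stores the intercept, the named coefficients (mappable and
#' non-mappable), the regularization strength and the standardization
#' statistics the coefficients assume, so a model can be shipped and
#' applied to new patients (or backprojected into decision maps) without
#' the training data.
#'
#' @param spec a `logistic_model_spec`.
#' @param path JSON file path.
#' @return `write_model_spec()` returns `path` invisibly;
#'   `read_model_spec()` returns the restored `logistic_model_spec`.
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "logistic_model_spec"))
  jsonlite::write_json(list(
    beta0 = spec$beta0,
    beta = tibble(feature = names(spec$beta), value = unname(spec$beta)),
    beta_prime = tibble(feature = names(spec$beta_prime),
                        value = unname(spec$beta_prime)),
    C = spec$C, scaling = spec$scaling, loss = spec$loss
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  mj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_coef <- function(df) {
    if (is.null(df) || length(df) == 0 || nrow(as.data.frame(df)) == 0)
      return(setNames(numeric(0), character(0)))
    setNames(as.numeric(df$value), df$feature)
  }
  structure(list(
    beta0 = mj$beta0,
    beta = as_coef(mj$beta),
    beta_prime = as_coef(mj$beta_prime),
    C = mj$C,
    scaling = as_tibble(mj$scaling),
    loss = mj$loss, converged = TRUE, n_iter = NA_integer_
  ), class = "logistic_model_spec")
}

#' Split a fitted spec into mappable and non-mappable coefficients
#'
#' Shape and volume descriptors have no voxel-level counterpart; their
#' coefficients contribute a constant per-patient offset to the decision
#' map rather than a voxel pattern. This helper moves the coefficients of
#' the named non-mappable features from `beta` into `beta_prime` (the
#' scaling table is shared and unchanged).
#'
#' @param spec a `logistic_model_spec`.
#' @param nonmappable feature names without voxel maps; defaults to the
#'   `SHAPE_`-prefixed features.
#' @return The updated `logistic_model_spec`.
#' @export
split_mappable <- function(spec, nonmappable = grep("^SHAPE_",
                                                    names(spec$beta),
                                                    value = TRUE)) {
  all_beta <- c(spec$beta, spec$beta_prime)
  nm <- intersect(nonmappable, names(all_beta))
  spec$beta_prime <- all_beta[nm]
  spec$beta <- all_beta[setdiff(names(all_beta), nm)]
  spec
}
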