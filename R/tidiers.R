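# broom-style tidiers for the fitted objects

#' @rdname tidiers
#' @method tidy logistic_model_spec
#' @export
tidy.logistic_model_spec <- function(x, ...) {
  tibble(term = c("(Intercept)", names(x$beta), names(x$beta_prime)),
         estimate = c(x$beta0, unname(x$beta), unname(x$beta_prime)),
         mappable = c(NA, rep(TRUE, length(x$beta)),
                      rep(FALSE, length(x$beta_prime))))
}

#' @rdname tidiers
#' @method glance logistic_model_spec
#' @export
glance.logistic_model_spec <- function(x, ...) {
  tibble(C = x$C, n_features = length(x$beta) + length(x$beta_prime),
         n_nonzero = sum(c(x$beta, x$beta_prime) != 0),
         converged = x$converged, n_iter = x$n_iter, loss = x$loss)
}

#' Tidiers for rdmap model objects
#'
#' `tidy()` returns per-term (or per-configuration) rows; `glance()`
#' returns a one-row model summary.
#'
#' @param x a fitted rdmap object.
#' @param ... unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy bagged_model
#' @export
tidy.bagged_model <- function(x, ...) x$coef_summary

#' @rdname tidiers
#' @method glance bagged_model
#' @export
glance.bagged_model <- function(x, ...) {
  tibble(n_boot = x$n_boot, oob_auc_mean = x$oob_auc_mean,
         oob_auc_sd = x$oob_auc_sd,
         oob_auc_ci_low = x$oob_auc_ci95[1],
         oob_auc_ci_high = x$oob_auc_ci95[2])
}

#' @rdname tidiers
#' @method tidy grid_search_result
#' @export
tidy.grid_search_result <- function(x, ...) {
  dplyr::mutate(x$results,
                features = purrr::map_chr(.data$features, paste,
                                          collapse = " + "))
}

#' @rdname tidiers
#' @method glance grid_search_result
#' @export
glance.grid_search_result <- function(x, ...) {
  s <- x$selected
  tibble(C = s$C, k = s$k, mean_asb = s$mean_asb, sd_asb = s$sd_asb,
         best_mean_asb = x$best_mean_asb)
}

#' @rdname tidiers
#' @method tidy permutation_result
#' @export
tidy.permutation_result <- function(x, ...) {
  tibble(null_score = x$null_scores)
}

#' @rdname tidiers
#' @method glance permutation_result
#' @export
glance.permutation_result <- function(x, ...) {
  tibble(observed = x$observed, n_perm = x$n_perm, p_value = x$p_value,
         null_mean = mean(x$null_scores), null_max = max(x$null_scores))
}

#' @rdname tidiers
#' @method tidy prune_trace
#' @export
tidy.prune_trace <- function(x, ...) x$removed

#' @rdname tidiers
#' @method glance prune_trace
#' @export
glance.prune_trace <- function(x, ...) {
  tibble(n_removed = nrow(x$removed),
         n_pairwise = sum(x$removed$reason == "PAIRWISE"),
         n_vif = sum(x$removed$reason == "VIF"),
         final_threshold = x$final_threshold)
}
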