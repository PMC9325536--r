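# Unsupervised redundancy removal on the cohort feature table.
#
# A cohort feature table is a wide tibble with identifier columns
# `patient_id` and `label`; every other numeric column is a feature.

feature_cols <- function(table) {
  setdiff(names(table), c("patient_id", "label"))
}

new_prune_trace <- function(removed, final_threshold) {
  structure(list(removed = removed, final_threshold = final_threshold),
            class = "prune_trace")
}

#' @export
print.prune_trace <- function(x, ...) {
  cat(sprintf("<prune_trace> %d features removed (final threshold %.3f)\n",
              nrow(x$removed), x$final_threshold))
  invisible(x)
}

#' Iterative pairwise-Pearson pruning to a non-singular correlation matrix
#'
#' Starting from an absolute-correlation threshold of 1, the threshold is
#' lowered in steps of 0.001 while the Pearson correlation matrix of the
#' surviving features is singular (|determinant| below `det_tol`). At each
#' threshold, every feature pair with |R| above the threshold is processed
#' in decreasing |R| order and the pair member with the highest mean
#' absolute correlation to all other features is removed; correlations are
#' re-evaluated after every removal. Zero-variance features are removed
#' up front (Pearson correlation is undefined for them). Ties are broken
#' toward the later column, deterministically.
#'
#' @param table cohort feature table (`patient_id`, `label`, features).
#' @param det_tol singularity tolerance on the correlation-matrix
#'   determinant.
#' @return A list with `table` (pruned) and `trace` (a `prune_trace`).
#' @export
pairwise_prune <- function(table, det_tol = 1e-12) {
  feats <- feature_cols(table)
  if (length(feats) < 2) stop("need at least 2 features", call. = FALSE)
  X <- as.matrix(table[feats])
  removed <- list()
  zv <- feats[apply(X, 2, function(c) pop_sd(c) <= the_eps)]
  for (f in zv)
    removed[[length(removed) + 1L]] <-
      tibble(feature = f, reason = "PAIRWISE", statistic = NA_real_)
  keep <- setdiff(feats, zv)
  thr <- 1
  repeat {
    if (length(keep) < 2)
      stop("fewer than 2 features survive pruning", call. = FALSE)
    R <- cor(X[, keep, drop = FALSE])
    if (abs(det(R)) > det_tol) break
    thr <- thr - 0.001
    if (thr < 0) break
    repeat {
      R <- cor(X[, keep, drop = FALSE])
      A <- abs(R); diag(A) <- 0
      over <- which(A > thr, arr.ind = TRUE)
      over <- over[over[, 1] < over[, 2], , drop = FALSE]
      if (nrow(over) == 0) break
      top <- over[which.max(A[over]), ]
      pair <- keep[c(top[1], top[2])]
      mean_r <- colMeans(A)[c(top[1], top[2])]
      # remove the member with the highest mean |R|; tie -> later column
      drop_ix <- if (mean_r[2] >= mean_r[1]) 2 else 1
      drop_f <- pair[drop_ix]
      removed[[length(removed) + 1L]] <-
        tibble(feature = drop_f, reason = "PAIRWISE",
               statistic = unname(A[top[1], top[2]]))
      keep <- setdiff(keep, drop_f)
      if (length(keep) < 2) break
    }
  }
  trace <- new_prune_trace(
    if (length(removed)) dplyr::bind_rows(removed)
    else tibble(feature = character(), reason = character(),
                statistic = numeric()),
    thr)
  list(table = table[c(intersect(names(table), c("patient_id", "label")), keep)],
       trace = trace)
}

#' Variance inflation factor of one feature
#'
#' `VIF = 1 / (1 - R^2)` where `R^2` is the coefficient of determination of
#' the least-squares regression (with intercept) of the feature on all
#' other features in the table. Returns `Inf` when the feature is an exact
#' linear combination of the others.
#'
#' @param table cohort feature table.
#' @param feature feature column name.
#' @return The VIF (>= 1 up to numerical tolerance).
#' @export
vif <- function(table, feature) {
  feats <- feature_cols(table)
  stopifnot(feature %in% feats)
  if (length(feats) < 2) stop("need at least 2 features", call. = FALSE)
  if (nrow(table) <= length(feats))
    stop("VIF undefined: need more patients than features", call. = FALSE)
  y <- table[[feature]]
  X <- as.matrix(table[setdiff(feats, feature)])
  fit <- stats::lm.fit(cbind(1, X), y)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  if (r2 >= 1 - the_eps) return(Inf)
  1 / (1 - r2)
}

#' Iterative VIF pruning
#'
#' Removes the feature with the highest VIF, one per iteration, until the
#' maximum VIF over the surviving features is below the threshold
#' (default 10). Ties break toward the later column.
#'
#' @param table cohort feature table (pairwise-pruned first, so VIFs are
#'   finite).
#' @param threshold VIF threshold.
#' @return A list with `table` and `trace`.
#' @export
vif_prune <- function(table, threshold = 10) {
  keep <- feature_cols(table)
  removed <- list()
  repeat {
    if (length(keep) < 2) break
    sub <- table[c("label", keep)]
    vifs <- vapply(keep, function(f) vif(sub, f), numeric(1))
    mx <- max(vifs)
    if (mx < threshold) break
    drop_f <- keep[max(which(vifs == mx))]
    removed[[length(removed) + 1L]] <-
      tibble(feature = drop_f, reason = "VIF", statistic = mx)
    keep <- setdiff(keep, drop_f)
  }
  trace <- new_prune_trace(
    if (length(removed)) dplyr::bind_rows(removed)
    else tibble(feature = character(), reason = character(),
                statistic = numeric()),
    threshold)
  list(table = table[c(intersect(names(table), c("patient_id", "label")), keep)],
       trace = trace)
}

#' Full multicollinearity reduction
#'
#' [pairwise_prune()] followed by [vif_prune()], with a combined trace.
#'
#' @inheritParams vif_prune
#' @param det_tol passed to [pairwise_prune()].
#' @return A list with `table` and `trace`.
#' @export
reduce_collinearity <- function(table, threshold = 10, det_tol = 1e-12) {
  s1 <- pairwise_prune(table, det_tol = det_tol)
  s2 <- vif_prune(s1$table, threshold = threshold)
  trace <- new_prune_trace(dplyr::bind_rows(s1$trace$removed, s2$trace$removed),
                           s1$trace$final_threshold)
  list(table = s2$table, trace = trace)
}
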