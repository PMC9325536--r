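#' Average stratified Brier score (ASB)
#'
#' A calibration-aware accuracy score giving equal importance to both
#' classes: the Brier score (mean squared error between outcome and
#' predicted probability) is computed separately within class 1 and class 0
#' and `ASB = 1 - (SB_C0 + SB_C1) / 2`. Anchor values: a perfect model
#' scores 1, a model that always predicts the wrong class with certainty
#' scores 0, a constant 0.5 predictor scores 0.75, and a dummy model
#' predicting the majority class with certainty scores 0.5.
#'
#' @param y binary outcome vector (0/1), both classes present.
#' @param p predicted probabilities of class 1, in `[0, 1]`.
#' @return A one-row tibble: `sb_c1`, `sb_c0`, `asb`.
#' @export
asb <- function(y, p) {
  stopifnot(length(y) == length(p))
  if (any(p < 0 | p > 1)) stop("probabilities must be in [0, 1]", call. = FALSE)
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("y must be binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2)
    stop("both classes must be present to stratify", call. = FALSE)
  sb1 <- mean((y[y == 1] - p[y == 1])^2)
  sb0 <- mean((y[y == 0] - p[y == 0])^2)
  tibble(sb_c1 = sb1, sb_c0 = sb0, asb = 1 - (sb0 + sb1) / 2)
}

asb_value <- function(y, p) {
  sb1 <- mean((y[y == 1] - p[y == 1])^2)
  sb0 <- mean((y[y == 0] - p[y == 0])^2)
  1 - (sb0 + sb1) / 2
}
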