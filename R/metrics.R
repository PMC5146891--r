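#' Misclassification rate (0-1 loss)
#'
#' @param y true labels.
#' @param yhat predicted labels of the same length.
#' @return Fraction of positions where `yhat != y`.
#' @export
misclassification <- function(y, yhat) {
  if (!length(y)) stopf("empty input")
  if (length(y) != length(yhat)) stopf("length mismatch")
  mean(as.character(yhat) != as.character(y))
}

#' Sensitivity and specificity of a binary prediction
#'
#' Sensitivity = TP / (TP + FN); specificity = TN / (TN + FP). A component
#' whose reference class is absent from `y` is undefined and returned as
#' `NA` with a warning, never silently 0.
#'
#' @param y true binary labels.
#' @param yhat predicted labels.
#' @param positive the positive-class label.
#' @return Named numeric vector `c(sensitivity, specificity)`.
#' @export
sens_spec <- function(y, yhat, positive) {
  y <- as.character(y); yhat <- as.character(yhat)
  if (length(y) != length(yhat)) stopf("length mismatch")
  pos <- y == positive
  sens <- if (!any(pos)) {
    warnf("positive class absent from y: sensitivity undefined")
    NA_real_
  } else {
    mean(yhat[pos] == positive)
  }
  spec <- if (all(pos)) {
    warnf("negative class absent from y: specificity undefined")
    NA_real_
  } else {
    mean(yhat[!pos] != positive)
  }
  c(sensitivity = sens, specificity = spec)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Rows are grouped by quantiles of the predicted probability (deciles by
#' default; ties fall to the lower group). The statistic is
#' `sum_g (O_g - E_g)^2 / (n_g * pibar_g * (1 - pibar_g))` with `O_g` the
#' observed positives, `pibar_g` the mean predicted probability and
#' `E_g = n_g * pibar_g`; the p-value is the chi-square upper tail on
#' `groups - 2` degrees of freedom. A group whose mean probability is
#' exactly 0 or 1 contributes an undefined term: it is skipped and the
#' degrees of freedom reduced accordingly (reported via a message).
#'
#' @param probabilities predicted positive-class probabilities in `[0, 1]`.
#' @param y binary outcome coded 0/1 (or a two-level factor, second level
#'   positive).
#' @param groups number of probability groups; default 10 (deciles).
#' @return List with `statistic`, `p_value` and `df`.
#' @export
hosmer_lemeshow <- function(probabilities, y, groups = 10L) {
  p <- as.numeric(probabilities)
  if (any(p < 0 | p > 1)) stopf("probabilities must lie in [0, 1]")
  if (is.factor(y)) y <- as.integer(y == levels(y)[2])
  if (!all(y %in% c(0, 1))) stopf("y must be binary 0/1")
  if (length(p) != length(y)) stopf("length mismatch")
  if (groups < 3) stopf("groups must be >= 3 (degrees of freedom = groups - 2)")
  br <- unname(stats::quantile(p, probs = seq_len(groups - 1) / groups, type = 7))
  g <- 1L + vapply(p, function(v) sum(v > br), numeric(1))
  stat <- 0
  used <- 0L
  skipped <- 0L
  for (gg in unique(g)) {
    idx <- g == gg
    n_g <- sum(idx)
    pibar <- mean(p[idx])
    if (pibar <= 0 || pibar >= 1) {
      skipped <- skipped + 1L
      next
    }
    O <- sum(y[idx])
    E <- n_g * pibar
    stat <- stat + (O - E)^2 / (n_g * pibar * (1 - pibar))
    used <- used + 1L
  }
  if (skipped > 0) {
    message(sprintf("hosmer_lemeshow: %d degenerate group(s) skipped", skipped))
  }
  df <- used - 2L
  if (df < 1) stopf("too few usable groups (%d) for the test", used)
  list(statistic = stat, p_value = stats::pchisq(stat, df = df, lower.tail = FALSE), df = df)
}

#' Brier score
#'
#' Mean squared difference between the predicted positive-class probability
#' and the binary outcome; lower is better calibrated.
#'
#' @param probabilities predicted positive-class probabilities.
#' @param y binary outcome coded 0/1 (or two-level factor, second level
#'   positive).
#' @return The score in `[0, 1]`.
#' @export
brier <- function(probabilities, y) {
  if (is.factor(y)) y <- as.integer(y == levels(y)[2])
  if (!all(y %in% c(0, 1))) stopf("y must be binary 0/1")
  if (length(probabilities) != length(y)) stopf("length mismatch")
  mean((as.numeric(probabilities) - y)^2)
}

#' Out-of-bag Brier score of a random forest
#'
#' The Brier score computed from the forest's out-of-bag vote fractions for
#' the positive class against the training labels. OOB vote fractions are
#' frequencies, not probabilities, but are the standard calibration proxy
#' for forests. Rows never out of bag (possible at tiny `ntree`) are
#' excluded with a message.
#'
#' @param model a random-forest `classifier_model` from
#'   [fit_random_forest()].
#' @param positive positive-class label; default the second class.
#' @return The OOB Brier score.
#' @export
oob_brier <- function(model, positive = NULL) {
  stopifnot(inherits(model, "classifier_model"))
  if (model$family != "random_forest") stopf("OOB votes exist only for random forests")
  votes <- model$oob_votes
  if (is.null(positive)) positive <- model$classes[2]
  keep <- is.finite(votes[, positive])
  if (any(!keep)) {
    message(sprintf("oob_brier: %d row(s) never out of bag excluded", sum(!keep)))
  }
  y <- as.integer(as.character(model$oob_y)[keep] == positive)
  brier(votes[keep, positive], y)
}
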