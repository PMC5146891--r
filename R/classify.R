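#' Fit a (multinomial) logistic-regression classifier
#'
#' Dichotomous responses are fitted by maximum likelihood through
#' `stats::glm(family = binomial)`; responses with more than two classes
#' through `nnet::multinom`. Perfect separation is left to the backend's
#' convergence policy; any fitting warnings are recorded on the returned
#' model under `$notes`.
#'
#' @param train completed `labeled_table` (no missing predictor cells, at
#'   least two classes present).
#' @return A `classifier_model` exposing class probabilities via
#'   [predict_labels()].
#' @export
fit_logistic <- function(train) {
  stopifnot(inherits(train, "labeled_table"))
  if (anyNA(train$x)) stopf("training table has missing cells; impute first")
  y <- droplevels(train$y)
  if (nlevels(y) < 2) stopf("need >= 2 response classes")
  df <- data.frame(train$x, .y = y, check.names = FALSE)
  notes <- character()
  fit <- withCallingHandlers(
    {
      if (nlevels(y) == 2) {
        stats::glm(.y ~ ., data = df, family = stats::binomial())
      } else {
        nnet::multinom(.y ~ ., data = df, trace = FALSE)
      }
    },
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  structure(
    list(family = "logistic", fit = fit, classes = levels(y),
         features = names(train$x), notes = notes),
    class = "classifier_model"
  )
}

#' Fit a random-forest classifier
#'
#' An ensemble of `ntree` CART trees, each grown on a bootstrap resample
#' with `mtry` candidate predictors per split (default `sqrt(p)`).
#' Out-of-bag vote fractions are recorded per training row for OOB-based
#' calibration scoring.
#'
#' @param train completed `labeled_table`.
#' @param ntree number of trees (>= 1); 5000 mirrors the reference setting,
#'   500 is a practical default.
#' @param mtry predictors tried per split; default `floor(sqrt(p))`.
#' @param seed integer seed (bootstrap and split randomness).
#' @return A `classifier_model` carrying the ensemble and the OOB vote
#'   matrix (`$oob_votes`, rows summing to 1).
#' @export
fit_random_forest <- function(train, ntree = 500L, mtry = NULL, seed = 1L) {
  stopifnot(inherits(train, "labeled_table"))
  if (anyNA(train$x)) stopf("training table has missing cells; impute first")
  if (ntree < 1) stopf("ntree must be >= 1")
  y <- droplevels(train$y)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(train$x))))
  fit <- with_seed(
    derive_seed(seed, 808L),
    randomForest::randomForest(
      x = as.data.frame(train$x), y = y,
      ntree = as.integer(ntree), mtry = as.integer(mtry)
    )
  )
  structure(
    list(family = "random_forest", fit = fit, classes = levels(y),
         features = names(train$x), oob_votes = fit$votes, oob_y = y),
    class = "classifier_model"
  )
}

#' @export
print.classifier_model <- function(x, ...) {
  cat(sprintf(
    "<classifier_model> %s over %d features, classes: %s\n",
    x$family, length(x$features), paste(x$classes, collapse = ", ")
  ))
  invisible(x)
}

#' Class probabilities for new rows
#'
#' @param model a `classifier_model`.
#' @param test completed `labeled_table` (or data.frame of predictors).
#' @return Numeric matrix, one row per test row, one column per class,
#'   rows summing to 1.
#' @export
predict_proba <- function(model, test) {
  stopifnot(inherits(model, "classifier_model"))
  newx <- if (inherits(test, "labeled_table")) test$x else as.data.frame(test)
  missing_cols <- setdiff(model$features, names(newx))
  if (length(missing_cols)) {
    stopf("test schema lacks training column(s): %s", paste(missing_cols, collapse = ", "))
  }
  newx <- newx[model$features]
  if (model$family == "logistic" && length(model$classes) == 2) {
    p2 <- stats::predict(model$fit, newdata = newx, type = "response")
    pr <- cbind(1 - p2, p2)
  } else if (model$family == "logistic") {
    pr <- stats::predict(model$fit, newdata = newx, type = "probs")
    if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1)
  } else {
    pr <- stats::predict(model$fit, newdata = newx, type = "prob")
  }
  pr <- as.matrix(pr)
  colnames(pr) <- model$classes
  rownames(pr) <- NULL
  pr
}

#' Predict labels, pooling over multiple completed datasets if needed
#'
#' For a single model, probabilities come straight from [predict_proba()].
#' For a list of models (one per completed dataset of a multiple-imputation
#' run), each model scores its paired test table (or the shared one) and
#' the class-probability matrices are averaged before the argmax; ties go
#' to the smallest class index. With one model the pooled path equals the
#' single-model path exactly.
#'
#' @param model_or_models a `classifier_model` or list of them.
#' @param test a completed `labeled_table`, or a list of them paired with
#'   the models.
#' @return List with `labels` (factor) and `prob` (averaged probability
#'   matrix).
#' @export
predict_labels <- function(model_or_models, test) {
  models <- if (inherits(model_or_models, "classifier_model")) list(model_or_models) else model_or_models
  tests <- if (inherits(test, "labeled_table") || is.data.frame(test)) {
    rep(list(test), length(models))
  } else {
    test
  }
  stopifnot(length(models) == length(tests))
  probs <- predict_proba(models[[1]], tests[[1]])
  if (length(models) > 1) {
    for (i in 2:length(models)) probs <- probs + predict_proba(models[[i]], tests[[i]])
    probs <- probs / length(models)
  }
  idx <- apply(probs, 1, which.max) # which.max ties -> smallest index
  labels <- factor(models[[1]]$classes[idx], levels = models[[1]]$classes)
  list(labels = labels, prob = probs)
}
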