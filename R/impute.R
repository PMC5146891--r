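#' Mean imputation
#'
#' Every missing predictor cell, in training and test alike, is replaced by
#' the mean of the observed values of that column in the training fold.
#' Training statistics are never contaminated by test rows. Level-coded
#' columns receive the arithmetic mean unrounded by default (downstream
#' classifiers accept numeric inputs); set `round_levels = TRUE` to round
#' half-up to the nearest admissible level.
#'
#' @param train training `labeled_table`.
#' @param test optional test `labeled_table` with the same schema.
#' @param round_levels round imputed values in level-coded columns.
#' @return List with completed `train` and (if supplied) `test` tables.
#' @export
mean_impute <- function(train, test = NULL, round_levels = FALSE) {
  stopifnot(inherits(train, "labeled_table"))
  means <- vapply(names(train$x), function(nm) {
    obs <- train$x[[nm]][!is.na(train$x[[nm]])]
    if (!length(obs)) stopf("column '%s' is fully missing in the training fold", nm)
    mean(obs)
  }, numeric(1))
  fill <- function(tab) {
    for (nm in names(tab$x)) {
      idx <- is.na(tab$x[[nm]])
      if (any(idx)) {
        v <- means[[nm]]
        if (round_levels && train$schema[[nm]]$kind != "continuous") v <- floor(v + 0.5)
        tab$x[[nm]][idx] <- v
      }
    }
    tab
  }
  out <- list(train = fill(train))
  if (!is.null(test)) out$test <- fill(test)
  out
}

# Scaled co-observed Euclidean distances from one (scaled) row to a block
# of (scaled) reference rows. Rows sharing no observed predictor get Inf.
row_distances <- function(target, ref) {
  obs_t <- !is.na(target)
  d2 <- sweep(ref, 2, target, "-")^2
  obs <- !is.na(d2)
  d2[!obs] <- 0
  shared <- rowSums(obs)
  d <- sqrt(rowSums(d2))
  d[shared == 0] <- Inf
  d
}

# Fill missing cells of `tab` using neighbours drawn from `ref` (training
# rows). `exclude_self` removes reference row i when filling tab row i
# (used when tab and ref are the same table).
knn_fill <- function(tab, ref, k, scale_sd, train_means, exclude_self = FALSE) {
  ref_s <- sweep(as.matrix(ref$x), 2, scale_sd, "/")
  tab_s <- sweep(as.matrix(tab$x), 2, scale_sd, "/")
  for (i in which(rowSums(is.na(tab$x)) > 0)) {
    miss_cols <- which(is.na(as.numeric(tab$x[i, ])))
    d <- row_distances(tab_s[i, ], ref_s)
    if (exclude_self) d[i] <- Inf
    for (j in miss_cols) {
      donors <- which(!is.na(ref$x[[j]]) & is.finite(d))
      if (!length(donors)) {
        tab$x[i, j] <- train_means[j]
        next
      }
      donors <- donors[order(d[donors], donors)]
      take <- utils::head(donors, k)
      tab$x[i, j] <- mean(ref$x[take, j])
    }
  }
  tab
}

#' k-nearest-neighbour imputation
#'
#' A missing cell is filled with the mean of its column's observed values
#' among the k nearest rows, where distance is Euclidean over co-observed
#' predictors after unit-variance scaling fitted on the training fold. Test
#' rows take their neighbours exclusively from training rows. When `k` is
#' `NULL` it is selected by 3-fold cross-validation on the training fold,
#' minimizing the downstream classifier's misclassification (logistic
#' regression by default); ties go to the smallest k. A cell whose column no
#' neighbour observes falls back to the training-column mean.
#'
#' @param train training `labeled_table`.
#' @param test optional test `labeled_table`.
#' @param k neighbourhood size, or `NULL` to select from `k_grid`.
#' @param k_grid candidate sizes for selection.
#' @param seed integer seed (selection folds).
#' @param select_fit,select_predict downstream fitter and label-predictor
#'   used during k selection; defaults wrap [fit_logistic()] and
#'   [predict_labels()].
#' @return List with completed `train`, completed `test` (if supplied), and
#'   the `k` used.
#' @export
knn_impute <- function(train, test = NULL, k = NULL, k_grid = c(1, 3, 5, 10),
                       seed = 1L, select_fit = fit_logistic,
                       select_predict = function(m, tab) predict_labels(m, tab)$labels) {
  stopifnot(inherits(train, "labeled_table"))
  scale_sd <- vapply(names(train$x), function(nm) {
    obs <- train$x[[nm]][!is.na(train$x[[nm]])]
    s <- if (length(obs) > 1) stats::sd(obs) else 0
    if (!is.finite(s) || s == 0) 1 else s
  }, numeric(1))
  train_means <- vapply(names(train$x), function(nm) {
    obs <- train$x[[nm]][!is.na(train$x[[nm]])]
    if (!length(obs)) stopf("column '%s' is fully missing in the training fold", nm)
    mean(obs)
  }, numeric(1))

  if (is.null(k)) {
    n <- nrow(train$x)
    folds <- with_seed(derive_seed(seed, 404L), sample(rep_len(1:3, n)))
    feasible <- sort(unique(as.integer(k_grid)))
    err <- vapply(feasible, function(kk) {
      fold_err <- vapply(1:3, function(f) {
        tr <- table_rows(train, folds != f)
        te <- table_rows(train, folds == f)
        comp <- tryCatch(
          knn_impute(tr, te, k = kk, seed = seed),
          error = function(e) NULL
        )
        if (is.null(comp)) return(NA_real_)
        pred <- tryCatch({
          mod <- select_fit(comp$train)
          select_predict(mod, comp$test)
        }, error = function(e) NULL)
        if (is.null(pred)) return(NA_real_)
        mean(as.character(pred) != as.character(te$y))
      }, numeric(1))
      mean(fold_err, na.rm = TRUE)
    }, numeric(1))
    if (all(is.na(err))) stopf("k selection failed for every candidate")
    k <- feasible[which.min(err)]
  }

  out <- list(train = knn_fill(train, train, k, scale_sd, train_means, exclude_self = TRUE))
  if (!is.null(test)) out$test <- knn_fill(test, train, k, scale_sd, train_means)
  out$k <- as.integer(k)
  out
}

#' Random-forest proximity imputation of the training fold
#'
#' Missing cells are seeded with the column median (mode for level-coded
#' columns), then iteratively refined: a supervised forest is grown on the
#' completed data, pairwise proximities (the fraction of trees in which two
#' rows share a terminal node) are computed, and each originally-missing
#' cell is replaced by the proximity-weighted mean of its column's observed
#' values. Test rows are deliberately not handled here: at evaluation time
#' they receive training-mean imputation instead.
#'
#' @param train training `labeled_table` (response required: the forests
#'   are supervised).
#' @param iterations proximity-update iterations; default 5.
#' @param ntree trees per imputation forest; default 100 (independent of
#'   the evaluation forests).
#' @param seed integer seed.
#' @return Completed training `labeled_table`.
#' @export
rf_proximity_impute <- function(train, iterations = 5L, ntree = 100L, seed = 1L) {
  stopifnot(inherits(train, "labeled_table"))
  if (nlevels(droplevels(train$y)) < 2) stopf("degenerate forest: single response class")
  if (ntree < 1) stopf("ntree must be >= 1")
  if (!anyNA(train$x)) return(train)
  x <- as.data.frame(train$x)
  y <- droplevels(train$y)
  completed <- with_seed(derive_seed(seed, 505L), {
    out <- NULL
    # rfImpute prints per-iteration OOB summaries; keep the run quiet
    utils::capture.output(out <- randomForest::rfImpute(x, y, iter = iterations, ntree = ntree))
    out
  })
  out <- train
  out$x <- completed[, -1, drop = FALSE] # first column is the response
  names(out$x) <- names(train$x)
  out
}

# Draw completions for the missing cells of one column given fitted
# conditional models; `draw = FALSE` returns the conditional mean / modal
# class instead of a stochastic draw.
impute_column_from_model <- function(fit, kind, rows_x, draw = TRUE) {
  if (kind == "continuous_lm") {
    mu <- stats::predict(fit$model, newdata = rows_x)
    if (draw) mu + stats::rnorm(length(mu), sd = fit$sigma) else mu
  } else {
    pr <- stats::predict(fit$model, newdata = rows_x, type = "probs")
    if (is.null(dim(pr))) pr <- cbind(1 - pr, pr)
    lv <- fit$levels
    if (draw) {
      idx <- apply(pr, 1, function(p) sample.int(length(lv), 1, prob = p))
    } else {
      idx <- apply(pr, 1, which.max)
    }
    as.numeric(lv[idx])
  }
}

fit_conditional <- function(col_name, data, schema) {
  others <- setdiff(names(data), col_name)
  fml <- stats::as.formula(paste0("`", col_name, "` ~ ", paste(sprintf("`%s`", others), collapse = " + ")))
  kind <- schema[[col_name]]$kind
  if (kind == "continuous" || kind == "ordinal") {
    fit <- stats::lm(fml, data = data)
    sigma <- stats::sigma(fit)
    if (!is.finite(sigma)) sigma <- 0
    list(model = fit, sigma = sigma, kind = "continuous_lm")
  } else {
    lv <- sort(unique(data[[col_name]]))
    d2 <- data
    d2[[col_name]] <- factor(d2[[col_name]], levels = lv)
    fit <- nnet::multinom(fml, data = d2, trace = FALSE)
    list(model = fit, levels = lv, kind = "multinom")
  }
}

# One chained-equations chain: initialize missing cells from random
# observed draws, Gibbs-sweep the incomplete columns `sweeps` times, and
# return the completed data plus the final per-column models.
mice_chain <- function(train, sweeps, seed) {
  x <- as.data.frame(train$x)
  miss <- lapply(x, function(col) which(is.na(col)))
  incomplete <- names(x)[vapply(miss, length, integer(1)) > 0]
  with_seed(seed, {
    for (nm in incomplete) {
      obs <- x[[nm]][!is.na(x[[nm]])]
      x[[nm]][miss[[nm]]] <- sample(obs, length(miss[[nm]]), replace = TRUE)
    }
    models <- list()
    for (s in seq_len(sweeps)) {
      for (nm in incomplete) {
        fitdata <- x
        fitdata[[nm]][miss[[nm]]] <- NA
        fit <- tryCatch(
          fit_conditional(nm, fitdata[!is.na(fitdata[[nm]]), , drop = FALSE], train$schema),
          error = function(e) NULL
        )
        if (is.null(fit)) {
          # non-convergent conditional fit: mean/mode fallback for this sweep
          obs <- x[[nm]][-miss[[nm]]]
          x[[nm]][miss[[nm]]] <- mean(obs)
          message(sprintf("chained equations: fallback fill for column '%s' (sweep %d)", nm, s))
          next
        }
        draws <- impute_column_from_model(fit, fit$kind, x[miss[[nm]], , drop = FALSE])
        if (train$schema[[nm]]$kind != "continuous") {
          obs_rng <- range(x[[nm]][-miss[[nm]]])
          draws <- pmax(obs_rng[1], pmin(obs_rng[2], draws))
        }
        x[[nm]][miss[[nm]]] <- draws
        models[[nm]] <- fit
      }
    }
    list(x = x, models = models, incomplete = incomplete)
  })
}

#' Chained-equations (multiple) imputation
#'
#' Iterative per-column conditional modelling in the spirit of MICE: each
#' incomplete column is regressed on all others (linear models for
#' numeric-coded columns, multinomial logistic for categorical ones), and
#' its missing cells are redrawn from the fitted conditional distribution;
#' the sweep over columns is repeated for a burn-in of `sweeps` iterations.
#' `m` independent chains with distinct sub-seeds yield `m` completed
#' training sets. Test rows are completed by applying each chain's final
#' conditional models (with stochastic draws), without refitting: test
#' missing cells start at the training-column mean and two passes of the
#' final models resolve cross-column dependence.
#'
#' @param train training `labeled_table`.
#' @param test optional test `labeled_table`.
#' @param m number of completed datasets; default 5.
#' @param seed integer seed.
#' @param sweeps burn-in sweeps per chain; default 10.
#' @return List of `m` elements, each a list with completed `train` and (if
#'   supplied) `test` tables.
#' @export
mice_impute <- function(train, test = NULL, m = 5L, seed = 1L, sweeps = 10L) {
  stopifnot(inherits(train, "labeled_table"))
  if (m < 1) stopf("m must be >= 1")
  train_means <- vapply(names(train$x), function(nm) {
    obs <- train$x[[nm]][!is.na(train$x[[nm]])]
    if (!length(obs)) stopf("column '%s' is fully missing in the training fold", nm)
    mean(obs)
  }, numeric(1))
  lapply(seq_len(m), function(i) {
    chain_seed <- derive_seed(seed, 606L, i)
    chain <- mice_chain(train, sweeps, chain_seed)
    out_train <- train
    out_train$x <- chain$x
    out <- list(train = out_train)
    if (!is.null(test)) {
      tx <- as.data.frame(test$x)
      miss <- lapply(tx, function(col) which(is.na(col)))
      with_seed(derive_seed(chain_seed, 707L), {
        for (nm in names(tx)) {
          if (length(miss[[nm]])) tx[[nm]][miss[[nm]]] <- train_means[[nm]]
        }
        for (pass in 1:2) {
          for (nm in chain$incomplete) {
            if (!length(miss[[nm]]) || is.null(chain$models[[nm]])) next
            fit <- chain$models[[nm]]
            draws <- impute_column_from_model(fit, fit$kind, tx[miss[[nm]], , drop = FALSE])
            if (test$schema[[nm]]$kind != "continuous") {
              obs_rng <- range(train$x[[nm]], na.rm = TRUE)
              draws <- pmax(obs_rng[1], pmin(obs_rng[2], draws))
            }
            tx[[nm]][miss[[nm]]] <- draws
          }
        }
      })
      out_test <- test
      out_test$x <- tx
      out$test <- out_test
    }
    out
  })
}
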