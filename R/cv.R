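#' Repeated cross-validation plan
#'
#' Assigns every row to exactly one of `K` folds, independently for each of
#' `R` repetitions. Within a repetition the assignment is fixed across
#' missingness levels and mechanisms, so severity effects are cumulative on
#' identical train/test splits. Assignment is simple random; set
#' `stratify = TRUE` to balance class shares across folds in imbalance
#' studies.
#'
#' @param n row count.
#' @param K fold count; default 3 (two thirds train, one third test).
#' @param R repetitions; default 50.
#' @param seed integer seed.
#' @param y response labels, required when `stratify = TRUE`.
#' @param stratify stratify fold assignment by class.
#' @return A `cv_plan` with an `n x R` fold-id matrix.
#' @export
cv_plan <- function(n, K = 3L, R = 50L, seed = 1L, y = NULL, stratify = FALSE) {
  if (K < 2 || n < K) stopf("need n >= K >= 2")
  folds <- matrix(0L, nrow = n, ncol = R)
  for (r in seq_len(R)) {
    folds[, r] <- with_seed(derive_seed(seed, 909L, r), {
      if (stratify) {
        if (is.null(y)) stopf("stratified plan needs y")
        out <- integer(n)
        for (cl in unique(y)) {
          idx <- which(y == cl)
          out[idx] <- sample(rep_len(seq_len(K), length(idx)))
        }
        out
      } else {
        sample(rep_len(seq_len(K), n))
      }
    })
  }
  structure(list(folds = folds, K = as.integer(K), R = as.integer(R), seed = as.integer(seed)),
            class = "cv_plan")
}

#' Options controlling the per-method machinery inside the CV harness
#'
#' @param ntree evaluation-forest size; 5000 mirrors the reference setting,
#'   500 keeps routine runs fast.
#' @param rf_impute_ntree,rf_impute_iterations imputation-forest settings.
#' @param knn_grid candidate k for the kNN imputer.
#' @param mice_m,mice_sweeps completed-dataset count and burn-in for
#'   chained equations.
#' @param default_levels discretization level count for all-continuous
#'   tables.
#' @param hl_groups Hosmer-Lemeshow group count.
#' @return A plain options list.
#' @export
cv_options <- function(ntree = 500L, rf_impute_ntree = 100L, rf_impute_iterations = 5L,
                       knn_grid = c(1, 3, 5, 10), mice_m = 5L, mice_sweeps = 10L,
                       default_levels = 4L, hl_groups = 10L) {
  list(
    ntree = as.integer(ntree), rf_impute_ntree = as.integer(rf_impute_ntree),
    rf_impute_iterations = as.integer(rf_impute_iterations),
    knn_grid = knn_grid, mice_m = as.integer(mice_m),
    mice_sweeps = as.integer(mice_sweeps),
    default_levels = as.integer(default_levels), hl_groups = as.integer(hl_groups)
  )
}

cf_methods <- c("CF")
lr_methods <- c("LR-MI", "LR-kNN", "LR-MICE")
rf_methods <- c("RF-MI", "RF-kNN", "RF-MICE", "RF-Imp")

#' All method labels understood by the harness
#' @return Character vector of method names.
#' @export
all_methods <- function() c(cf_methods, lr_methods, rf_methods)

# Run one method on one (train, test) pair of discretized tables.
# Returns yhat, positive-class probabilities (or NULL), the fitted model
# (for OOB scoring) and any selected tuning value.
run_method_cell <- function(method, dt, train_idx, train_t, test_t, cf, opts, seed) {
  if (method == "CF") {
    rm <- rating_matrix(dt, train_idx)
    cfg <- cf
    cfg$seed <- seed
    k <- cfg$k %||% select_k(rm, cfg)
    cfg$k <- k
    return(list(yhat = predict_response(rm, cfg), prob = NULL, model = NULL, selected_k = k))
  }
  parts <- strsplit(method, "-", fixed = TRUE)[[1]]
  family <- parts[1]
  imput <- parts[2]
  selected_k <- NA_integer_
  if (imput == "MI") {
    comp <- mean_impute(train_t, test_t)
    trains <- list(comp$train); tests <- list(comp$test)
  } else if (imput == "kNN") {
    comp <- knn_impute(train_t, test_t, k_grid = opts$knn_grid, seed = seed)
    selected_k <- comp$k
    trains <- list(comp$train); tests <- list(comp$test)
  } else if (imput == "MICE") {
    comp <- mice_impute(train_t, test_t, m = opts$mice_m, seed = seed, sweeps = opts$mice_sweeps)
    trains <- lapply(comp, `[[`, "train"); tests <- lapply(comp, `[[`, "test")
  } else if (imput == "Imp") {
    ct <- rf_proximity_impute(train_t, iterations = opts$rf_impute_iterations,
                              ntree = opts$rf_impute_ntree, seed = seed)
    trains <- list(ct)
    tests <- list(mean_impute(train_t, test_t)$test)
  } else {
    stopf("unknown method '%s'", method)
  }
  models <- lapply(seq_along(trains), function(i) {
    if (family == "LR") fit_logistic(trains[[i]])
    else fit_random_forest(trains[[i]], ntree = opts$ntree, seed = derive_seed(seed, i))
  })
  pred <- predict_labels(models, tests)
  list(yhat = pred$labels, prob = pred$prob, model = models[[1]], selected_k = selected_k)
}

#' Run the repeated cross-validation benchmark
#'
#' For every repetition, severity level and fold: split rows by the plan's
#' (level-invariant) fold assignment, overlay the pattern's mask for that
#' level, fit the quantile discretization on the training fold and apply it
#' to both folds, then run every requested method — collaborative filtering
#' directly on the rating matrix, the impute-and-classify combinations
#' otherwise — and score the held-out fold. A method failure marks that
#' cell failed and the run continues.
#'
#' @param table a fully observed `labeled_table`.
#' @param patterns list of `mask_set` patterns (one per repetition,
#'   recycled if shorter than `plan$R`).
#' @param methods subset of [all_methods()].
#' @param plan a [cv_plan()].
#' @param cf a [cf_config()].
#' @param opts a [cv_options()] list.
#' @return A `cv_report`: list with per-cell `records` and per-condition
#'   `aggregates` (mean and fold spread, the spread being the plain
#'   standard deviation across fold-level values).
#' @export
run_repeated_cv <- function(table, patterns, methods = all_methods(), plan,
                            cf = cf_config(), opts = cv_options()) {
  stopifnot(inherits(table, "labeled_table"), inherits(plan, "cv_plan"))
  bad <- setdiff(methods, all_methods())
  if (length(bad)) stopf("unknown method(s): %s", paste(bad, collapse = ", "))
  mechanism <- patterns[[1]]$mechanism
  positive <- levels(table$y)[nlevels(table$y)]
  binary <- nlevels(table$y) == 2
  rows <- list()
  for (r in seq_len(plan$R)) {
    pattern <- patterns[[(r - 1L) %% length(patterns) + 1L]]
    folds <- plan$folds[, r]
    for (li in seq_along(pattern$masks)) {
      masked <- apply_mask(table, pattern$masks[[li]])
      for (f in seq_len(plan$K)) {
        train_idx <- folds != f
        scheme <- fit_discretization(masked, rows = which(train_idx),
                                     config_default = opts$default_levels)
        dt <- discretize_table(masked, scheme)
        train_t <- table_rows(dt, train_idx)
        test_t <- table_rows(dt, !train_idx)
        for (mi in seq_along(methods)) {
          method <- methods[mi]
          seed <- derive_seed(plan$seed, r, li, f, mi)
          cell <- tryCatch(
            run_method_cell(method, dt, which(train_idx), train_t, test_t, cf, opts, seed),
            error = function(e) e
          )
          if (inherits(cell, "error")) {
            rows[[length(rows) + 1L]] <- data.frame(
              method = method, mechanism = mechanism, level = pattern$levels[li],
              rep = r, fold = f, misclass = NA_real_, sensitivity = NA_real_,
              specificity = NA_real_, hl_stat = NA_real_, hl_p = NA_real_,
              brier = NA_real_, brier_oob = NA_real_, selected_k = NA_integer_,
              failed = TRUE, note = conditionMessage(cell)
            )
            next
          }
          mc <- misclassification(test_t$y, cell$yhat)
          ss <- if (binary) {
            suppressWarnings(sens_spec(test_t$y, cell$yhat, positive))
          } else {
            c(sensitivity = NA_real_, specificity = NA_real_)
          }
          hl <- c(stat = NA_real_, p = NA_real_)
          br <- NA_real_
          br_oob <- NA_real_
          if (binary && !is.null(cell$prob)) {
            pvec <- cell$prob[, positive]
            hl_res <- tryCatch(
              suppressMessages(hosmer_lemeshow(pvec, test_t$y, groups = opts$hl_groups)),
              error = function(e) NULL
            )
            if (!is.null(hl_res)) hl <- c(stat = hl_res$statistic, p = hl_res$p_value)
            br <- brier(pvec, test_t$y)
          }
          if (binary && !is.null(cell$model) && cell$model$family == "random_forest") {
            br_oob <- tryCatch(
              suppressMessages(oob_brier(cell$model, positive = positive)),
              error = function(e) NA_real_
            )
          }
          rows[[length(rows) + 1L]] <- data.frame(
            method = method, mechanism = mechanism, level = pattern$levels[li],
            rep = r, fold = f, misclass = mc,
            sensitivity = unname(ss["sensitivity"]), specificity = unname(ss["specificity"]),
            hl_stat = unname(hl["stat"]), hl_p = unname(hl["p"]),
            brier = br, brier_oob = br_oob,
            selected_k = as.integer(cell$selected_k %||% NA_integer_),
            failed = FALSE, note = ""
          )
        }
      }
    }
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  structure(
    list(records = records, aggregates = aggregate_records(records),
         K = plan$K, R = plan$R, seed = plan$seed),
    class = "cv_report"
  )
}

# Per-condition mean and fold spread; spread is the SD across fold-level
# values (0 for a single record).
aggregate_records <- function(records) {
  ok <- records[!records$failed, , drop = FALSE]
  if (!nrow(ok)) return(data.frame())
  key <- interaction(ok$method, ok$mechanism, ok$level, drop = TRUE)
  out <- do.call(rbind, lapply(split(ok, key), function(d) {
    data.frame(
      method = d$method[1], mechanism = d$mechanism[1], level = d$level[1],
      n_cells = nrow(d),
      mean_misclass = mean(d$misclass),
      spread_misclass = if (nrow(d) > 1) stats::sd(d$misclass) else 0,
      mean_sensitivity = mean(d$sensitivity, na.rm = TRUE),
      mean_specificity = mean(d$specificity, na.rm = TRUE),
      mean_brier = mean(d$brier, na.rm = TRUE),
      mean_hl_p = mean(d$hl_p, na.rm = TRUE)
    )
  }))
  rownames(out) <- NULL
  out[order(out$mechanism, out$level, out$method), , drop = FALSE]
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "<cv_report> %d records (%d failed), K=%d, R=%d\n",
    nrow(x$records), sum(x$records$failed), x$K, x$R
  ))
  print(x$aggregates, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Summarize a cross-validation report
#'
#' Recomputes the per-condition aggregates (mean and fold spread of every
#' metric) from the raw records and returns them alongside a plot-ready
#' long table. Conditions whose every cell failed are omitted with a
#' warning.
#'
#' @param report a `cv_report`, or the path of a records CSV written by
#'   [write_report()].
#' @return List with `aggregates` and `long` (method, mechanism, level,
#'   rep, fold, metric, value).
#' @export
summarize_report <- function(report) {
  records <- if (inherits(report, "cv_report")) {
    report$records
  } else {
    if (!file.exists(report)) stopf("report not found: %s", report)
    utils::read.csv(report)
  }
  needed <- c("method", "mechanism", "level", "rep", "fold", "misclass", "failed")
  if (!all(needed %in% names(records))) stopf("malformed report: missing columns")
  dropped <- unique(records[records$failed, c("method", "mechanism", "level")])
  agg <- aggregate_records(records)
  if (nrow(dropped)) {
    kept <- paste(agg$method, agg$mechanism, agg$level)
    gone <- paste(dropped$method, dropped$mechanism, dropped$level)
    if (any(!gone %in% kept)) warnf("condition(s) with no successful cells omitted")
  }
  metrics <- c("misclass", "sensitivity", "specificity", "hl_stat", "hl_p", "brier", "brier_oob")
  ok <- records[!records$failed, , drop = FALSE]
  long <- do.call(rbind, lapply(metrics, function(m) {
    data.frame(
      method = ok$method, mechanism = ok$mechanism, level = ok$level,
      rep = ok$rep, fold = ok$fold, metric = m, value = ok[[m]]
    )
  }))
  list(aggregates = agg, long = long)
}

#' Write a report's records and aggregates to disk
#'
#' @param report a `cv_report`.
#' @param dir output directory (created if absent).
#' @return Invisibly, the written paths.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "cv_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rec_path <- file.path(dir, "cv_records.csv")
  agg_path <- file.path(dir, "cv_summary.json")
  utils::write.csv(report$records, rec_path, row.names = FALSE)
  jsonlite::write_json(report$aggregates, agg_path, dataframe = "rows", pretty = TRUE, digits = NA)
  invisible(c(records = rec_path, summary = agg_path))
}
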