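#' Rating matrix for user-based collaborative filtering
#'
#' Recasts a discretized clinical table as a patients-by-items rating
#' matrix: the items are the level-coded predictors plus one response item
#' holding the class code. Training rows keep their response rating; test
#' rows have it hidden, and the predictor treats recovering it as an
#' ordinary item-prediction problem.
#'
#' @param table a discretized `labeled_table` (integer level codes).
#' @param train logical or integer index marking training rows; all other
#'   rows are test rows.
#' @return A `rating_matrix`: integer matrix with attributes `train`
#'   (logical), `response_item` (column index), `class_levels` (response
#'   label set) and `level_count` (admissible levels per item).
#' @export
rating_matrix <- function(table, train) {
  stopifnot(inherits(table, "labeled_table"))
  n <- nrow(table$x)
  if (!is.logical(train)) train <- seq_len(n) %in% train
  stopifnot(length(train) == n)
  entries <- as.matrix(sapply(table$x, as.integer))
  if (n == 1) entries <- matrix(entries, nrow = 1, dimnames = list(NULL, names(table$x)))
  y_code <- as.integer(table$y)
  y_code[!train] <- NA_integer_
  entries <- cbind(entries, stats::setNames(y_code, NULL))
  colnames(entries) <- c(names(table$x), table$response_name)
  level_count <- c(
    vapply(names(table$x), function(nm) {
      lv <- table$schema[[nm]]$levels
      if (is.null(lv)) max(entries[, nm], na.rm = TRUE) else length(lv)
    }, numeric(1)),
    nlevels(table$y)
  )
  structure(
    entries,
    train = train,
    response_item = ncol(entries),
    class_levels = levels(table$y),
    level_count = as.integer(level_count),
    class = c("rating_matrix", "matrix", "array")
  )
}

#' @export
print.rating_matrix <- function(x, ...) {
  cat(sprintf(
    "<rating_matrix> %d patients (%d train / %d test) x %d items (response: '%s')\n",
    nrow(x), sum(attr(x, "train")), sum(!attr(x, "train")), ncol(x),
    colnames(x)[attr(x, "response_item")]
  ))
  invisible(x)
}

#' Configuration for the collaborative-filtering predictor
#'
#' @param k neighbourhood size; `NULL` means select via [select_k()].
#' @param k_grid candidate neighbourhood sizes for selection.
#' @param similarity `"cosine"` (default) or `"pearson"`.
#' @param inner_folds folds for the inner k-selection cross-validation.
#' @param seed integer seed (inner fold assignment).
#' @return A `cf_config` list.
#' @export
cf_config <- function(k = NULL, k_grid = c(5, 10, 20, 30, 50),
                      similarity = c("cosine", "pearson"),
                      inner_folds = 3L, seed = 1L) {
  similarity <- match.arg(similarity)
  if (!is.null(k) && k < 1) stopf("k must be >= 1")
  if (!length(k_grid)) stopf("k_grid must be non-empty")
  structure(
    list(
      k = k, k_grid = sort(unique(as.integer(k_grid))),
      similarity = similarity, inner_folds = as.integer(inner_folds),
      seed = as.integer(seed)
    ),
    class = "cf_config"
  )
}

#' Similarity between two patients' rating vectors
#'
#' Computed over the common set of co-observed items only. Cosine: inner
#' product over the overlap divided by the product of the restricted
#' Euclidean norms. The similarity is undefined (`NA`) when the overlap is
#' empty or a restricted vector has zero norm (Pearson: also when the
#' overlap has fewer than two items or zero variance); undefined
#' similarities are excluded from neighbourhoods rather than raised as
#' errors.
#'
#' @param u,v numeric rating vectors with `NA` for unobserved items.
#' @param metric `"cosine"` or `"pearson"`.
#' @return A number in `[-1, 1]`, or `NA` if undefined.
#' @export
patient_similarity <- function(u, v, metric = c("cosine", "pearson")) {
  metric <- match.arg(metric)
  ov <- !is.na(u) & !is.na(v)
  if (!any(ov)) return(NA_real_)
  a <- u[ov]; b <- v[ov]
  if (metric == "cosine") {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) return(NA_real_)
    max(-1, min(1, sum(a * b) / (na * nb)))
  } else {
    if (length(a) < 2 || stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    max(-1, min(1, stats::cor(a, b)))
  }
}

# Vectorized cosine similarity of one target rating vector against a block
# of candidate rows, over pairwise co-observed items. Returns NA where
# undefined.
cosine_to_rows <- function(target, rows) {
  obs_t <- !is.na(target)
  t0 <- ifelse(obs_t, target, 0)
  obs_m <- !is.na(rows)
  m0 <- rows
  m0[!obs_m] <- 0
  dot <- drop(m0 %*% t0)
  norm_m <- sqrt(drop((m0^2) %*% obs_t))
  norm_t <- sqrt(drop(obs_m %*% (t0^2)))
  overlap <- drop(obs_m %*% obs_t)
  sim <- dot / (norm_m * norm_t)
  sim[overlap == 0 | norm_m == 0 | norm_t == 0] <- NA_real_
  pmax(-1, pmin(1, sim))
}

similarity_to_train <- function(target, rows, metric) {
  if (metric == "cosine") {
    cosine_to_rows(target, rows)
  } else {
    apply(rows, 1, function(r) patient_similarity(target, r, metric = "pearson"))
  }
}

#' Find a patient's neighbourhood among training rows
#'
#' Similarity is computed over predictor items only (the response item never
#' enters the similarity). The neighbourhood holds the `k` training rows
#' with the highest defined similarity (fewer if fewer are defined); ties
#' are broken in favour of the lower row id. The target itself is never its
#' own neighbour.
#'
#' @param target_row row index into `matrix`, or a full rating vector.
#' @param matrix a [rating_matrix()].
#' @param k neighbourhood size.
#' @param metric similarity metric.
#' @return A `neighborhood`: list with `ids` (matrix row indices, descending
#'   similarity) and `sims`.
#' @export
find_neighborhood <- function(target_row, matrix, k, metric = "cosine") {
  train <- attr(matrix, "train")
  resp <- attr(matrix, "response_item")
  cand <- which(train)
  if (length(target_row) == 1 && is.numeric(target_row)) {
    idx <- as.integer(target_row)
    target <- matrix[idx, -resp]
    cand <- setdiff(cand, idx)
  } else {
    target <- target_row[-resp]
  }
  if (!length(cand)) stopf("rating matrix has no training rows")
  sims <- similarity_to_train(target, matrix[cand, -resp, drop = FALSE], metric)
  keep <- which(!is.na(sims))
  ord <- keep[order(-sims[keep], cand[keep])]
  top <- utils::head(ord, k)
  structure(list(ids = cand[top], sims = sims[top]), class = "neighborhood")
}

# Training-majority class code with ties to the smallest code.
majority_code <- function(matrix) {
  resp <- attr(matrix, "response_item")
  codes <- matrix[attr(matrix, "train"), resp]
  tab <- table(factor(codes, levels = seq_len(attr(matrix, "level_count")[resp])))
  as.integer(which.max(tab))
}

#' Predict one item for one patient from a neighbourhood
#'
#' The estimate is the similarity-weighted mean of the item's value over the
#' neighbours that observe it, with the weights renormalized over those
#' contributors. Fallbacks, in order: zero total weight with contributors
#' present uses the unweighted contributor mean; no contributor at all uses
#' the global observed item mean over training rows (for the response item,
#' the training majority class). Predictor items are rounded half-up to the
#' nearest admissible level; a binary response is thresholded at 0.5 on the
#' weighted mean of its 0/1 codes (exact ties go to the training majority
#' class); a multiclass response takes the similarity-weighted vote with
#' ties to the smallest class code.
#'
#' @param target_row row index (unused for the computation itself, kept for
#'   interface clarity; may be `NULL`).
#' @param item item (column) index to predict.
#' @param nbh a [find_neighborhood()] result.
#' @param matrix a [rating_matrix()].
#' @return Integer level or class code, with the pre-rounding estimate in
#'   attribute `"raw"` where one exists.
#' @export
predict_item <- function(target_row, item, nbh, matrix) {
  resp <- attr(matrix, "response_item")
  L <- attr(matrix, "level_count")[item]
  vals <- matrix[nbh$ids, item]
  keep <- !is.na(vals)
  vals <- as.numeric(vals[keep])
  w <- nbh$sims[keep]

  if (!length(vals)) {
    if (item == resp) return(majority_code(matrix))
    pool <- matrix[attr(matrix, "train"), item]
    pool <- pool[!is.na(pool)]
    if (!length(pool)) pool <- stats::na.omit(matrix[, item])
    est <- mean(pool)
    return(structure(as.integer(max(1, min(L, floor(est + 0.5)))), raw = est))
  }
  if (abs(sum(w)) < 1e-12) w <- rep(1, length(vals))

  if (item != resp) {
    est <- sum(w * vals) / sum(w)
    return(structure(as.integer(max(1, min(L, floor(est + 0.5)))), raw = est))
  }
  if (L == 2) {
    est <- sum(w * (vals - 1)) / sum(w)
    code <- if (est > 0.5) 2L else if (est < 0.5) 1L else majority_code(matrix)
    structure(code, raw = est)
  } else {
    scores <- vapply(seq_len(L), function(cc) sum(w[vals == cc]), numeric(1))
    structure(as.integer(which.max(scores)), raw = max(scores))
  }
}

# Predict the response item for every test row, for each k in k_grid,
# reusing one similarity/neighbourhood computation per row.
predict_response_grid <- function(matrix, k_grid, metric = "cosine") {
  train <- attr(matrix, "train")
  resp <- attr(matrix, "response_item")
  test_idx <- which(!train)
  k_max <- max(k_grid)
  out <- lapply(k_grid, function(k) integer(length(test_idx)))
  names(out) <- as.character(k_grid)
  for (i in seq_along(test_idx)) {
    nbh <- find_neighborhood(test_idx[i], matrix, k_max, metric = metric)
    for (g in seq_along(k_grid)) {
      sub <- list(
        ids = utils::head(nbh$ids, k_grid[g]),
        sims = utils::head(nbh$sims, k_grid[g])
      )
      out[[g]][i] <- as.integer(predict_item(test_idx[i], resp, sub, matrix))
    }
  }
  out
}

#' Predict the hidden response for every test row
#'
#' Each test row's response item is estimated through its neighbourhood
#' ([find_neighborhood()] + [predict_item()]); degenerate cases are absorbed
#' by the documented fallback hierarchy, so a label is always produced.
#'
#' @param matrix a [rating_matrix()].
#' @param config a [cf_config()] with `k` fixed (use [select_k()] first).
#' @return Factor of predicted labels, one per test row, in test-row order.
#' @export
predict_response <- function(matrix, config) {
  stopifnot(inherits(config, "cf_config"))
  k <- config$k
  if (is.null(k)) stopf("config$k is not set; run select_k() first")
  codes <- predict_response_grid(matrix, k, metric = config$similarity)[[1]]
  factor(attr(matrix, "class_levels")[codes], levels = attr(matrix, "class_levels"))
}

#' Select the neighbourhood size by inner cross-validation
#'
#' Training rows are split into `inner_folds` folds; within each fold the
#' held-out rows have their response hidden and are predicted from the
#' remaining training rows for every candidate `k`. The `k` minimizing the
#' mean misclassification over folds wins, with ties going to the smallest
#' `k`. Candidates exceeding the smallest inner training-set size are
#' dropped.
#'
#' @param matrix a [rating_matrix()] (its test rows are ignored here).
#' @param config a [cf_config()].
#' @return The selected integer `k`.
#' @export
select_k <- function(matrix, config) {
  stopifnot(inherits(config, "cf_config"))
  train_idx <- which(attr(matrix, "train"))
  n_tr <- length(train_idx)
  folds <- with_seed(
    derive_seed(config$seed, 303L),
    sample(rep_len(seq_len(config$inner_folds), n_tr))
  )
  min_inner_train <- min(vapply(seq_len(config$inner_folds), function(f) sum(folds != f), integer(1)))
  grid <- config$k_grid[config$k_grid <= min_inner_train]
  if (!length(grid)) stopf("no feasible k in the grid (inner training sets hold %d rows)", min_inner_train)
  err <- matrix(NA_real_, nrow = config$inner_folds, ncol = length(grid))
  resp <- attr(matrix, "response_item")
  for (f in seq_len(config$inner_folds)) {
    sub <- matrix[train_idx, , drop = FALSE]
    sub_train <- folds != f
    truth <- sub[!sub_train, resp]
    sub[!sub_train, resp] <- NA_integer_
    sub_rm <- structure(
      sub,
      train = sub_train,
      response_item = resp,
      class_levels = attr(matrix, "class_levels"),
      level_count = attr(matrix, "level_count"),
      class = c("rating_matrix", "matrix", "array")
    )
    preds <- predict_response_grid(sub_rm, grid, metric = config$similarity)
    for (g in seq_along(grid)) err[f, g] <- mean(preds[[g]] != truth)
  }
  grid[which.min(colMeans(err))]
}
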