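#' Specification of a missingness mechanism and severity ladder
#'
#' Severity levels are cumulative: within a pattern, every cell missing at a
#' lower level is missing at all higher levels. MCAR rates are matrix-wide
#' fractions of predictor cells; MAR rates are fractions of the target
#' column's entries (missingness is imposed on the target column whenever
#' the driver column exceeds the corresponding upper quantile).
#' `"mcar_matched"` generates MAR masks first and then matches an MCAR mask
#' to each level's masked-cell count, spread uniformly over all predictor
#' cells, enabling fair MCAR/MAR comparisons at identical missing volumes.
#'
#' @param mechanism `"mcar"`, `"mar"`, or `"mcar_matched"`.
#' @param levels strictly increasing target rates in `[0, 1)`.
#' @param mar_driver driver column (index or name); default the second
#'   predictor.
#' @param mar_target target column; default the first predictor.
#' @param seed integer seed from which all pattern seeds derive.
#' @return A `missingness_spec` list.
#' @export
missingness_spec <- function(mechanism = c("mcar", "mar", "mcar_matched"),
                             levels = c(0.1, 0.2, 0.3),
                             mar_driver = 2L, mar_target = 1L, seed = 1L) {
  mechanism <- match.arg(mechanism)
  if (any(levels < 0) || any(levels >= 1)) stopf("levels must lie in [0, 1)")
  if (length(levels) > 1 && any(diff(levels) <= 0)) stopf("levels must be strictly increasing")
  if (identical(mar_driver, mar_target)) stopf("MAR driver and target must differ")
  structure(
    list(
      mechanism = mechanism, levels = as.numeric(levels),
      mar_driver = mar_driver, mar_target = mar_target, seed = as.integer(seed)
    ),
    class = "missingness_spec"
  )
}

empty_mask <- function(table) {
  m <- matrix(FALSE, nrow = nrow(table$x), ncol = ncol(table$x))
  colnames(m) <- names(table$x)
  m
}

#' Inject missing-completely-at-random cells
#'
#' Deletion is uniform over all predictor cells, so every predictor is
#' affected to a comparable extent; the response is never touched. The
#' achieved count is exactly `round(rate * n * p)`, counting any cells
#' already present in `base_mask`, so a lower-severity mask grows into a
#' higher-severity one (cumulative missingness).
#'
#' @param table a `labeled_table`.
#' @param rate target overall predictor-cell missing rate in `[0, 1)`.
#' @param seed integer seed.
#' @param base_mask optional logical n x p mask to extend (its cells are
#'   always retained).
#' @return Logical n x p mask.
#' @export
inject_mcar <- function(table, rate, seed = 1L, base_mask = NULL) {
  stopifnot(inherits(table, "labeled_table"))
  if (rate < 0 || rate >= 1) stopf("rate must lie in [0, 1)")
  n <- nrow(table$x); p <- ncol(table$x)
  if (is.null(base_mask)) base_mask <- empty_mask(table)
  stopifnot(identical(dim(base_mask), c(n, p)))
  target <- round(rate * n * p)
  have <- sum(base_mask)
  if (target < have) {
    stopf("nesting violation: rate %.3f targets %d cells but base mask already holds %d", rate, target, have)
  }
  mask <- base_mask
  free <- which(!base_mask)
  add <- target - have
  if (add > 0) {
    picked <- with_seed(seed, sample(free, add))
    mask[picked] <- TRUE
  }
  mask
}

#' Inject missing-at-random cells driven by an observed covariate
#'
#' The target column's cell in row i is masked iff the driver column's value
#' in row i exceeds the empirical `(1 - rate)` quantile of the driver, i.e.
#' exactly the `ceiling(rate * n)` rows with the largest driver values are
#' masked. The rule is deterministic given the table; `seed` is accepted for
#' interface symmetry and ignored. Masks at increasing rates are nested by
#' construction.
#'
#' @param table a `labeled_table`.
#' @param rate target missing fraction of the target column in `[0, 1)`.
#' @param driver fully observed driver column (index or name).
#' @param target column receiving the missingness.
#' @param seed ignored (the rule is deterministic).
#' @return Logical n x p mask, TRUE only within the target column.
#' @export
inject_mar <- function(table, rate, driver = 2L, target = 1L, seed = NULL) {
  stopifnot(inherits(table, "labeled_table"))
  if (rate < 0 || rate >= 1) stopf("rate must lie in [0, 1)")
  drv <- table$x[[driver]]
  if (anyNA(drv)) stopf("MAR driver column has missing values")
  mask <- empty_mask(table)
  m <- as.integer(ceiling(rate * length(drv)))
  if (m > 0) {
    ord <- order(drv, decreasing = TRUE)
    tcol <- if (is.character(target)) match(target, names(table$x)) else as.integer(target)
    mask[ord[seq_len(m)], tcol] <- TRUE
  }
  mask
}

#' Match an MCAR mask to a MAR mask's missing volume
#'
#' Returns an MCAR mask with exactly as many masked cells as `mar_mask`,
#' drawn uniformly over all predictor cells (optionally extending a
#' lower-severity `base_mask` so matched masks can also be cumulative).
#'
#' @param mar_mask logical n x p MAR mask.
#' @param table the `labeled_table` the mask refers to.
#' @param seed integer seed.
#' @param base_mask optional lower-severity matched mask to extend.
#' @return Logical n x p mask with `sum(mask) == sum(mar_mask)`.
#' @export
match_mcar_to_mar <- function(mar_mask, table, seed = 1L, base_mask = NULL) {
  stopifnot(inherits(table, "labeled_table"))
  n <- nrow(table$x); p <- ncol(table$x)
  stopifnot(identical(dim(mar_mask), c(n, p)))
  if (is.null(base_mask)) base_mask <- empty_mask(table)
  target <- sum(mar_mask)
  have <- sum(base_mask)
  if (target < have) stopf("nesting violation: matched count %d below base mask's %d", target, have)
  mask <- base_mask
  add <- target - have
  if (add > 0) {
    picked <- with_seed(seed, sample(which(!base_mask), add))
    mask[picked] <- TRUE
  }
  mask
}

#' Generate replicate patterns of nested missingness masks
#'
#' Each replicate ("pattern") is a `mask_set`: one mask per severity level,
#' nested so that lower-severity masks are subsets of higher-severity ones.
#' Pattern seeds derive deterministically from `spec$seed` and the pattern
#' id.
#'
#' @param table a `labeled_table`.
#' @param spec a [missingness_spec()].
#' @param replicates number of patterns (>= 1).
#' @return List of `mask_set` objects, each with elements `masks` (list of
#'   logical matrices), `levels`, `mechanism` and `pattern_id`.
#' @export
generate_patterns <- function(table, spec, replicates = 50L) {
  stopifnot(inherits(table, "labeled_table"), inherits(spec, "missingness_spec"))
  if (replicates < 1) stopf("replicates must be >= 1")
  lapply(seq_len(replicates), function(id) {
    masks <- vector("list", length(spec$levels))
    base <- NULL
    for (i in seq_along(spec$levels)) {
      rate <- spec$levels[i]
      lvl_seed <- derive_seed(spec$seed, id, i)
      masks[[i]] <- switch(spec$mechanism,
        mcar = inject_mcar(table, rate, seed = lvl_seed, base_mask = base),
        mar = inject_mar(table, rate, driver = spec$mar_driver, target = spec$mar_target),
        mcar_matched = match_mcar_to_mar(
          inject_mar(table, rate, driver = spec$mar_driver, target = spec$mar_target),
          table, seed = lvl_seed, base_mask = base
        )
      )
      base <- masks[[i]]
    }
    structure(
      list(masks = masks, levels = spec$levels, mechanism = spec$mechanism, pattern_id = id),
      class = "mask_set"
    )
  })
}

#' @export
print.mask_set <- function(x, ...) {
  counts <- vapply(x$masks, sum, integer(1))
  cat(sprintf(
    "<mask_set> pattern %d (%s): levels %s -> %s masked cells\n",
    x$pattern_id, x$mechanism,
    paste(x$levels, collapse = "/"), paste(counts, collapse = "/")
  ))
  invisible(x)
}

#' Apply a mask to a labeled table
#'
#' @param table a `labeled_table`.
#' @param mask logical n x p matrix over predictor cells.
#' @return The table with masked predictor cells set to `NA`; the response
#'   is untouched.
#' @export
apply_mask <- function(table, mask) {
  stopifnot(inherits(table, "labeled_table"))
  stopifnot(identical(dim(mask), dim(table$x)))
  out <- table
  for (j in seq_len(ncol(out$x))) out$x[mask[, j], j] <- NA
  out
}

#' Serialize a mask set as (row, column, level_index) triples
#'
#' @param maskset a `mask_set`.
#' @param path CSV destination.
#' @return Invisibly, `path`. Each cell appears once at the lowest level
#'   index at which it is masked (nesting implies membership at all higher
#'   levels).
#' @export
write_mask_set <- function(maskset, path) {
  stopifnot(inherits(maskset, "mask_set"))
  seen <- maskset$masks[[1]] & FALSE
  rows <- list()
  for (i in seq_along(maskset$masks)) {
    new <- maskset$masks[[i]] & !seen
    idx <- which(new, arr.ind = TRUE)
    if (nrow(idx)) {
      rows[[length(rows) + 1]] <- data.frame(
        row = idx[, 1], column = idx[, 2], level_index = i
      )
    }
    seen <- seen | new
  }
  df <- if (length(rows)) do.call(rbind, rows) else data.frame(row = integer(), column = integer(), level_index = integer())
  df <- df[order(df$level_index, df$row, df$column), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
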