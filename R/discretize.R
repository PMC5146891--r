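#' Infer the discretization level count from a table's schema
#'
#' The level count is the maximal level-set size across categorical and
#' ordinal predictor columns, so that continuous predictors are binned onto
#' the same rating scale the discrete columns already use. For an
#' all-continuous table (e.g. the synthetic datasets) the configured
#' default applies.
#'
#' @param schema named list of column descriptors (see [labeled_table()]).
#' @param config_default level count used when no predictor is level-coded;
#'   default 4.
#' @param exclude column names to ignore (the response).
#' @return Integer L >= 2.
#' @export
infer_level_count <- function(schema, config_default = 4L, exclude = NULL) {
  if (!length(schema)) stopf("empty schema")
  cols <- setdiff(names(schema), exclude)
  sizes <- vapply(cols, function(nm) {
    entry <- schema[[nm]]
    if (entry$kind %in% c("categorical", "ordinal") && !is.null(entry$levels)) {
      length(entry$levels)
    } else 0L
  }, integer(1))
  L <- if (any(sizes > 0)) max(sizes) else as.integer(config_default)
  if (L < 2) stopf("inferred level count %d is below 2", L)
  as.integer(L)
}

#' Fit quantile cutpoints for one continuous column
#'
#' Cutpoints sit at the i/L empirical quantiles (i = 1..L-1) of the observed
#' training values, with linear interpolation between order statistics, so
#' the resulting levels are balanced on the fitting data. Missing values are
#' ignored.
#'
#' @param values observed training values (may contain `NA`).
#' @param L level count (>= 2).
#' @return Numeric vector of L-1 non-decreasing cutpoints.
#' @export
fit_cutpoints <- function(values, L) {
  if (L < 2) stopf("level count must be >= 2")
  obs <- values[!is.na(values)]
  if (!length(obs)) stopf("cannot fit cutpoints on an empty column")
  cuts <- unname(stats::quantile(obs, probs = seq_len(L - 1) / L, type = 7))
  if (max(obs) == min(obs)) {
    warnf("constant column: degenerate cutpoints, all values map to level 1")
  }
  cuts
}

#' Map values onto discretization levels
#'
#' Bins are right-closed: a value at or below the first cutpoint maps to
#' level 1, a value above the last cutpoint to level L, and ties on a
#' cutpoint go to the lower level. Missing values stay missing.
#'
#' @param column numeric values.
#' @param cutpoints sorted cutpoints from [fit_cutpoints()].
#' @return Integer levels in `1..(length(cutpoints) + 1)` with `NA`
#'   preserved.
#' @export
apply_discretization <- function(column, cutpoints) {
  out <- rep(NA_integer_, length(column))
  obs <- !is.na(column)
  out[obs] <- 1L + vapply(
    column[obs],
    function(v) sum(v > cutpoints),
    numeric(1)
  )
  as.integer(out)
}

#' Fit a discretization scheme on training rows
#'
#' Continuous columns get quantile cutpoints fitted on the observed training
#' values; categorical and ordinal columns get a recode map onto
#' `1..level_count` of their declared level set. The binary response is
#' already level-coded and is never re-discretized.
#'
#' @param table a `labeled_table` (typically with missingness applied).
#' @param rows training-row index used to fit cutpoints; default all rows.
#' @param L level count; default inferred via [infer_level_count()].
#' @param config_default default level count for all-continuous tables.
#' @return A `discretization_scheme` with per-column cutpoints or recode
#'   maps, the level count, and the fitting row set.
#' @export
fit_discretization <- function(table, rows = NULL, L = NULL, config_default = 4L) {
  stopifnot(inherits(table, "labeled_table"))
  if (is.null(rows)) rows <- seq_len(nrow(table$x))
  if (is.null(L)) {
    L <- infer_level_count(table$schema, config_default, exclude = table$response_name)
  }
  columns <- lapply(names(table$x), function(nm) {
    entry <- table$schema[[nm]]
    if (entry$kind == "continuous") {
      list(kind = "continuous", cutpoints = fit_cutpoints(table$x[[nm]][rows], L))
    } else {
      lv <- entry$levels %||% sort(unique(table$x[[nm]][!is.na(table$x[[nm]])]))
      list(kind = entry$kind, map = lv)
    }
  })
  names(columns) <- names(table$x)
  structure(
    list(level_count = as.integer(L), columns = columns, source = rows),
    class = "discretization_scheme"
  )
}

#' Apply a fitted discretization scheme to a table
#'
#' @param table a `labeled_table` with the same columns the scheme was
#'   fitted on.
#' @param scheme a [fit_discretization()] result.
#' @return A `labeled_table` whose predictors are integer level codes
#'   (ordinal, levels `1..L` for formerly continuous columns; `1..K` for
#'   level-coded columns), with missing cells preserved.
#' @export
discretize_table <- function(table, scheme) {
  stopifnot(inherits(table, "labeled_table"), inherits(scheme, "discretization_scheme"))
  out_x <- table$x
  schema <- table$schema
  for (nm in names(table$x)) {
    col <- scheme$columns[[nm]]
    if (is.null(col)) stopf("scheme does not cover column '%s'", nm)
    if (col$kind == "continuous") {
      out_x[[nm]] <- apply_discretization(table$x[[nm]], col$cutpoints)
      schema[[nm]] <- list(kind = "ordinal", levels = seq_len(scheme$level_count))
    } else {
      out_x[[nm]] <- as.integer(match(table$x[[nm]], col$map))
      schema[[nm]] <- list(kind = col$kind, levels = seq_along(col$map))
    }
  }
  labeled_table(out_x, table$y, schema = schema, response_name = table$response_name)
}

#' Serialize a discretization scheme for audit
#'
#' @param scheme a `discretization_scheme`.
#' @param path JSON destination (column -> cutpoints / level map).
#' @return Invisibly, `path`.
#' @export
write_discretization <- function(scheme, path) {
  stopifnot(inherits(scheme, "discretization_scheme"))
  out <- list(level_count = scheme$level_count)
  out$columns <- lapply(scheme$columns, function(col) {
    if (col$kind == "continuous") list(kind = col$kind, cutpoints = col$cutpoints)
    else list(kind = col$kind, map = col$map)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
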