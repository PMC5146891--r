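#' Construct a labeled clinical table
#'
#' A `labeled_table` couples a patient-by-feature predictor block (which may
#' contain missing cells) with a fully observed class-label response and a
#' per-column schema declaring each column as continuous, categorical or
#' ordinal. It is the common currency of the simulation, missingness,
#' discretization and imputation steps.
#'
#' @param x data.frame or matrix of predictor values; `NA` marks a missing
#'   cell. Continuous columns hold reals; categorical/ordinal columns hold
#'   integer level codes.
#' @param y response vector (factor or coercible); must contain no `NA`.
#' @param schema named list, one entry per column of `x` plus one for the
#'   response, each a list with elements `kind` (one of `"continuous"`,
#'   `"categorical"`, `"ordinal"`) and, for level-coded columns, `levels`
#'   (the admissible level codes). Missing entries default to continuous.
#' @param response_name name of the response column used on disk.
#'
#' @return An object of class `labeled_table` with elements `x`, `y`,
#'   `schema` and `response_name`.
#' @export
labeled_table <- function(x, y, schema = NULL, response_name = "Y") {
  x <- as.data.frame(x)
  if (anyNA(y)) stopf("response contains missing values")
  if (nrow(x) != length(y)) stopf("predictor rows (%d) != response length (%d)", nrow(x), length(y))
  y <- as.factor(y)
  if (is.null(schema)) {
    schema <- lapply(x, function(col) list(kind = "continuous", levels = NULL))
  }
  for (nm in names(x)) {
    if (is.null(schema[[nm]])) schema[[nm]] <- list(kind = "continuous", levels = NULL)
  }
  if (is.null(schema[[response_name]])) {
    schema[[response_name]] <- list(kind = "categorical", levels = levels(y))
  }
  for (nm in names(schema)) {
    kind <- schema[[nm]]$kind %||% "continuous"
    if (!kind %in% c("continuous", "categorical", "ordinal")) {
      stopf("column '%s' has unknown kind '%s'", nm, kind)
    }
    schema[[nm]]$kind <- kind
    lv <- schema[[nm]]$levels
    if (!is.null(lv) && nm %in% names(x) && kind != "continuous") {
      obs <- x[[nm]][!is.na(x[[nm]])]
      if (length(obs) && !all(obs %in% lv)) {
        stopf("column '%s' contains codes outside its declared level set", nm)
      }
    }
  }
  structure(
    list(x = x, y = y, schema = schema, response_name = response_name),
    class = "labeled_table"
  )
}

#' @export
print.labeled_table <- function(x, ...) {
  miss <- sum(is.na(x$x))
  cat(sprintf(
    "<labeled_table> %d patients x %d predictors, response '%s' (%d classes)\n",
    nrow(x$x), ncol(x$x), x$response_name, nlevels(x$y)
  ))
  cat(sprintf(
    "  missing predictor cells: %d (%.1f%%)\n",
    miss, 100 * miss / max(1, nrow(x$x) * ncol(x$x))
  ))
  kinds <- vapply(names(x$x), function(nm) x$schema[[nm]]$kind, character(1))
  cat("  kinds:", paste(sprintf("%s=%s", names(kinds), kinds), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.labeled_table <- function(x) dim(x$x)

#' Subset the rows of a labeled table
#'
#' @param table a `labeled_table`.
#' @param rows integer or logical row index.
#' @return A `labeled_table` containing the selected rows.
#' @export
table_rows <- function(table, rows) {
  stopifnot(inherits(table, "labeled_table"))
  out <- table
  out$x <- table$x[rows, , drop = FALSE]
  rownames(out$x) <- NULL
  out$y <- table$y[rows]
  out
}

#' Write a labeled table to CSV with a schema sidecar
#'
#' The table is written as a headed CSV with the missing token `NA` and the
#' response column last; the sidecar is a JSON key-value file mapping each
#' column to its kind, level set and (for the response) a response flag,
#' optionally with declared exclusion codes.
#'
#' @param table a `labeled_table`.
#' @param data_path CSV destination.
#' @param schema_path sidecar destination.
#' @return Invisibly, the two paths.
#' @export
write_labeled_table <- function(table, data_path, schema_path) {
  stopifnot(inherits(table, "labeled_table"))
  df <- table$x
  df[[table$response_name]] <- as.character(table$y)
  utils::write.csv(df, data_path, row.names = FALSE, na = "NA", quote = FALSE)
  side <- lapply(names(table$schema), function(nm) {
    entry <- table$schema[[nm]]
    out <- list(kind = entry$kind)
    if (!is.null(entry$levels)) out$levels <- entry$levels
    if (!is.null(entry$exclude)) out$exclude <- entry$exclude
    if (identical(nm, table$response_name)) out$response <- TRUE
    out
  })
  names(side) <- names(table$schema)
  jsonlite::write_json(side, schema_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(data = data_path, schema = schema_path))
}

#' Read a labeled table from CSV plus schema sidecar
#'
#' Cells equal to the token `NA` become missing. Rows holding a declared
#' exclusion code (e.g. refuse/unknown survey codes) in any column are
#' dropped, mirroring common survey cleaning policies. The schema must cover
#' every column and flag exactly one response column, which must be fully
#' observed.
#'
#' @param data_path CSV path (header row, `NA` missing token).
#' @param schema_path JSON sidecar path as written by [write_labeled_table()].
#' @return A `labeled_table`.
#' @export
load_table <- function(data_path, schema_path) {
  if (!file.exists(data_path)) stopf("data file not found: %s", data_path)
  if (!file.exists(schema_path)) stopf("schema file not found: %s", schema_path)
  side <- jsonlite::read_json(schema_path, simplifyVector = TRUE)
  df <- utils::read.csv(data_path, na.strings = "NA", check.names = FALSE)
  missing_cols <- setdiff(names(df), names(side))
  if (length(missing_cols)) {
    stopf("schema does not cover column(s): %s", paste(missing_cols, collapse = ", "))
  }
  resp <- names(side)[vapply(side, function(e) isTRUE(e$response), logical(1))]
  if (length(resp) != 1) stopf("schema must flag exactly one response column")
  if (!resp %in% names(df)) stopf("response column '%s' absent from data", resp)
  # drop rows carrying a declared exclusion code in any column
  drop <- rep(FALSE, nrow(df))
  for (nm in names(df)) {
    ex <- side[[nm]]$exclude
    if (!is.null(ex) && length(ex)) {
      drop <- drop | (!is.na(df[[nm]]) & df[[nm]] %in% ex)
    }
  }
  df <- df[!drop, , drop = FALSE]
  if (anyNA(df[[resp]])) stopf("response column '%s' has missing values", resp)
  y <- df[[resp]]
  x <- df[setdiff(names(df), resp)]
  for (nm in names(x)) {
    kind <- side[[nm]]$kind %||% "continuous"
    val <- suppressWarnings(as.numeric(x[[nm]]))
    bad <- which(is.na(val) & !is.na(x[[nm]]))
    if (length(bad)) stopf("non-parsable cell at row %d, column '%s'", bad[1], nm)
    x[[nm]] <- val
  }
  schema <- lapply(names(side), function(nm) {
    list(
      kind = side[[nm]]$kind %||% "continuous",
      levels = side[[nm]]$levels,
      exclude = side[[nm]]$exclude
    )
  })
  names(schema) <- names(side)
  labeled_table(x, y, schema = schema, response_name = resp)
}
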