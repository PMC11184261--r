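#' Gene-by-sample expression matrix
#'
#' Light container coupling a numeric genes x samples matrix with a units tag,
#' so downstream stages can refuse input on the wrong scale (e.g. running
#' log-CPM transformation twice, or z-scoring raw counts).
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Must carry
#'   unique, non-missing row and column names.
#' @param units One of `"counts"` (raw non-negative counts), `"logcpm"`
#'   (log2 counts per million) or `"unit_scaled"` (values in `[0, 1]` after
#'   scaling to a reference cohort).
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` and `units`.
#' @export
expression_matrix <- function(values, units = c("counts", "logcpm", "unit_scaled")) {
  units <- match.arg(units)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix (genes x samples)")
  }
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || anyNA(gid) || any(gid == "")) {
    stop("all genes must have non-missing ids (rownames)")
  }
  if (is.null(sid) || anyNA(sid) || any(sid == "")) {
    stop("all samples must have non-missing ids (colnames)")
  }
  if (anyDuplicated(sid)) stop("sample ids must be unique")
  if (units == "counts" && any(values < 0, na.rm = TRUE)) {
    stop("counts must be non-negative")
  }
  structure(list(values = values, units = units), class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Gene and sample identifiers
#' @param x An `ExpressionMatrix`.
#' @return Character vector of ids.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Subset an expression matrix, preserving the units tag
#' @param x An `ExpressionMatrix`.
#' @param i,j Gene / sample index (integer, logical or character).
#' @param ... Unused.
#' @export
`[.ExpressionMatrix` <- function(x, i, j, ...) {
  v <- x$values[i, j, drop = FALSE]
  expression_matrix(v, units = x$units)
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf(
    "ExpressionMatrix: %d genes x %d samples [%s]\n",
    nrow(x$values), ncol(x$values), x$units
  ))
  invisible(x)
}

#' Validate a sample metadata table
#'
#' Checks the per-sample covariate table used throughout the pipeline:
#' one row per sample, group labels among LN / SLE_nonrenal / HC, cohort
#' among discovery / replication / none.
#'
#' @param meta A data.frame with at least columns `sample_id`, `group`,
#'   `cohort`, `age`, `sex`, `batch`, `rin`.
#' @return The validated data.frame, invisibly coerced (factors to character).
#' @export
validate_metadata <- function(meta) {
  required <- c("sample_id", "group", "cohort", "age", "sex", "batch", "rin")
  missing <- setdiff(required, names(meta))
  if (length(missing)) {
    stop("metadata is missing columns: ", paste(missing, collapse = ", "))
  }
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id)) stop("metadata must have one row per sample")
  for (col in c("group", "cohort", "sex", "batch")) meta[[col]] <- as.character(meta[[col]])
  bad <- setdiff(unique(meta$group), c("LN", "SLE_nonrenal", "HC"))
  if (length(bad)) stop("unknown group labels: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(meta$cohort), c("discovery", "replication", "none"))
  if (length(bad)) stop("unknown cohort labels: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(meta$sex), c("F", "M"))
  if (length(bad)) stop("sex must be 'F' or 'M'")
  meta
}
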