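#' Transform raw counts to log2 counts per million
#'
#' `log2((c + prior_count) / (L + lib_offset) * 1e6)` with `L` the sample
#' library size (column sum). The voom-style pseudo-counts (0.5 on the count,
#' 1 on the library size) keep zeros finite and are configurable.
#'
#' @param counts An `ExpressionMatrix` with units `"counts"`.
#' @param prior_count Pseudo-count added to each count (default 0.5).
#' @param lib_offset Offset added to each library size (default 1).
#' @return An `ExpressionMatrix` with units `"logcpm"`.
#' @export
log_cpm <- function(counts, prior_count = 0.5, lib_offset = 1) {
  stopifnot(inherits(counts, "ExpressionMatrix"))
  if (counts$units != "counts") stop("log_cpm expects units 'counts', got '", counts$units, "'")
  lib <- colSums(counts$values)
  if (any(lib == 0)) {
    stop(
      "sample(s) with all-zero counts: ",
      paste(sample_ids(counts)[lib == 0], collapse = ", ")
    )
  }
  v <- log2(sweep(counts$values + prior_count, 2, lib + lib_offset, "/") * 1e6)
  dimnames(v) <- dimnames(counts$values)
  expression_matrix(v, units = "logcpm")
}

#' Remove genes with low counts
#'
#' Keeps a gene iff its counts-per-million (no pseudo-count) exceed `min_cpm`
#' in at least `min_fraction` of samples. The defaults (CPM > 1 in >= 10% of
#' samples) follow common practice for whole-blood RNA-seq.
#'
#' @param counts An `ExpressionMatrix` with units `"counts"`.
#' @param min_cpm CPM threshold (strict `>`).
#' @param min_fraction Minimum fraction of qualifying samples (`>=`).
#' @return The filtered `ExpressionMatrix`.
#' @export
filter_low_counts <- function(counts, min_cpm = 1, min_fraction = 0.1) {
  stopifnot(inherits(counts, "ExpressionMatrix"))
  if (counts$units != "counts") stop("filter_low_counts expects raw counts")
  lib <- colSums(counts$values)
  if (any(lib == 0)) stop("sample(s) with all-zero counts present; remove them first")
  cpm <- sweep(counts$values, 2, lib, "/") * 1e6
  keep <- rowMeans(cpm > min_cpm) >= min_fraction
  if (!any(keep)) stop("no genes pass the low-count filter")
  counts[keep, ]
}

#' Collapse duplicated gene symbols by averaging counts
#'
#' Rows sharing a gene id are replaced by a single row holding their
#' per-sample arithmetic mean count, placed at the position of the first
#' occurrence.
#'
#' @param counts An `ExpressionMatrix` with units `"counts"`.
#' @return An `ExpressionMatrix` with unique gene ids.
#' @export
collapse_duplicate_symbols <- function(counts) {
  stopifnot(inherits(counts, "ExpressionMatrix"))
  if (counts$units != "counts") stop("collapse_duplicate_symbols expects raw counts")
  ids <- gene_ids(counts)
  if (!anyDuplicated(ids)) return(counts)
  # rowsum(reorder = FALSE) groups in first-occurrence order
  sums <- rowsum(counts$values, group = ids, reorder = FALSE)
  n <- as.vector(rowsum(rep(1, length(ids)), group = ids, reorder = FALSE))
  expression_matrix(sums / n, units = "counts")
}

#' Residualize expression on sample covariates
#'
#' Replaces each gene's profile by the residuals of an ordinary
#' least-squares fit on the given covariates (plus intercept). Used before
#' coexpression network construction so that shared technical/demographic
#' axes (age, sex, batch, RIN) do not masquerade as coexpression.
#'
#' @param em An `ExpressionMatrix` (log-CPM).
#' @param meta Sample metadata covering all samples of `em`.
#' @param covariates Metadata columns to remove.
#' @return An `ExpressionMatrix` of residuals (units tag preserved).
#' @export
adjust_covariates <- function(em, meta, covariates = c("age", "sex", "batch", "rin")) {
  meta <- as.data.frame(meta)
  meta <- meta[match(sample_ids(em), meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) stop("metadata must cover every sample")
  fm <- stats::as.formula(paste("~", paste(covariates, collapse = " + ")))
  design <- stats::model.matrix(fm, data = meta)
  qrd <- qr(design)
  resid <- t(qr.resid(qrd, t(em$values)))
  dimnames(resid) <- dimnames(em$values)
  expression_matrix(resid, units = em$units)
}

#' Match cases to controls on age and sex
#'
#' Deterministic greedy nearest-age matching within sex: cases are processed
#' in input order; each receives the `ratio` not-yet-selected same-sex pool
#' members with smallest absolute age difference, ties broken by pool input
#' order. Selection is without replacement across cases.
#'
#' @param cases,pool Data frames with columns `sample_id`, `sex`, `age`.
#' @param ratio Controls per case (default 5, the study's 1:5 design).
#' @return Character vector of `ratio * nrow(cases)` selected control ids.
#' @export
match_controls <- function(cases, pool, ratio = 5) {
  for (df in list(cases, pool)) {
    if (!all(c("sample_id", "sex", "age") %in% names(df))) {
      stop("cases and pool need columns sample_id, sex, age")
    }
  }
  if (nrow(pool) < ratio * nrow(cases)) {
    stop("control pool smaller than ratio * number of cases")
  }
  available <- rep(TRUE, nrow(pool))
  selected <- character(0)
  for (i in seq_len(nrow(cases))) {
    eligible <- which(available & pool$sex == cases$sex[i])
    if (length(eligible) < ratio) {
      stop("insufficient same-sex controls for case ", cases$sample_id[i])
    }
    # order() is stable, so age ties resolve by pool input order
    pick <- eligible[order(abs(pool$age[eligible] - cases$age[i]))[seq_len(ratio)]]
    available[pick] <- FALSE
    selected <- c(selected, pool$sample_id[pick])
  }
  selected
}
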