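# Per-patient module dysregulation scores relative to healthy controls, and
# Ward clustering of modules and patients into lo/im/hi interferon subgroups.

#' Per-gene z-scores of patients against the healthy-control distribution
#'
#' `z_gp = (x_gp - mean_HC(g)) / sd_HC(g)` with the HC sample standard
#' deviation (ddof = 1). Genes with zero HC variance are dropped with a
#' warning.
#'
#' @param em `ExpressionMatrix` (log-CPM).
#' @param hc_ids Healthy-control sample ids (at least 2).
#' @param target_ids Patient sample ids to score.
#' @param genes Gene ids (e.g. one module).
#' @return Numeric matrix, retained genes x patients.
#' @export
gene_z <- function(em, hc_ids, target_ids, genes) {
  if (length(hc_ids) < 2) stop("need at least 2 healthy controls")
  genes <- intersect(genes, gene_ids(em))
  if (!length(genes)) stop("none of the module genes are present in the expression matrix")
  hc <- em$values[genes, hc_ids, drop = FALSE]
  mu <- rowMeans(hc)
  sdv <- apply(hc, 1, stats::sd)
  if (any(sdv == 0)) {
    warning(sum(sdv == 0), " gene(s) with zero HC variance excluded from z-scoring")
    keep <- sdv > 0
    if (!any(keep)) stop("all module genes have zero variance among healthy controls")
    genes <- genes[keep]
    mu <- mu[keep]
    sdv <- sdv[keep]
  }
  (em$values[genes, target_ids, drop = FALSE] - mu) / sdv
}

#' Module dysregulation score per patient
#'
#' Mean over the module's (retained) genes of the per-gene z-score against
#' healthy controls; the study's stratification statistic.
#'
#' @inheritParams gene_z
#' @param module Gene ids of one module.
#' @return Named numeric vector, one score per patient.
#' @export
module_z <- function(em, hc_ids, target_ids, module) {
  colMeans(gene_z(em, hc_ids, target_ids, module))
}

#' Module score matrix over a set of modules
#'
#' @inheritParams gene_z
#' @param modules Either a named list of gene-id vectors or a list of
#'   `CoexpressionModule` objects.
#' @return A `ModuleScoreMatrix`: list with `z` (modules x patients matrix)
#'   and `subgroup` (NULL until [label_ifn_subgroups()] is applied).
#' @export
module_score_matrix <- function(em, hc_ids, target_ids, modules) {
  sets <- module_gene_sets(modules)
  z <- t(vapply(
    sets, function(g) module_z(em, hc_ids, target_ids, g),
    numeric(length(target_ids))
  ))
  rownames(z) <- names(sets)
  colnames(z) <- target_ids
  structure(list(z = z, subgroup = NULL), class = "ModuleScoreMatrix")
}

module_gene_sets <- function(modules) {
  if (is.list(modules) && length(modules) && inherits(modules[[1]], "CoexpressionModule")) {
    sets <- lapply(modules, `[[`, "genes")
    names(sets) <- vapply(modules, function(m) {
      if (!is.na(m$annotation) && !identical(m$annotation, "unannotated")) m$annotation else m$name
    }, character(1))
    names(sets) <- make.unique(names(sets))
    sets
  } else {
    if (is.null(names(modules))) stop("modules must be named")
    modules
  }
}

#' Modules with prominent dysregulation in at least one subgroup
#'
#' Keeps a module iff the absolute subgroup-mean z-score exceeds
#' `threshold` (strict) in at least one patient subgroup.
#'
#' @param scores A `ModuleScoreMatrix` or plain modules x patients matrix.
#' @param subgroups Named character vector mapping patient id to subgroup.
#' @param threshold Prominence gate (default 1).
#' @return Character vector of module names.
#' @export
prominent_modules <- function(scores, subgroups, threshold = 1) {
  z <- if (inherits(scores, "ModuleScoreMatrix")) scores$z else scores
  subgroups <- subgroups[colnames(z)]
  keep <- apply(z, 1, function(row) {
    means <- tapply(row, subgroups, mean)
    max(abs(means)) > threshold
  })
  rownames(z)[keep]
}

#' Ward hierarchical clustering of a score matrix
#'
#' Ward.D2 linkage on Euclidean distances, cut into `k` groups. Items are
#' either the matrix columns (patients) or rows (modules).
#'
#' @param mat Numeric matrix.
#' @param k Number of clusters.
#' @param axis Cluster `"columns"` (default) or `"rows"`.
#' @return List with `tree` (hclust) and `labels` (named integer vector).
#' @export
ward_cluster <- function(mat, k, axis = c("columns", "rows")) {
  axis <- match.arg(axis)
  items <- if (axis == "columns") t(mat) else mat
  if (k > nrow(items)) stop("k exceeds the number of items to cluster")
  tree <- stats::hclust(stats::dist(items), method = "ward.D2")
  labels <- stats::cutree(tree, k = k)
  names(labels) <- rownames(items)
  list(tree = tree, labels = labels)
}

#' Label patient clusters as lo/im/hi interferon subgroups
#'
#' Ranks the `k = 3` patient clusters by their mean IFN-module z-score
#' (ascending) and labels them lo, im, hi. Ties are broken by cluster index
#' with a warning.
#'
#' @param scores A `ModuleScoreMatrix`.
#' @param labels Named integer cluster labels per patient (from
#'   [ward_cluster()]).
#' @param ifn_module Row name of the IFN-annotated module in `scores$z`.
#' @return The `ModuleScoreMatrix` with `subgroup` filled in (named character
#'   vector with values `"lo"`, `"im"`, `"hi"`).
#' @export
label_ifn_subgroups <- function(scores, labels, ifn_module) {
  z <- scores$z
  if (!ifn_module %in% rownames(z)) stop("IFN module '", ifn_module, "' not found in score matrix")
  if (length(unique(labels)) != 3) stop("expected exactly 3 patient clusters")
  ifn <- z[ifn_module, names(labels)]
  means <- tapply(ifn, labels, mean)
  if (anyDuplicated(means)) {
    warning("tied cluster means on the IFN module; breaking ties by cluster index")
  }
  ord <- order(means, as.integer(names(means)))
  map <- stats::setNames(c("lo", "im", "hi"), names(means)[ord])
  scores$subgroup <- stats::setNames(unname(map[as.character(labels)]), names(labels))
  scores
}
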