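# Weighted coexpression module detection with topological overlap, a
# discovery/replication design, and annotation against reference module
# collections (curated blood transcriptional module compendia).

#' Network construction parameters
#'
#' @param beta Soft-threshold power applied to `|cor|` (default 6, the usual
#'   choice for unsigned networks).
#' @param min_module_size Smallest cluster kept as a module (default 30).
#' @param cut_height Static cut height on the 1-TOM average-linkage tree
#'   (default 0.90; on the 1-TOM scale correlated blocks merge well below
#'   this while unrelated genes sit near 1).
#' @param kme_min Module-membership gate: after the cut, genes whose
#'   correlation with their cluster's eigengene falls below this value (in
#'   absolute value) are returned to the unassigned pool (default 0.65).
#'   This is the usual kME pruning step that removes genes swept into a
#'   cluster by chance correlation in small cohorts.
#' @param cor_type `"pearson"` or `"spearman"`.
#' @param network_type `"signed_hybrid"` (default; negative correlations get
#'   zero adjacency, so anti-correlated genes never share a module) or
#'   `"unsigned"` (adjacency from `|cor|`).
#' @return A list of class `NetworkParams`.
#' @export
network_params <- function(beta = 6L, min_module_size = 30L, cut_height = 0.90,
                           kme_min = 0.65, cor_type = c("pearson", "spearman"),
                           network_type = c("signed_hybrid", "unsigned")) {
  cor_type <- match.arg(cor_type)
  network_type <- match.arg(network_type)
  beta <- as.integer(beta)
  if (beta < 1L) stop("beta must be a positive integer")
  if (min_module_size < 5L) stop("min_module_size must be at least 5")
  if (cut_height <= 0 || cut_height > 1) stop("cut_height must be in (0, 1]")
  if (kme_min < 0 || kme_min >= 1) stop("kme_min must be in [0, 1)")
  structure(
    list(
      beta = beta, min_module_size = as.integer(min_module_size),
      cut_height = cut_height, kme_min = kme_min, cor_type = cor_type,
      network_type = network_type
    ),
    class = "NetworkParams"
  )
}

gene_correlation <- function(em, cor_type = "pearson") {
  x <- t(em$values)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop(
      "constant genes present (filter first): ",
      paste(utils::head(gene_ids(em)[sds == 0], 5), collapse = ", ")
    )
  }
  stats::cor(x, method = cor_type)
}

#' Scale-free topology fit of a connectivity vector
#'
#' Bins connectivities, regresses `log10` frequency on `log10` mean binned
#' connectivity, and reports the fit.
#'
#' @param k Connectivity vector (row sums of the adjacency minus 1).
#' @param nbreaks Number of equal-width bins (default 10).
#' @return List with `r2` and `slope` (slope < 0 for scale-free-like decay).
#' @export
scale_free_fit <- function(k, nbreaks = 10) {
  k <- k[is.finite(k) & k > 0]
  if (length(unique(k)) < 3 || diff(range(k)) < 1e-8 * max(k)) {
    return(list(r2 = NA_real_, slope = NA_real_))
  }
  bins <- cut(k, breaks = nbreaks)
  freq <- tapply(k, bins, length)
  kmean <- tapply(k, bins, mean)
  keep <- !is.na(freq) & freq > 0 & kmean > 0
  if (sum(keep) < 3) return(list(r2 = NA_real_, slope = NA_real_))
  fit <- stats::lm(log10(freq[keep]) ~ log10(kmean[keep]))
  list(r2 = summary(fit)$r.squared, slope = unname(stats::coef(fit)[2]))
}

#' Choose the soft-threshold power
#'
#' Smallest candidate `beta` whose adjacency `|cor|^beta` yields a scale-free
#' fit with `r2 >= r2_cut` and negative slope; if none qualifies, the
#' candidate maximising `r2`. Degenerate inputs (all genes near-perfectly
#' correlated) fall back to the largest candidate with a warning.
#'
#' @param em `ExpressionMatrix` (log-CPM), at least 10 samples.
#' @param candidate_betas Integer candidates (default 1-10, 12, 14, ..., 20).
#' @param r2_cut Scale-free fit threshold (default 0.8).
#' @param cor_type Correlation type.
#' @return The chosen power (integer).
#' @export
pick_soft_threshold <- function(em, candidate_betas = c(1:10, seq(12L, 20L, 2L)),
                                r2_cut = 0.8, cor_type = "pearson") {
  if (ncol(em$values) < 10) stop("need at least 10 samples to pick a power")
  candidate_betas <- as.integer(candidate_betas)
  if (length(candidate_betas) == 1L) return(candidate_betas)
  ac <- abs(gene_correlation(em, cor_type))
  diag(ac) <- 0
  fits <- lapply(candidate_betas, function(b) scale_free_fit(rowSums(ac^b)))
  r2 <- vapply(fits, function(f) ifelse(is.na(f$r2), -Inf, f$r2), numeric(1))
  slope <- vapply(fits, `[[`, numeric(1), "slope")
  if (all(!is.finite(r2))) {
    warning("degenerate connectivity distribution; falling back to the largest candidate power")
    return(max(candidate_betas))
  }
  ok <- which(is.finite(r2) & r2 >= r2_cut & !is.na(slope) & slope < 0)
  if (length(ok)) candidate_betas[min(ok)] else candidate_betas[which.max(r2)]
}

#' Topological overlap from an adjacency matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k` the connectivity (row sums excluding the diagonal); diagonal set to 1.
#'
#' @param adjacency Symmetric matrix with entries in `[0, 1]`.
#' @return The TOM similarity matrix.
#' @export
tom_similarity <- function(adjacency) {
  a <- adjacency
  diag(a) <- 0
  k <- rowSums(a)
  shared <- a %*% a
  kmin <- outer(k, k, pmin)
  tom <- (shared + a) / (kmin + 1 - a)
  diag(tom) <- 1
  tom
}

#' Detect coexpression modules in one cohort
#'
#' Signed-hybrid (or unsigned) adjacency raised to `beta`, topological
#' overlap, average-linkage clustering of `1 - TOM`, static cut at
#' `cut_height`. Clusters passing `min_module_size` act as module cores and
#' are refined by eigengene membership (kME): core genes with
#' `kME < kme_min` return to the unassigned pool, and every unassigned gene
#' is recruited by the module for which its kME is maximal, provided it
#' reaches `kme_min`. Each module carries an eigengene profile: the first
#' principal-component score of its standardized expression, sign-oriented
#' to correlate positively with the module's mean expression.
#'
#' @param em `ExpressionMatrix` (log-CPM) restricted to one cohort's samples.
#' @param params A `NetworkParams` object.
#' @param cohort Label recorded on each module.
#' @return List of `CoexpressionModule` objects (name, genes, cohort,
#'   eigen_profile, annotation, replicated), ordered by decreasing size.
#' @export
detect_modules <- function(em, params = network_params(), cohort = "discovery") {
  if (nrow(em$values) < params$min_module_size) {
    stop("fewer genes than min_module_size")
  }
  cc <- gene_correlation(em, params$cor_type)
  adj <- if (params$network_type == "signed_hybrid") {
    pmax(cc, 0)^params$beta
  } else {
    abs(cc)^params$beta
  }
  tom <- tom_similarity(adj)
  tree <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  labels <- stats::cutree(tree, h = params$cut_height)
  sizes <- table(labels)
  keep <- names(sizes)[sizes >= params$min_module_size]
  gene_sets <- lapply(keep, function(kk) gene_ids(em)[labels == as.integer(kk)])
  if (params$kme_min > 0 && length(gene_sets)) {
    # kME refinement: prune weak core members, then recruit unassigned
    # genes to the module with maximal membership
    kme <- vapply(gene_sets, function(genes) {
      eig <- module_eigengene(em, genes)
      stats::cor(t(em$values), eig)[, 1]
    }, numeric(nrow(em$values)))
    if (params$network_type != "signed_hybrid") kme <- abs(kme)
    best <- max.col(kme, ties.method = "first")
    assigned <- ifelse(kme[cbind(seq_len(nrow(kme)), best)] >= params$kme_min, best, 0L)
    gene_sets <- lapply(seq_along(gene_sets), function(i) gene_ids(em)[assigned == i])
  }
  gene_sets <- gene_sets[lengths(gene_sets) >= params$min_module_size]
  gene_sets <- gene_sets[order(-lengths(gene_sets))]
  mods <- vector("list", length(gene_sets))
  for (i in seq_along(gene_sets)) {
    genes <- gene_sets[[i]]
    mods[[i]] <- structure(
      list(
        name = sprintf("%s_M%02d", cohort, i),
        genes = genes,
        cohort = cohort,
        eigen_profile = module_eigengene(em, genes),
        annotation = NA_character_,
        replicated = NA
      ),
      class = "CoexpressionModule"
    )
  }
  mods
}

#' First-PC eigengene of a gene set, oriented with mean expression
#' @param em `ExpressionMatrix`.
#' @param genes Gene ids (must be present in `em`).
#' @return Named numeric vector, one score per sample.
#' @export
module_eigengene <- function(em, genes) {
  x <- em$values[intersect(genes, gene_ids(em)), , drop = FALSE]
  if (!nrow(x)) stop("none of the genes are present in the expression matrix")
  xs <- t(scale(t(x))) # standardize each gene across samples
  xs[!is.finite(xs)] <- 0
  pc <- stats::prcomp(t(xs), center = FALSE, scale. = FALSE)$x[, 1]
  m <- colMeans(xs)
  if (stats::sd(m) > 0 && stats::cor(pc, m) < 0) pc <- -pc
  stats::setNames(pc, sample_ids(em))
}

#' Declare discovery modules replicated against a replication cohort
#'
#' A discovery module is replicated iff its best-matching replication module
#' (by Jaccard index on gene sets) reaches `jaccard_min` AND the overlap's
#' hypergeometric p-value survives BH correction across discovery modules at
#' `alpha`. Replicated modules carry their discovery gene sets forward.
#'
#' @param discovery_mods,replication_mods Module lists from [detect_modules()].
#' @param universe Gene universe common to both cohorts.
#' @param jaccard_min Jaccard threshold (default 0.25).
#' @param alpha FDR threshold for the overlap test (default 0.05).
#' @return The discovery modules with `replicated`, `partner`, `jaccard` and
#'   `overlap_fdr` filled in.
#' @export
replicate_modules <- function(discovery_mods, replication_mods, universe,
                              jaccard_min = 0.25, alpha = 0.05) {
  if (!length(discovery_mods)) return(discovery_mods)
  N <- length(unique(universe))
  best <- lapply(discovery_mods, function(dm) {
    if (!length(replication_mods)) {
      return(list(j = 0, p = 1, partner = NA_character_))
    }
    js <- vapply(replication_mods, function(rm) {
      length(intersect(dm$genes, rm$genes)) / length(union(dm$genes, rm$genes))
    }, numeric(1))
    b <- which.max(js)
    k <- length(intersect(dm$genes, replication_mods[[b]]$genes))
    K <- length(intersect(replication_mods[[b]]$genes, universe))
    n <- length(intersect(dm$genes, universe))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    list(j = js[b], p = p, partner = replication_mods[[b]]$name)
  })
  fdr <- bh_adjust(vapply(best, `[[`, numeric(1), "p"))
  for (i in seq_along(discovery_mods)) {
    discovery_mods[[i]]$jaccard <- best[[i]]$j
    discovery_mods[[i]]$overlap_fdr <- fdr[i]
    discovery_mods[[i]]$partner <- best[[i]]$partner
    discovery_mods[[i]]$replicated <- best[[i]]$j >= jaccard_min && fdr[i] < alpha
  }
  discovery_mods
}

#' Annotate modules against reference gene-set collections
#'
#' Dual gate: the Pearson correlation between the module eigengene and a
#' reference set's mean standardized expression (over the same samples) must
#' reach `min_abs_r` in absolute value, and the gene overlap's hypergeometric
#' FDR (across references, per module) must be below `alpha`. The qualifying
#' reference with largest `|r|` becomes the annotation; otherwise
#' `"unannotated"`.
#'
#' @param modules List of `CoexpressionModule`s.
#' @param reference_sets Named list of reference gene sets (GMT).
#' @param em `ExpressionMatrix` over the samples the eigengenes were computed
#'   on.
#' @param min_abs_r Correlation gate (default 0.5).
#' @param alpha Overlap FDR gate (default 0.05).
#' @return The modules with `annotation` (and `annotation_r`) filled in.
#' @export
annotate_modules <- function(modules, reference_sets, em, min_abs_r = 0.5, alpha = 0.05) {
  if (!length(reference_sets)) stop("reference gene-set collection is empty")
  xs <- t(scale(t(em$values)))
  xs[!is.finite(xs)] <- 0
  universe <- gene_ids(em)
  N <- length(universe)
  profiles <- lapply(reference_sets, function(g) {
    g <- intersect(g, universe)
    if (!length(g)) return(NULL)
    colMeans(xs[g, , drop = FALSE])
  })
  for (i in seq_along(modules)) {
    mod <- modules[[i]]
    r <- vapply(profiles, function(pr) {
      if (is.null(pr) || stats::sd(pr) == 0 || stats::sd(mod$eigen_profile) == 0) {
        return(NA_real_)
      }
      stats::cor(mod$eigen_profile, pr[names(mod$eigen_profile)])
    }, numeric(1))
    pov <- vapply(names(reference_sets), function(nm) {
      K <- length(intersect(reference_sets[[nm]], universe))
      k <- length(intersect(mod$genes, intersect(reference_sets[[nm]], universe)))
      n <- length(intersect(mod$genes, universe))
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    }, numeric(1))
    fdr <- bh_adjust(pov)
    ok <- which(!is.na(r) & abs(r) >= min_abs_r & fdr < alpha)
    if (length(ok)) {
      pick <- ok[which.max(abs(r[ok]))]
      modules[[i]]$annotation <- names(reference_sets)[pick]
      modules[[i]]$annotation_r <- unname(r[pick])
    } else {
      modules[[i]]$annotation <- "unannotated"
      modules[[i]]$annotation_r <- NA_real_
    }
  }
  modules
}
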