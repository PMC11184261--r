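# Chief-regulator ranking by target-set enrichment, and drug-gene annotation
# of dysregulated module genes split by direction and interaction type.

#' Rank candidate regulators of a module
#'
#' Hypergeometric enrichment of each regulator's target set in the module
#' (the same mathematics as [ora()], without term-size filters), BH-adjusted
#' across regulators and sorted by p-value. The top hit is the module's
#' "chief regulator".
#'
#' @param module_genes Character vector of module gene ids.
#' @param regulons Named list: regulator -> target gene ids (GMT).
#' @param universe Background gene ids.
#' @return Data frame with columns `regulator`, `module_overlap`, `p`, `fdr`,
#'   `target_genes_in_module`, sorted by p.
#' @export
rank_regulators <- function(module_genes, regulons, universe) {
  if (!length(regulons)) stop("regulon collection is empty")
  res <- ora(module_genes, regulons, universe,
    min_size = 1, max_size = Inf,
    restrict_to_library = FALSE
  )
  res <- res[order(res$p, res$term_id), ]
  data.frame(
    regulator = res$term_id,
    module_overlap = res$overlap_count,
    p = res$p,
    fdr = res$fdr,
    target_genes_in_module = res$overlap_genes,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Annotate dysregulated module genes with drugs
#'
#' Genes with subgroup-mean |z| at or above `min_abs_z` are classed up- or
#' downregulated and joined against a local drug-gene interaction table.
#' Inhibitors of upregulated genes and stimulators of downregulated genes
#' are flagged as counteracting candidates; other combinations are reported
#' but flagged non-counteracting.
#'
#' @param genes Gene ids of the annotated module.
#' @param mean_z Named numeric vector: subgroup-mean per-gene z-score.
#' @param subgroup Subgroup label recorded on each output row.
#' @param interactions Data frame with columns `drug`, `gene`,
#'   `interaction` (one of inhibitor / stimulator / other).
#' @param min_abs_z Direction gate on |mean z| (default 0.5).
#' @return Data frame with columns `gene`, `drug`, `interaction`,
#'   `gene_direction`, `subgroup`, `counteracting`.
#' @export
annotate_drugs <- function(genes, mean_z, subgroup, interactions, min_abs_z = 0.5) {
  need <- c("drug", "gene", "interaction")
  if (!all(need %in% names(interactions))) {
    stop("interactions table needs columns drug, gene, interaction")
  }
  mean_z <- mean_z[intersect(genes, names(mean_z))]
  directed <- mean_z[abs(mean_z) >= min_abs_z]
  if (!length(directed)) {
    return(data.frame(
      gene = character(), drug = character(), interaction = character(),
      gene_direction = character(), subgroup = character(),
      counteracting = logical(), stringsAsFactors = FALSE
    ))
  }
  dir <- ifelse(directed > 0, "up", "down")
  hit <- interactions[interactions$gene %in% names(directed), , drop = FALSE]
  out <- data.frame(
    gene = hit$gene,
    drug = hit$drug,
    interaction = hit$interaction,
    gene_direction = unname(dir[hit$gene]),
    subgroup = rep(subgroup, nrow(hit)),
    stringsAsFactors = FALSE
  )
  out$counteracting <- (out$gene_direction == "up" & out$interaction == "inhibitor") |
    (out$gene_direction == "down" & out$interaction == "stimulator")
  rownames(out) <- NULL
  out
}
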