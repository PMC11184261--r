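#' Overrepresentation analysis against a gene-set library
#'
#' Hypergeometric upper-tail test of a query gene list against each set of a
#' GMT-style library. With `N = |universe|`, `K = |term  universe|`,
#' `n = |query  universe|` and `k` the overlap, the per-term p-value is
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`, BH-adjusted across tested
#' terms. The reported `gene_ratio` is `k` divided by the number of query
#' genes annotated anywhere in the library (the library's own universe), the
#' convention used for dot-plot style summaries.
#'
#' @param query Character vector of gene ids (e.g. a DEG signature).
#' @param gene_sets Named list of character vectors (see [read_gmt()]).
#' @param universe Background gene ids (e.g. all genes tested for DE). The
#'   effective universe is its intersection with library-annotated genes when
#'   `restrict_to_library = TRUE` (default), standard ORA practice.
#' @param min_size,max_size Term-size filters applied after intersection
#'   with the universe (defaults 10 and 500).
#' @param restrict_to_library Intersect the universe with the union of
#'   library genes before testing.
#' @return Data frame sorted by `fdr` then `p`, with columns `term_id`,
#'   `term_name`, `overlap_count`, `gene_ratio`, `p`, `fdr` and
#'   `overlap_genes` (comma-separated).
#' @export
ora <- function(query, gene_sets, universe, min_size = 10, max_size = 500,
                restrict_to_library = TRUE) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  lib_genes <- unique(unlist(gene_sets, use.names = FALSE))
  if (restrict_to_library) universe <- intersect(universe, lib_genes)
  if (!length(universe)) stop("universe is empty after intersection with the library")
  query_u <- intersect(unique(query), universe)
  query_lib <- intersect(unique(query), intersect(universe, lib_genes))
  n_lib <- length(query_lib)

  desc <- attr(gene_sets, "descriptions")
  rows <- lapply(names(gene_sets), function(nm) {
    term <- intersect(gene_sets[[nm]], universe)
    K <- length(term)
    if (K < min_size || K > max_size) return(NULL)
    hits <- intersect(term, query_u)
    k <- length(hits)
    p <- stats::phyper(k - 1, K, length(universe) - K, length(query_u), lower.tail = FALSE)
    data.frame(
      term_id = nm,
      term_name = if (!is.null(desc) && nm %in% names(desc) && desc[[nm]] != "na") desc[[nm]] else nm,
      overlap_count = k,
      gene_ratio = if (n_lib > 0) k / n_lib else NA_real_,
      p = p,
      overlap_genes = paste(sort(hits), collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(
      term_id = character(), term_name = character(), overlap_count = integer(),
      gene_ratio = numeric(), p = numeric(), fdr = numeric(),
      overlap_genes = character(), stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  out <- out[order(out$fdr, out$p, out$term_id), c(
    "term_id", "term_name", "overlap_count", "gene_ratio", "p", "fdr", "overlap_genes"
  )]
  rownames(out) <- NULL
  out
}
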