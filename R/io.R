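# Readers/writers for the plain-text formats used across the pipeline:
# counts as TSV or MatrixMarket, gene sets as GMT, signed pathway graphs as
# SIF plus a JSON sidecar, and generic TSV tables. All text UTF-8 with LF.

#' Read / write an expression matrix as TSV
#'
#' Layout: first column `gene_id`, remaining columns one per sample.
#'
#' @param x An `ExpressionMatrix`.
#' @param path File path.
#' @param units Units tag to attach on read.
#' @return `read_counts_tsv` returns an `ExpressionMatrix`.
#' @export
write_counts_tsv <- function(x, path) {
  df <- data.frame(gene_id = gene_ids(x), x$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path, units = "counts") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") stop("expected first column 'gene_id' in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  expression_matrix(m, units = units)
}

#' Read / write an expression matrix as MatrixMarket
#'
#' Writes `<prefix>.mtx` plus `<prefix>.rows.txt` and `<prefix>.cols.txt`
#' with gene and sample identifiers, one per line.
#'
#' @param x An `ExpressionMatrix`.
#' @param prefix Path prefix (without extension).
#' @param units Units tag to attach on read.
#' @export
write_counts_mtx <- function(x, prefix) {
  Matrix::writeMM(Matrix::Matrix(x$values, sparse = TRUE), paste0(prefix, ".mtx"))
  writeLines(gene_ids(x), paste0(prefix, ".rows.txt"))
  writeLines(sample_ids(x), paste0(prefix, ".cols.txt"))
  invisible(prefix)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(prefix, units = "counts") {
  m <- as.matrix(Matrix::readMM(paste0(prefix, ".mtx")))
  rownames(m) <- readLines(paste0(prefix, ".rows.txt"))
  colnames(m) <- readLines(paste0(prefix, ".cols.txt"))
  expression_matrix(m, units = units)
}

#' Read / write gene-set collections in GMT format
#'
#' One set per line: `name<TAB>description<TAB>gene1<TAB>gene2...`. Sets are
#' represented in R as a named list of character vectors; descriptions are
#' kept in a `"descriptions"` attribute (named character vector).
#'
#' @param sets Named list of character vectors.
#' @param path File path.
#' @param descriptions Optional named character vector of descriptions.
#' @return `read_gmt` returns the named list with a `descriptions` attribute.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("gene sets must have unique names")
  }
  if (is.null(descriptions)) descriptions <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    desc <- if (!is.null(descriptions) && nm %in% names(descriptions)) descriptions[[nm]] else "na"
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  desc <- vapply(parts, `[[`, character(1), 2)
  names(desc) <- names(sets)
  attr(sets, "descriptions") <- desc
  sets
}

#' Read / write a signed pathway graph as SIF + JSON sidecar
#'
#' The SIF carries one edge per line, `source<TAB>relation<TAB>target` with
#' relation `activates` or `inhibits`. The sidecar JSON carries the node
#' roles and gene memberships: `{"name": ..., "nodes": {id: {"genes": [...],
#' "role": "receptor"|"intermediate"|"effector"}}, "targets": {...}}`.
#'
#' @param graph A `PathwayGraph` (see [pathway_graph()]).
#' @param sif_path,sidecar_path File paths.
#' @export
write_sif_pathway <- function(graph, sif_path, sidecar_path) {
  rel <- ifelse(graph$edges$sign > 0, "activates", "inhibits")
  writeLines(paste(graph$edges$from, rel, graph$edges$to, sep = "\t"), sif_path)
  nodes <- lapply(seq_len(nrow(graph$nodes)), function(i) {
    id <- graph$nodes$id[i]
    list(genes = as.list(graph$node_genes[[id]]), role = graph$nodes$role[i])
  })
  names(nodes) <- graph$nodes$id
  jsonlite::write_json(
    list(name = graph$name, nodes = nodes, targets = as.list(graph$target_annotation)),
    sidecar_path,
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(sif_path)
}

#' @rdname write_sif_pathway
#' @export
read_sif_pathway <- function(sif_path, sidecar_path) {
  parts <- strsplit(readLines(sif_path), "\t", fixed = TRUE)
  edges <- data.frame(
    from = vapply(parts, `[[`, character(1), 1),
    to = vapply(parts, `[[`, character(1), 3),
    sign = ifelse(vapply(parts, `[[`, character(1), 2) == "activates", 1, -1),
    stringsAsFactors = FALSE
  )
  side <- jsonlite::read_json(sidecar_path)
  ids <- names(side$nodes)
  nodes <- data.frame(
    id = ids,
    role = vapply(side$nodes, function(n) n$role, character(1)),
    stringsAsFactors = FALSE
  )
  node_genes <- lapply(side$nodes, function(n) unlist(n$genes, use.names = FALSE))
  names(node_genes) <- ids
  pathway_graph(
    name = side$name, nodes = nodes, edges = edges, node_genes = node_genes,
    target_annotation = unlist(side$targets)
  )
}

#' Read / write plain TSV tables (metadata, serology, drug interactions)
#' @param df A data.frame.
#' @param path File path.
#' @export
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
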