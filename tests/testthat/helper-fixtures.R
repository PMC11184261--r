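# Shared fixtures. The default synthetic cohort pipeline is expensive enough
# to cache per seed; all fixture data are generated in code.

.pipeline_cache <- new.env(parent = emptyenv())

cached_pipeline <- function(seed) {
  key <- paste0("seed_", seed)
  if (is.null(.pipeline_cache[[key]])) {
    .pipeline_cache[[key]] <- run_pipeline(pipeline_config(seed = seed))
  }
  .pipeline_cache[[key]]
}

ln_truth <- function(res) {
  meta <- res$data$meta
  stats::setNames(
    meta$subgroup[meta$group == "LN"],
    meta$sample_id[meta$group == "LN"]
  )
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# small counts ExpressionMatrix with given dimensions
toy_counts <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  expression_matrix(m, units = "counts")
}

# two planted coexpression blocks (within-block correlation rho, across 0)
block_fixture <- function(n_per_block = 60, n_samples = 40, rho = 0.9, seed = 1) {
  set.seed(seed)
  mk_block <- function(prefix) {
    f <- rnorm(n_samples)
    x <- t(vapply(
      seq_len(n_per_block),
      function(i) sqrt(rho) * f + sqrt(1 - rho) * rnorm(n_samples),
      numeric(n_samples)
    ))
    rownames(x) <- sprintf("%s%03d", prefix, seq_len(n_per_block))
    x
  }
  m <- rbind(mk_block("A"), mk_block("B"))
  colnames(m) <- sprintf("s%03d", seq_len(n_samples))
  expression_matrix(m, units = "logcpm")
}

# three-node activation chain R -> I -> E
chain_graph <- function() {
  pathway_graph(
    name = "chain",
    nodes = data.frame(
      id = c("R", "I", "E"),
      role = c("receptor", "intermediate", "effector"),
      stringsAsFactors = FALSE
    ),
    edges = data.frame(
      from = c("R", "I"), to = c("I", "E"), sign = c(1, 1),
      stringsAsFactors = FALSE
    ),
    node_genes = list(R = "gR", I = "gI", E = "gE"),
    target_annotation = c(drugX = "R")
  )
}

# random layered signed DAG with valid roles, for propagation properties
random_dag <- function(seed) {
  set.seed(seed)
  n_layers <- sample(3:5, 1)
  sizes <- sample(1:3, n_layers, replace = TRUE)
  ids <- unlist(lapply(seq_len(n_layers), function(l) {
    sprintf("L%d_%d", l, seq_len(sizes[l]))
  }))
  layer_of <- rep(seq_len(n_layers), sizes)
  roles <- ifelse(layer_of == 1, "receptor",
    ifelse(layer_of == n_layers, "effector", "intermediate")
  )
  edges <- do.call(rbind, lapply(which(layer_of > 1), function(i) {
    parents <- which(layer_of == layer_of[i] - 1)
    pick <- parents[sample.int(length(parents), sample(seq_along(parents), 1))]
    data.frame(
      from = ids[pick], to = ids[i],
      sign = sample(c(-1, 1), length(pick), replace = TRUE),
      stringsAsFactors = FALSE
    )
  }))
  # ensure every effector keeps at least one activating incoming edge so it
  # stays reachable; flip one inhibitor if needed
  g <- pathway_graph(
    name = paste0("rand", seed),
    nodes = data.frame(id = ids, role = roles, stringsAsFactors = FALSE),
    edges = edges
  )
  list(graph = g, v = stats::setNames(runif(length(ids)), ids))
}
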