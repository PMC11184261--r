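# Mechanistic pathway signal propagation and in-silico target inhibition.
# Node values v (from HC-referenced unit-scaled expression) are propagated
# through a signed directed graph:
#   receptors:  S = v
#   elsewhere:  S_n = v_n * (1 - prod_{a in activators}(1 - S_a))
#                       * prod_{i in inhibitors}(1 - S_i)
# Inhibiting a drug target multiplies its node value by a factor (0.1 by
# default); the per-patient response score is the summed absolute change of
# the effector-node signals.

#' Construct a signed pathway graph
#'
#' @param name Graph name.
#' @param nodes Data frame with columns `id` and `role`
#'   (`receptor` / `intermediate` / `effector`).
#' @param edges Data frame with columns `from`, `to`, `sign` (+1 activating,
#'   -1 inhibiting).
#' @param node_genes Named list: node id -> measured gene ids.
#' @param target_annotation Named character vector: drug target -> node id.
#' @return A `PathwayGraph` object. Validates that there is at least one
#'   receptor and one effector, signs are in {-1, +1}, and every effector is
#'   reachable from a receptor.
#' @export
pathway_graph <- function(name, nodes, edges, node_genes = list(),
                          target_annotation = character()) {
  if (!all(c("id", "role") %in% names(nodes))) stop("nodes need columns id, role")
  if (anyDuplicated(nodes$id)) stop("node ids must be unique")
  bad <- setdiff(nodes$role, c("receptor", "intermediate", "effector"))
  if (length(bad)) stop("unknown node roles: ", paste(bad, collapse = ", "))
  if (!any(nodes$role == "receptor")) stop("graph '", name, "' has no receptor node")
  if (!any(nodes$role == "effector")) stop("graph '", name, "' has no effector node")
  if (nrow(edges)) {
    if (!all(c("from", "to", "sign") %in% names(edges))) {
      stop("edges need columns from, to, sign")
    }
    if (!all(edges$sign %in% c(-1, 1))) stop("edge signs must be +1 or -1")
    unknown <- setdiff(c(edges$from, edges$to), nodes$id)
    if (length(unknown)) stop("edges reference unknown nodes: ", paste(unknown, collapse = ", "))
  }
  g <- structure(
    list(
      name = name, nodes = nodes, edges = edges,
      node_genes = node_genes, target_annotation = target_annotation
    ),
    class = "PathwayGraph"
  )
  reach <- reachable_from(g, nodes$id[nodes$role == "receptor"])
  eff <- nodes$id[nodes$role == "effector"]
  if (!all(eff %in% reach)) {
    stop(
      "effector(s) unreachable from any receptor in graph '", name, "': ",
      paste(setdiff(eff, reach), collapse = ", ")
    )
  }
  g
}

reachable_from <- function(graph, start) {
  seen <- start
  frontier <- start
  while (length(frontier)) {
    nxt <- unique(graph$edges$to[graph$edges$from %in% frontier])
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  seen
}

topological_order <- function(graph) {
  ids <- graph$nodes$id
  indeg <- stats::setNames(integer(length(ids)), ids)
  tab <- table(graph$edges$to)
  indeg[names(tab)] <- as.integer(tab)
  order <- character(0)
  queue <- ids[indeg == 0]
  edges <- graph$edges
  while (length(queue)) {
    n <- queue[1]
    queue <- queue[-1]
    order <- c(order, n)
    out <- edges$to[edges$from == n]
    for (m in out) {
      indeg[m] <- indeg[m] - 1L
      if (indeg[m] == 0L) queue <- c(queue, m)
    }
    edges <- edges[edges$from != n, , drop = FALSE]
  }
  if (length(order) < length(ids)) NULL else order # NULL when cyclic
}

#' Min-max scale expression to a healthy-control reference
#'
#' Per gene, values are scaled by the HC 1st-99th percentile range and
#' clamped to `[0, 1]`; genes with zero HC range map to 0.5 with a warning.
#'
#' @param em `ExpressionMatrix` (log-CPM).
#' @param hc_ids Healthy-control sample ids (at least 2).
#' @param lower,upper Anchor percentiles (defaults 0.01 and 0.99).
#' @return `ExpressionMatrix` with units `"unit_scaled"` (all samples kept).
#' @export
normalize_to_reference <- function(em, hc_ids, lower = 0.01, upper = 0.99) {
  if (length(hc_ids) < 2) stop("need at least 2 healthy controls")
  hc <- em$values[, hc_ids, drop = FALSE]
  lo <- apply(hc, 1, stats::quantile, probs = lower, names = FALSE)
  hi <- apply(hc, 1, stats::quantile, probs = upper, names = FALSE)
  rng <- hi - lo
  flat <- rng <= 0
  if (any(flat)) {
    warning(sum(flat), " gene(s) with zero HC range set to 0.5")
    rng[flat] <- 1
  }
  v <- (em$values - lo) / rng
  v[flat, ] <- 0.5
  v <- pmin(pmax(v, 0), 1)
  dimnames(v) <- dimnames(em$values)
  expression_matrix(v, units = "unit_scaled")
}

#' Node values of one sample
#'
#' The value of a node is the mean unit-scaled expression of its genes;
#' nodes with no measured gene default to 0.5 with a warning.
#'
#' @param graph A `PathwayGraph`.
#' @param em `ExpressionMatrix` with units `"unit_scaled"`.
#' @param sample Sample id.
#' @return Named numeric vector of node values in `[0, 1]`.
#' @export
node_values <- function(graph, em, sample) {
  if (em$units != "unit_scaled") stop("node_values expects unit-scaled expression")
  x <- stats::setNames(em$values[, sample], rownames(em$values))
  v <- vapply(graph$nodes$id, function(id) {
    g <- intersect(graph$node_genes[[id]], gene_ids(em))
    if (!length(g)) return(NA_real_)
    mean(x[g])
  }, numeric(1))
  if (anyNA(v)) {
    warning(sum(is.na(v)), " node(s) without measured genes set to 0.5 in graph '", graph$name, "'")
    v[is.na(v)] <- 0.5
  }
  v
}

#' Propagate node values to signals
#'
#' DAGs are evaluated in topological order; cyclic graphs by damped
#' fixed-point iteration (damping 0.5) to tolerance 1e-9, erroring on
#' non-convergence.
#'
#' @param graph A `PathwayGraph`.
#' @param v Named numeric node values in `[0, 1]`.
#' @param damping Damping factor for cyclic graphs (default 0.5).
#' @param tol,max_iter Convergence controls for cyclic graphs.
#' @return Named numeric vector of signals `S` in `[0, 1]`.
#' @export
propagate <- function(graph, v, damping = 0.5, tol = 1e-9, max_iter = 1000) {
  ids <- graph$nodes$id
  v <- v[ids]
  if (anyNA(v) || any(v < 0 | v > 1)) stop("node values must be in [0, 1] for every node")
  is_receptor <- stats::setNames(graph$nodes$role == "receptor", ids)
  parents <- lapply(ids, function(id) {
    e <- graph$edges[graph$edges$to == id, , drop = FALSE]
    list(act = e$from[e$sign > 0], inh = e$from[e$sign < 0])
  })
  names(parents) <- ids
  signal_of <- function(id, S) {
    if (is_receptor[[id]]) return(v[[id]])
    pa <- parents[[id]]
    act <- if (length(pa$act)) 1 - prod(1 - S[pa$act]) else 0
    inh <- if (length(pa$inh)) prod(1 - S[pa$inh]) else 1
    v[[id]] * act * inh
  }
  topo <- topological_order(graph)
  if (!is.null(topo)) {
    S <- stats::setNames(numeric(length(ids)), ids)
    for (id in topo) S[id] <- signal_of(id, S)
    return(S[ids])
  }
  # cyclic: damped fixed point
  S <- v
  for (iter in seq_len(max_iter)) {
    S_new <- vapply(ids, signal_of, numeric(1), S = S)
    S_next <- damping * S + (1 - damping) * S_new
    if (max(abs(S_next - S)) < tol) return(stats::setNames(S_next, ids))
    S <- S_next
  }
  stop("signal propagation failed to converge for graph '", graph$name, "'")
}

#' Simulate inhibition of a drug target in one patient
#'
#' Multiplies the target node's value by `factor` (0.1 by default), re-runs
#' the propagation, and scores the response as the summed absolute change of
#' the effector-node signals.
#'
#' @param graph A `PathwayGraph`.
#' @param v Named node values for one patient.
#' @param target Target node id, or a drug-target name registered in the
#'   graph's `target_annotation`.
#' @param factor Multiplication factor in `(0, 1]` (default 0.1).
#' @return List with `score`, `deltas` (per effector), `before`, `after`.
#' @export
simulate_inhibition <- function(graph, v, target, factor = 0.1) {
  if (factor <= 0 || factor > 1) stop("factor must be in (0, 1]")
  node <- if (target %in% graph$nodes$id) {
    target
  } else if (target %in% names(graph$target_annotation)) {
    graph$target_annotation[[target]]
  } else {
    stop("target '", target, "' is neither a node nor an annotated drug target")
  }
  before <- propagate(graph, v)
  v2 <- v
  v2[node] <- factor * v2[node]
  after <- propagate(graph, v2)
  eff <- graph$nodes$id[graph$nodes$role == "effector"]
  deltas <- after[eff] - before[eff]
  list(score = sum(abs(deltas)), deltas = deltas, before = before, after = after)
}

#' Classify anticipated responders
#'
#' A patient is an anticipated responder to a target when their response
#' score is greater than or equal to the mean response score over all
#' patients (ties inclusive, so at least one responder always exists).
#'
#' @param scores Named numeric vector of per-patient response scores
#'   (at least 2 patients).
#' @return Named logical vector.
#' @export
classify_responders <- function(scores) {
  if (length(scores) < 2) stop("need at least 2 patients")
  scores >= mean(scores)
}

#' Compare responder proportions between two subgroups
#'
#' Uses the classical expected-count rule: if any expected cell count of the
#' 2x2 table is below `expected_min`, a two-sided Fisher exact test;
#' otherwise Pearson's chi-square with Yates continuity correction (df = 1).
#'
#' @param table 2x2 integer matrix (rows: subgroups; columns:
#'   responder / non-responder).
#' @param expected_min Expected-count threshold (default 5).
#' @return List with `method` (`"fisher"` or `"chisq_yates"`), `p`, and the
#'   minimum expected count.
#' @export
compare_proportions <- function(table, expected_min = 5) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("expected a 2x2 table")
  if (any(table < 0) || any(table != round(table))) stop("table must hold nonnegative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("2x2 table has a zero margin")
  }
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected < expected_min)) {
    list(
      method = "fisher",
      p = stats::fisher.test(table)$p.value,
      min_expected = min(expected)
    )
  } else {
    list(
      method = "chisq_yates",
      p = suppressWarnings(stats::chisq.test(table, correct = TRUE)$p.value),
      min_expected = min(expected)
    )
  }
}

#' Per-target subgroup response report
#'
#' Responder proportions per patient subgroup for each simulated target, and
#' all pairwise subgroup comparisons via [compare_proportions()]. With a
#' single subgroup the pairwise tests are skipped with a note.
#'
#' @param results Data frame with columns `patient_id`, `target`, `score`,
#'   `responder`.
#' @param subgroups Named character vector: patient id -> subgroup.
#' @return List with `proportions` (data frame: target, subgroup, n,
#'   responders, proportion) and `tests` (data frame: target, group_a,
#'   group_b, method, p; NULL, with an explanatory `note` element, when a
#'   single subgroup makes pairwise testing impossible).
#' @export
subgroup_response_report <- function(results, subgroups) {
  results$subgroup <- unname(subgroups[results$patient_id])
  if (anyNA(results$subgroup)) stop("every patient needs a subgroup label")
  props <- do.call(rbind, lapply(split(results, results$target), function(d) {
    agg <- do.call(rbind, lapply(split(d, d$subgroup), function(s) {
      data.frame(
        target = s$target[1], subgroup = s$subgroup[1], n = nrow(s),
        responders = sum(s$responder),
        proportion = mean(s$responder), stringsAsFactors = FALSE
      )
    }))
    agg
  }))
  rownames(props) <- NULL
  groups <- sort(unique(results$subgroup))
  if (length(groups) < 2) {
    return(list(
      proportions = props, tests = NULL,
      note = "single subgroup: pairwise tests skipped"
    ))
  }
  pairs <- utils::combn(groups, 2)
  tests <- do.call(rbind, lapply(split(results, results$target), function(d) {
    do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      ga <- d[d$subgroup == pairs[1, j], ]
      gb <- d[d$subgroup == pairs[2, j], ]
      if (!nrow(ga) || !nrow(gb)) return(NULL)
      tab <- rbind(
        c(sum(ga$responder), sum(!ga$responder)),
        c(sum(gb$responder), sum(!gb$responder))
      )
      cp <- tryCatch(compare_proportions(tab), error = function(e) NULL)
      if (is.null(cp)) return(NULL)
      data.frame(
        target = d$target[1], group_a = pairs[1, j], group_b = pairs[2, j],
        method = cp$method, p = cp$p, stringsAsFactors = FALSE
      )
    }))
  }))
  rownames(tests) <- NULL
  list(proportions = props, tests = tests)
}
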