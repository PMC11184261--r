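test_that("signal propagation follows the activation/inhibition product rule", {
  g <- chain_graph()
  v1 <- c(R = 1, I = 1, E = 1)
  expect_equal(propagate(g, v1), c(R = 1, I = 1, E = 1))
  v2 <- c(R = 0.1, I = 1, E = 1)
  expect_equal(unname(propagate(g, v2)["E"]), 0.1, tolerance = 1e-12)

  # one saturated activator and one saturated inhibitor cancel the node
  g2 <- pathway_graph(
    name = "ai",
    nodes = data.frame(
      id = c("A", "B", "X"),
      role = c("receptor", "receptor", "effector")
    ),
    edges = data.frame(from = c("A", "B"), to = "X", sign = c(1, -1)),
    node_genes = list()
  )
  s <- propagate(g2, c(A = 1, B = 1, X = 1))
  expect_equal(unname(s["X"]), 0)
})

test_that("signals stay in [0, 1] on random signed DAGs", {
  for (seed in 1:25) {
    fx <- random_dag(seed)
    s <- propagate(fx$graph, fx$v)
    expect_true(all(s >= -1e-12 & s <= 1 + 1e-12))
  }
})

test_that("on activation-only DAGs decreasing any node value never increases signals", {
  g <- chain_graph()
  set.seed(51)
  for (i in 1:10) {
    v <- c(R = runif(1), I = runif(1), E = runif(1))
    s <- propagate(g, v)
    node <- sample(names(v), 1)
    v2 <- v
    v2[node] <- v2[node] * runif(1)
    s2 <- propagate(g, v2)
    expect_true(all(s2 <= s + 1e-12))
  }
})

test_that("cyclic graphs converge by damped iteration; invalid values are rejected", {
  g <- pathway_graph(
    name = "loop",
    nodes = data.frame(
      id = c("R", "A", "B", "E"),
      role = c("receptor", "intermediate", "intermediate", "effector")
    ),
    edges = data.frame(
      from = c("R", "A", "B", "B"),
      to = c("A", "B", "A", "E"),
      sign = c(1, 1, 1, 1)
    ),
    node_genes = list()
  )
  s <- propagate(g, c(R = 0.8, A = 0.9, B = 0.9, E = 0.7))
  expect_true(all(s >= 0 & s <= 1))
  expect_error(propagate(g, c(R = 1.2, A = 1, B = 1, E = 1)), "\\[0, 1\\]")
})

test_that("inhibition scoring: chain response, no-op factor, disconnected target", {
  g <- chain_graph()
  v <- c(R = 1, I = 1, E = 1)
  hit <- simulate_inhibition(g, v, "R", factor = 0.1)
  expect_equal(hit$score, 0.9, tolerance = 1e-12)
  expect_equal(simulate_inhibition(g, v, "R", factor = 1)$score, 0)
  # drug-target name resolves through the annotation
  expect_equal(simulate_inhibition(g, v, "drugX", factor = 0.1)$score, 0.9)

  g3 <- pathway_graph(
    name = "side",
    nodes = data.frame(
      id = c("R", "E", "X"),
      role = c("receptor", "effector", "receptor")
    ),
    edges = data.frame(from = "R", to = "E", sign = 1),
    node_genes = list()
  )
  off <- simulate_inhibition(g3, c(R = 1, E = 1, X = 1), "X", factor = 0.1)
  expect_equal(off$score, 0) # X reaches no effector
  expect_error(simulate_inhibition(g, v, "R", factor = 0), "factor")
})

test_that("responder classification thresholds at the cohort mean, ties inclusive", {
  expect_equal(
    unname(classify_responders(c(a = 0.9, b = 0.3, c = 0.0))),
    c(TRUE, FALSE, FALSE)
  )
  expect_true(all(classify_responders(c(1, 1, 1)))) # all equal: all responders
  expect_equal(unname(classify_responders(c(0, 1))), c(FALSE, TRUE))
  # at least one responder always exists (max >= mean)
  set.seed(52)
  for (i in 1:10) {
    expect_true(any(classify_responders(runif(sample(2:20, 1)))))
  }
  expect_error(classify_responders(0.5), "at least 2")
})

test_that("normalization to the HC reference anchors and clamps correctly", {
  set.seed(53)
  hc <- matrix(runif(500 * 2, 0, 10), 2, 500)
  dimnames(hc) <- list(c("g1", "g2"), sprintf("h%03d", 1:500))
  x <- cbind(hc, p1 = c(5, 50), p2 = c(-5, quantile(hc[2, ], 0.01, names = FALSE)))
  em <- expression_matrix(x, "logcpm")
  sc <- normalize_to_reference(em, sprintf("h%03d", 1:500))
  expect_identical(sc$units, "unit_scaled")
  expect_equal(sc$values["g1", "p1"], 0.5, tolerance = 0.02) # mid-range
  expect_equal(sc$values["g2", "p1"], 1) # above 99th percentile: clamped
  expect_equal(sc$values["g1", "p2"], 0) # below 1st percentile
  expect_equal(sc$values["g2", "p2"], 0, tolerance = 1e-8) # at the anchor

  # zero-range genes map to 0.5 with a warning
  x2 <- rbind(x, flat = 3)
  expect_warning(
    sc2 <- normalize_to_reference(expression_matrix(x2, "logcpm"), sprintf("h%03d", 1:500)),
    "zero HC range"
  )
  expect_true(all(sc2$values["flat", ] == 0.5))
})

test_that("node values average member genes and default to 0.5 when unmeasured", {
  em <- expression_matrix(
    matrix(c(0.2, 0.8, 0.4), 3, 1, dimnames = list(c("gA", "gB", "gC"), "p1")),
    "unit_scaled"
  )
  g <- pathway_graph(
    name = "nv",
    nodes = data.frame(id = c("R", "E"), role = c("receptor", "effector")),
    edges = data.frame(from = "R", to = "E", sign = 1),
    node_genes = list(R = c("gA", "gB"), E = "missing_gene")
  )
  expect_warning(v <- node_values(g, em, "p1"), "without measured genes")
  expect_equal(unname(v["R"]), 0.5) # mean of 0.2 and 0.8
  expect_equal(unname(v["E"]), 0.5) # unmeasured default
  em2 <- expression_matrix(
    matrix(0.4, 1, 1, dimnames = list("gC", "p1")), "unit_scaled"
  )
  g2 <- pathway_graph(
    name = "nv2",
    nodes = data.frame(id = c("R", "E"), role = c("receptor", "effector")),
    edges = data.frame(from = "R", to = "E", sign = 1),
    node_genes = list(R = "gC", E = "gC")
  )
  expect_equal(unname(node_values(g2, em2, "p1")["R"]), 0.4) # single-gene node
})

test_that("graph validation enforces roles, signs and reachability", {
  nodes <- data.frame(id = c("R", "E"), role = c("receptor", "effector"))
  expect_error(
    pathway_graph("bad", nodes, data.frame(from = "R", to = "E", sign = 2)),
    "sign"
  )
  expect_error(
    pathway_graph(
      "orphan",
      data.frame(id = c("R", "E", "F"), role = c("receptor", "effector", "effector")),
      data.frame(from = "R", to = "E", sign = 1)
    ),
    "unreachable"
  )
  expect_error(
    pathway_graph("norec", data.frame(id = "E", role = "effector"),
      edges = data.frame(from = character(), to = character(), sign = numeric())
    ),
    "no receptor"
  )
})

test_that("proportion comparison switches between Fisher and Yates chi-square", {
  fisher_case <- compare_proportions(matrix(c(14, 5, 1, 8), 2, byrow = TRUE))
  expect_identical(fisher_case$method, "fisher")
  chisq_case <- compare_proportions(matrix(c(14, 5, 5, 8), 2, byrow = TRUE))
  expect_identical(chisq_case$method, "chisq_yates")
  expect_error(compare_proportions(matrix(c(0, 0, 3, 4), 2)), "zero margin")
  expect_error(compare_proportions(matrix(c(1.5, 2, 3, 4), 2)), "integers")
})

test_that("subgroup response report aggregates proportions and pairwise tests", {
  results <- data.frame(
    patient_id = sprintf("p%02d", 1:12),
    target = "drugA",
    score = c(rep(1, 6), rep(0, 6)),
    responder = c(rep(TRUE, 6), rep(FALSE, 6))
  )
  sub <- setNames(rep(c("hi", "lo"), each = 6), results$patient_id)
  rep1 <- subgroup_response_report(results, sub)
  expect_equal(
    rep1$proportions$proportion[rep1$proportions$subgroup == "hi"], 1
  )
  expect_equal(nrow(rep1$tests), 1)
  expect_identical(rep1$tests$method, "fisher")

  # single subgroup: tests skipped with a note
  rep2 <- subgroup_response_report(results, setNames(rep("hi", 12), results$patient_id))
  expect_null(rep2$tests)
  expect_match(rep2$note, "skipped")
})
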