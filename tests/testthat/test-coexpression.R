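test_that("topological overlap of a complete graph is 1 everywhere", {
  a <- matrix(1, 8, 8)
  tom <- tom_similarity(a)
  expect_equal(tom, matrix(1, 8, 8), tolerance = 1e-12)
})

test_that("TOM is symmetric with entries in [0, 1] and unit diagonal", {
  set.seed(21)
  for (i in 1:5) {
    r <- matrix(runif(100), 10, 10)
    a <- (r + t(r)) / 2
    diag(a) <- 1
    tom <- tom_similarity(a)
    expect_equal(tom, t(tom), tolerance = 1e-12)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    expect_equal(unname(diag(tom)), rep(1, 10))
  }
})

test_that("an analytic power-law degree sequence yields a near-perfect scale-free fit", {
  # frequency proportional to k^-2 across octaves
  k <- rep(c(1, 2, 4, 8, 16, 32), times = c(4096, 1024, 256, 64, 16, 4))
  fit <- scale_free_fit(k, nbreaks = 12)
  expect_gt(fit$r2, 0.95)
  expect_lt(fit$slope, 0)
})

test_that("soft-threshold selection handles degenerate and trivial inputs", {
  # single candidate returned unchanged
  em <- block_fixture(n_per_block = 10, n_samples = 15, seed = 3)
  expect_identical(pick_soft_threshold(em, candidate_betas = 7L), 7L)
  # all genes mutually correlated: degenerate connectivity, fall back with warning
  base <- rnorm(20)
  x <- t(vapply(1:12, function(i) base * 1, numeric(20))) + 1e-9 * matrix(rnorm(240), 12)
  dimnames(x) <- list(sprintf("g%02d", 1:12), sprintf("s%02d", 1:20))
  em2 <- expression_matrix(x, "logcpm")
  expect_warning(b <- pick_soft_threshold(em2, candidate_betas = c(2L, 4L, 6L)), "degenerate")
  expect_identical(b, 6L)
  # constant genes are rejected
  x[1, ] <- 5
  em3 <- expression_matrix(x, "logcpm")
  expect_error(pick_soft_threshold(em3, candidate_betas = c(2L, 4L)), "constant")
})

test_that("two planted correlation blocks are recovered as exactly two modules", {
  em <- block_fixture(n_per_block = 60, n_samples = 40, rho = 0.9, seed = 1)
  mods <- detect_modules(em, network_params(), cohort = "discovery")
  expect_length(mods, 2)
  blocks <- list(
    A = grep("^A", gene_ids(em), value = TRUE),
    B = grep("^B", gene_ids(em), value = TRUE)
  )
  for (m in mods) {
    best <- max(vapply(blocks, jaccard, numeric(1), b = m$genes))
    expect_gte(best, 0.95)
  }
  # modules partition assigned genes: no gene in two modules
  expect_equal(anyDuplicated(unlist(lapply(mods, `[[`, "genes"))), 0L)
})

test_that("independent genes yield no large modules in most seeds", {
  hits <- 0
  for (seed in 1:5) {
    set.seed(seed)
    x <- matrix(rnorm(300 * 30), 300, 30)
    dimnames(x) <- list(sprintf("g%03d", 1:300), sprintf("s%02d", 1:30))
    mods <- detect_modules(expression_matrix(x, "logcpm"), network_params())
    if (length(mods) == 0) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("module eigengene is oriented with mean expression", {
  em <- block_fixture(n_per_block = 30, n_samples = 25, seed = 5)
  genes <- grep("^A", gene_ids(em), value = TRUE)
  eig <- module_eigengene(em, genes)
  xs <- t(scale(t(em$values[genes, ])))
  expect_gt(cor(eig, colMeans(xs)), 0.9)
})

test_that("module replication requires both Jaccard and overlap significance", {
  mk <- function(name, genes, cohort) {
    structure(
      list(
        name = name, genes = genes, cohort = cohort,
        eigen_profile = NULL, annotation = NA, replicated = NA
      ),
      class = "CoexpressionModule"
    )
  }
  universe <- sprintf("u%04d", 1:2000)
  d1 <- mk("d1", universe[1:50], "discovery")
  r_same <- mk("r1", universe[1:50], "replication")
  r_part <- mk("r2", c(universe[1:30], universe[100:119]), "replication")
  r_disj <- mk("r3", universe[500:549], "replication")

  same <- replicate_modules(list(d1), list(r_same), universe)
  expect_true(same[[1]]$replicated)
  expect_equal(same[[1]]$jaccard, 1)

  none <- replicate_modules(list(d1), list(r_disj), universe)
  expect_false(none[[1]]$replicated)

  # 30/50 overlap in a 2000-gene universe: enormous significance
  part <- replicate_modules(list(d1), list(r_part), universe)
  expect_true(part[[1]]$replicated)
  expect_lt(part[[1]]$overlap_fdr, 1e-20)
  # Jaccard symmetry
  expect_equal(
    jaccard(d1$genes, r_part$genes),
    jaccard(r_part$genes, d1$genes)
  )
})

test_that("module annotation uses the dual correlation and overlap gate", {
  em <- block_fixture(n_per_block = 40, n_samples = 30, seed = 6)
  blockA <- grep("^A", gene_ids(em), value = TRUE)
  blockB <- grep("^B", gene_ids(em), value = TRUE)
  mods <- detect_modules(em, network_params(), "discovery")
  modA <- mods[[which.max(vapply(mods, function(m) jaccard(m$genes, blockA), numeric(1)))]]

  # reference identical to the module: annotated with |r| ~ 1
  ann <- annotate_modules(list(modA), list(REF_A = blockA), em)
  expect_identical(ann[[1]]$annotation, "REF_A")
  expect_gt(abs(ann[[1]]$annotation_r), 0.95)

  # disjoint, uncorrelated reference: unannotated
  ann2 <- annotate_modules(list(modA), list(REF_B = blockB), em)
  expect_identical(ann2[[1]]$annotation, "unannotated")
})
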