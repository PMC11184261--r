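test_that("log-CPM matches the stated pseudo-count formula", {
  # one sample with library size 1e6 - 1: log2((c + .5)/(L + 1) * 1e6)
  lib_target <- 1e6 - 1
  em <- toy_counts(matrix(c(0, 1023.5, lib_target - 1023.5), 3, 1))
  lc <- log_cpm(em)
  expect_identical(lc$units, "logcpm")
  expect_equal(lc$values[1, 1], -1.0, tolerance = 1e-12) # zero count -> log2(0.5)
  expect_equal(lc$values[2, 1], 10.0, tolerance = 1e-12) # log2(1024)
})

test_that("log-CPM is scale invariant up to the pseudo-count term", {
  set.seed(1)
  em <- toy_counts(matrix(rpois(40, 2000), 10, 4))
  doubled <- expression_matrix(em$values * 2, "counts")
  a <- log_cpm(em)$values
  b <- log_cpm(doubled)$values
  expect_lt(max(abs(a - b)), 0.002) # pseudo-count effect only
  # with pseudo-counts removed the invariance is exact
  a0 <- log_cpm(em, prior_count = 0, lib_offset = 0)$values
  b0 <- log_cpm(doubled, prior_count = 0, lib_offset = 0)$values
  expect_equal(a0, b0, tolerance = 1e-12)
})

test_that("log-CPM rejects all-zero samples by name", {
  em <- toy_counts(matrix(c(5, 3, 0, 0), 2, 2), samples = c("ok", "empty"))
  expect_error(log_cpm(em), "empty")
})

test_that("low-count filter keeps genes by CPM threshold and fraction", {
  # library ~1e6 so CPM ~ count; gene3 exceeds CPM 1 in only 1/20 samples
  n <- 20
  base <- matrix(rep(1e6 / 3, 3 * n), 3, n)
  g_zero <- rep(0, n)
  g_high <- rep(2, n) # CPM ~2 everywhere
  g_rare <- c(50, rep(0, n - 1)) # above threshold in 5% of samples
  em <- toy_counts(rbind(base, g_zero, g_high, g_rare))
  kept <- filter_low_counts(em, min_cpm = 1, min_fraction = 0.1)
  expect_true("g05" %in% gene_ids(kept)) # the CPM~2 gene
  expect_false("g04" %in% gene_ids(kept)) # all-zero gene removed
  expect_false("g06" %in% gene_ids(kept)) # 5% < 10% qualifying samples
})

test_that("duplicate symbols collapse to per-sample means at first position", {
  em <- toy_counts(
    matrix(c(
      2, 8,
      1, 1,
      4, 10,
      6, 4
    ), 4, 2, byrow = TRUE),
    genes = c("GENE1", "OTHER", "GENE1", "GENE1")
  )
  out <- collapse_duplicate_symbols(em)
  expect_identical(gene_ids(out), c("GENE1", "OTHER"))
  expect_equal(out$values["GENE1", ], c(s01 = 4, s02 = (8 + 10 + 4) / 3))
  # duplicate-free input is untouched
  clean <- toy_counts(matrix(1:6, 3, 2))
  expect_identical(collapse_duplicate_symbols(clean)$values, clean$values)
})

test_that("collapse-then-logCPM equals logCPM on duplicate-free input", {
  set.seed(2)
  em <- toy_counts(matrix(rpois(30, 100), 6, 5))
  expect_equal(log_cpm(collapse_duplicate_symbols(em))$values, log_cpm(em)$values)
})

test_that("greedy matching picks nearest-age same-sex controls without replacement", {
  cases <- data.frame(sample_id = "c1", sex = "F", age = 40)
  pool <- data.frame(
    sample_id = paste0("p", 1:6),
    sex = c("F", "F", "F", "F", "F", "M"),
    age = c(39, 41, 60, 61, 62, 40)
  )
  expect_setequal(match_controls(cases, pool, ratio = 5), paste0("p", 1:5))

  # two cases: the first (input order) takes the closest ages
  cases2 <- data.frame(sample_id = c("c1", "c2"), sex = "F", age = c(40, 40))
  sel <- match_controls(cases2, pool[1:5, ], ratio = 2)
  expect_identical(sel[1:2], c("p1", "p2"))
  expect_false(anyDuplicated(sel) > 0)

  # insufficient same-sex pool errors with the case name
  cases3 <- data.frame(sample_id = "cM", sex = "M", age = 50)
  expect_error(match_controls(cases3, pool, ratio = 2), "cM")
})

test_that("matching output size is always ratio x cases with unique ids", {
  set.seed(7)
  for (i in 1:5) {
    n_cases <- sample(3:10, 1)
    pool <- data.frame(
      sample_id = paste0("p", 1:80),
      sex = sample(c("F", "M"), 80, replace = TRUE, prob = c(.8, .2)),
      age = sample(20:70, 80, replace = TRUE)
    )
    cases <- data.frame(
      sample_id = paste0("c", 1:n_cases),
      sex = "F", age = sample(25:60, n_cases, replace = TRUE)
    )
    sel <- match_controls(cases, pool, ratio = 4)
    expect_length(sel, 4 * n_cases)
    expect_false(anyDuplicated(sel) > 0)
  }
})

test_that("covariate residualization removes covariate axes only", {
  set.seed(11)
  n <- 40
  meta <- data.frame(
    sample_id = sprintf("s%02d", 1:n), group = "HC", cohort = "none",
    age = rnorm(n, 45, 12), sex = sample(c("F", "M"), n, TRUE),
    batch = sample(c("B1", "B2"), n, TRUE), rin = rnorm(n, 8, .5)
  )
  signal <- rnorm(n)
  x <- rbind(
    2 * meta$age + rnorm(n, 0, .1), # pure covariate gene
    signal + rnorm(n, 0, .1) # covariate-free gene
  )
  dimnames(x) <- list(c("covgene", "siggene"), meta$sample_id)
  adj <- adjust_covariates(expression_matrix(x, "logcpm"), meta)
  expect_lt(sd(adj$values["covgene", ]), 0.2)
  expect_gt(cor(adj$values["siggene", ], signal), 0.9)
})
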