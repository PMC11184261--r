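test_that("cohort specification validates counts and subgroup arithmetic", {
  spec <- cohort_spec()
  expect_equal(spec$n_hc, 497)
  expect_equal(spec$n_ln_discovery + spec$n_ln_replication, 41)
  expect_equal(unname(spec$subgroup_sizes[c("lo", "im", "hi")]), c(13, 9, 19))
  expect_error(cohort_spec(subgroup_sizes = c(lo = 10, im = 10, hi = 10)), "sum")
  expect_error(cohort_spec(n_hc = 0), "at least 1")
  expect_error(
    planted_module_effect("x", "g1", c(lo = 6, im = 0, hi = 0)),
    "delta_z"
  )
})

test_that("generation is deterministic and rejects invalid planted effects", {
  spec <- cohort_spec(
    n_hc = 40, n_ln_discovery = 8, n_ln_replication = 6, n_nonrenal = 5,
    subgroup_sizes = c(lo = 5, im = 4, hi = 5), n_genes = 400, seed = 99
  )
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$counts$values, b$counts$values)
  expect_identical(a$meta, b$meta)

  overlapping <- default_module_effects()
  overlapping$BCELL$genes[1] <- overlapping$IFN$genes[1]
  expect_error(generate_cohort(spec, overlapping), "disjoint")
})

test_that("null planted effects produce near-zero module dysregulation", {
  null_effects <- default_module_effects()
  for (nm in names(null_effects)) {
    null_effects[[nm]]$delta_z[] <- 0
  }
  d <- generate_cohort(cohort_spec(seed = 2), null_effects)
  prep <- log_cpm(filter_low_counts(d$counts))
  meta <- d$meta
  hc <- meta$sample_id[meta$group == "HC"]
  ln <- meta$sample_id[meta$group == "LN"]
  for (nm in names(null_effects)) {
    z <- module_z(prep, hc, ln, null_effects[[nm]]$genes)
    expect_lt(abs(mean(z)), 0.15)
  }
})

test_that("a planted hi-subgroup shift is realized within tolerance of the target", {
  effects <- default_module_effects()
  effects$IFN$delta_z <- c(lo = 0.5, im = 1.5, hi = 2.5)
  d <- generate_cohort(cohort_spec(seed = 3), effects)
  prep <- log_cpm(filter_low_counts(d$counts))
  meta <- d$meta
  hc <- meta$sample_id[meta$group == "HC"]
  hi <- meta$sample_id[meta$group == "LN" & !is.na(meta$subgroup) & meta$subgroup == "hi"]
  z <- module_z(prep, hc, hi, effects$IFN$genes)
  expect_lt(abs(mean(z) - 2.5), 0.3)
})

test_that("generated pathways wire the target receptor to module effectors", {
  effects <- default_module_effects()
  universe <- unlist(lapply(effects, `[[`, "genes"))
  graphs <- generate_pathways(default_drug_targets(), effects, universe)
  expect_length(graphs, 3)
  g <- graphs[["path_IFN.001"]]
  expect_equal(sum(g$nodes$role == "receptor"), 1)
  expect_identical(g$node_genes[["R1"]], "IFN.001")
  eff_genes <- unlist(g$node_genes[g$nodes$id[g$nodes$role == "effector"]])
  expect_true(all(eff_genes %in% effects$IFN$genes))
  expect_true(nrow(g$nodes) >= 5 && nrow(g$nodes) <= 30)

  # a 3-node chain variant has one receptor and one effector
  chain <- generate_pathways(default_drug_targets()[1, ], effects, universe,
    n_intermediate = 1, n_effector = 1
  )[[1]]
  expect_equal(nrow(chain$nodes), 3)
  expect_equal(sum(chain$nodes$role == "effector"), 1)

  expect_error(
    generate_pathways(
      data.frame(target_gene = "ABSENT", module = "IFN"),
      effects, universe
    ),
    "absent"
  )
  expect_error(
    generate_pathways(default_drug_targets(), effects, universe, cyclic = TRUE),
    "damping"
  )
})

test_that("serology generation tracks module scores by its loadings", {
  set.seed(61)
  z <- matrix(rnorm(2 * 41), 2, 41, dimnames = list(
    c("IFN", "PLASMA"), sprintf("p%02d", 1:41)
  ))
  scores <- structure(list(z = z, subgroup = NULL), class = "ModuleScoreMatrix")

  tight <- serology_spec(
    data.frame(
      analyte = "a1", module = "IFN", slope = 1,
      type = "continuous", positivity_rate = NA
    ),
    noise_sd = 1e-6
  )
  sero <- generate_serology(scores, tight, seed = 1)
  expect_gt(cor(sero$value, z["IFN", sero$sample_id], method = "spearman"), 0.999)

  null_spec <- serology_spec(
    data.frame(
      analyte = "a0", module = "IFN", slope = 0,
      type = "continuous", positivity_rate = NA
    ),
    noise_sd = 1
  )
  sero0 <- generate_serology(scores, null_spec, seed = 2)
  expect_lt(abs(cor(sero0$value, z["IFN", sero0$sample_id], method = "spearman")), 0.3)

  # binary positivity respects the requested rate exactly at n = 40
  z40 <- z[, 1:40]
  scores40 <- structure(list(z = z40, subgroup = NULL), class = "ModuleScoreMatrix")
  bin <- serology_spec(
    data.frame(
      analyte = "ab", module = "PLASMA", slope = 1,
      type = "binary", positivity_rate = 0.5
    ),
    noise_sd = 0.5
  )
  serob <- generate_serology(scores40, bin, seed = 3)
  expect_equal(sum(serob$positive), 20)

  bad <- serology_spec(
    data.frame(
      analyte = "x", module = "NOPE", slope = 1,
      type = "continuous", positivity_rate = NA
    )
  )
  expect_error(generate_serology(scores, bad, seed = 1), "unknown modules")
})
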