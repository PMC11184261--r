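# Fully synthetic study generator. Emulates the design the downstream
# analysis assumes: a large healthy-control reference, 41 active-LN patients
# split into a discovery (26) and a replication (15) set, 62 active nonrenal
# SLE patients, three planted LN subgroups with differential IFN / B-cell /
# plasma-cell module shifts, cytokines tied to module activity, and toy
# signaling pathways containing the drug targets.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Cohort design specification
#'
#' Defaults mirror the study design: 497 healthy controls, 41 active-LN
#' patients (26 discovery + 15 replication), 62 active nonrenal SLE, and
#' planted LN subgroup sizes lo/im/hi = 13/9/19 (the unique integers
#' consistent with the reported subgroup response percentages and n = 41).
#'
#' @param n_hc,n_ln_discovery,n_ln_replication,n_nonrenal Sample counts.
#' @param subgroup_sizes Named integer vector `c(lo=, im=, hi=)`; must sum to
#'   `n_ln_discovery + n_ln_replication`.
#' @param n_genes Number of genes in the universe (default 2000).
#' @param seed RNG seed.
#' @return A list of class `CohortSpec`.
#' @export
cohort_spec <- function(n_hc = 497, n_ln_discovery = 26, n_ln_replication = 15,
                        n_nonrenal = 62,
                        subgroup_sizes = c(lo = 13, im = 9, hi = 19),
                        n_genes = 2000, seed = 1) {
  counts <- c(n_hc, n_ln_discovery, n_ln_replication, n_nonrenal, subgroup_sizes, n_genes)
  if (any(counts < 1)) stop("all counts must be at least 1")
  if (!identical(sort(names(subgroup_sizes)), c("hi", "im", "lo"))) {
    stop("subgroup_sizes must be named lo, im, hi")
  }
  if (sum(subgroup_sizes) != n_ln_discovery + n_ln_replication) {
    stop("subgroup sizes must sum to the number of LN patients")
  }
  structure(
    list(
      n_hc = n_hc, n_ln_discovery = n_ln_discovery,
      n_ln_replication = n_ln_replication, n_nonrenal = n_nonrenal,
      subgroup_sizes = subgroup_sizes, n_genes = as.integer(n_genes),
      seed = as.integer(seed)
    ),
    class = "CohortSpec"
  )
}

#' A planted module effect
#'
#' @param module_name Module label.
#' @param genes Gene ids (disjoint across planted modules).
#' @param delta_z Named numeric `c(lo=, im=, hi=)`: target subgroup-mean
#'   z-shift in HC-sd units (|delta| <= 5).
#' @param within_module_cor Residual within-module correlation in (0, 1)
#'   beyond the subgroup structure itself.
#' @return A list of class `PlantedModuleEffect`.
#' @export
planted_module_effect <- function(module_name, genes, delta_z, within_module_cor = 0.05) {
  if (any(abs(delta_z) > 5)) stop("|delta_z| must be at most 5")
  if (!all(c("lo", "im", "hi") %in% names(delta_z))) {
    stop("delta_z must be named lo, im, hi")
  }
  if (within_module_cor <= 0 || within_module_cor >= 1) {
    stop("within_module_cor must be in (0, 1)")
  }
  structure(
    list(
      module_name = module_name, genes = genes,
      delta_z = delta_z[c("lo", "im", "hi")],
      within_module_cor = within_module_cor
    ),
    class = "PlantedModuleEffect"
  )
}

#' Default planted module effects
#'
#' Three 60-gene blood-transcriptional modules with the qualitative subgroup
#' pattern of the study: IFN upregulated in all subgroups with increasing
#' magnitude lo < im < hi; B cell down in lo and hi, up in im; plasma cell
#' down in lo, up in im and hi.
#'
#' @param module_size Genes per module (default 60).
#' @return Named list of `PlantedModuleEffect`s.
#' @export
default_module_effects <- function(module_size = 60) {
  mk <- function(prefix) sprintf("%s.%03d", prefix, seq_len(module_size))
  list(
    IFN = planted_module_effect("IFN", mk("IFN"), c(lo = 0.5, im = 2, hi = 4)),
    BCELL = planted_module_effect("BCELL", mk("BCELL"), c(lo = -2, im = 2, hi = -2)),
    PLASMA = planted_module_effect("PLASMA", mk("PLASMA"), c(lo = -2, im = 2, hi = 1))
  )
}

split_counts <- function(sizes, total_a) {
  # largest-remainder split of subgroup sizes into cohort A totalling total_a
  raw <- sizes * total_a / sum(sizes)
  base <- floor(raw)
  rem <- total_a - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Generate a synthetic cohort with planted module effects
#'
#' Negative-binomial counts with log-normal library sizes and gene-wise
#' dispersions, small covariate effects (age, sex, batch, RIN) on a random
#' 10% of genes, a weak shared latent factor per planted module, and
#' subgroup-specific mean shifts on planted module genes calibrated so the
#' realized per-gene z-score versus the generated healthy controls
#' approximates `delta_z` (the calibration pass measures the realized HC
#' log-CPM standard deviation per gene).
#'
#' @param spec A `CohortSpec`.
#' @param effects List of `PlantedModuleEffect`s (gene sets must be disjoint
#'   and fit inside the gene universe).
#' @param nonrenal_delta Named numeric: z-shift applied to every nonrenal SLE
#'   patient per module (default IFN +2, B cell +0.5, plasma +0.5).
#' @return List with `counts` (`ExpressionMatrix`), `meta` (metadata data
#'   frame carrying a hidden-truth `subgroup` column for LN patients), and
#'   `effects`.
#' @export
generate_cohort <- function(spec, effects = default_module_effects(),
                            nonrenal_delta = c(IFN = 2, BCELL = 0.5, PLASMA = 0.5)) {
  stopifnot(inherits(spec, "CohortSpec"))
  planted <- unlist(lapply(effects, `[[`, "genes"), use.names = FALSE)
  if (anyDuplicated(planted)) stop("planted module gene sets must be disjoint")
  if (length(planted) >= spec$n_genes) stop("n_genes too small for the planted modules")
  genes <- c(planted, sprintf("G%04d", seq_len(spec$n_genes - length(planted))))

  with_seed(spec$seed, {
    n_ln <- spec$n_ln_discovery + spec$n_ln_replication
    # subgroup labels interleaved across discovery/replication so both
    # cohorts contain all three subgroups
    disc_sizes <- split_counts(spec$subgroup_sizes, spec$n_ln_discovery)
    subgroup <- character(0)
    cohort_ln <- character(0)
    for (g in names(spec$subgroup_sizes)) {
      subgroup <- c(subgroup, rep(g, spec$subgroup_sizes[[g]]))
      cohort_ln <- c(
        cohort_ln,
        rep("discovery", disc_sizes[[g]]),
        rep("replication", spec$subgroup_sizes[[g]] - disc_sizes[[g]])
      )
    }
    meta <- data.frame(
      sample_id = c(
        sprintf("HC%03d", seq_len(spec$n_hc)),
        sprintf("LN%03d", seq_len(n_ln)),
        sprintf("SLE%03d", seq_len(spec$n_nonrenal))
      ),
      group = c(
        rep("HC", spec$n_hc), rep("LN", n_ln),
        rep("SLE_nonrenal", spec$n_nonrenal)
      ),
      cohort = c(rep("none", spec$n_hc), cohort_ln, rep("none", spec$n_nonrenal)),
      stringsAsFactors = FALSE
    )
    n <- nrow(meta)
    meta$age <- pmin(pmax(round(stats::rnorm(n, 44, 13)), 18), 80)
    meta$sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.88, 0.12))
    meta$batch <- sample(paste0("B", 1:4), n, replace = TRUE)
    meta$rin <- pmin(pmax(round(stats::rnorm(n, 8, 0.7), 1), 5), 10)
    meta$subgroup <- NA_character_
    meta$subgroup[meta$group == "LN"] <- subgroup

    # gene-level baseline (log2 CPM scale) and dispersion
    n_genes <- length(genes)
    eta <- stats::rnorm(n_genes, 3.5, 1.8)
    # planted genes moderately expressed with a narrow spread: comfortably
    # above the low-count filter without dominating library composition
    eta[seq_along(planted)] <- stats::rnorm(length(planted), 3.5, 1)
    prop <- 2^eta / sum(2^eta)
    disp <- exp(stats::rnorm(n_genes, log(0.1), 0.5))
    lib <- exp(stats::rnorm(n, log(8e6), 0.25))

    # covariate effects on log2 mean for a random 10% of genes each
    cov_shift <- matrix(0, n_genes, n)
    pick <- function() sample.int(n_genes, round(0.1 * n_genes))
    idx <- pick()
    cov_shift[idx, ] <- cov_shift[idx, ] +
      outer(stats::rnorm(length(idx), 0, 0.01), meta$age - 44)
    idx <- pick()
    cov_shift[idx, ] <- cov_shift[idx, ] +
      outer(stats::rnorm(length(idx), 0, 0.3), as.numeric(meta$sex == "M"))
    idx <- pick()
    bshift <- matrix(stats::rnorm(length(idx) * 4, 0, 0.25), length(idx), 4)
    cov_shift[idx, ] <- cov_shift[idx, ] + bshift[, match(meta$batch, paste0("B", 1:4))]
    idx <- pick()
    cov_shift[idx, ] <- cov_shift[idx, ] +
      outer(stats::rnorm(length(idx), 0, 0.15), meta$rin - 8)

    # weak shared latent factor per planted module (residual co-regulation)
    mu_typical <- prop * stats::median(lib)
    var_base <- (1 / mu_typical + disp) / log(2)^2 # delta-method log2 variance
    factor_shift <- matrix(0, n_genes, n)
    for (ef in effects) {
      gi <- match(ef$genes, genes)
      lambda <- sqrt(ef$within_module_cor / (1 - ef$within_module_cor) * var_base[gi])
      f <- stats::rnorm(n)
      factor_shift[gi, ] <- factor_shift[gi, ] + outer(lambda, f)
    }

    planted_idx <- seq_along(planted)
    draw_counts <- function(cols, extra_shift) {
      shift <- cov_shift[, cols, drop = FALSE] + factor_shift[, cols, drop = FALSE] + extra_shift
      w <- prop * 2^shift
      # compositional calibration: scale the planted genes per sample so
      # their realized CPM equals the target exactly; the (small, realistic)
      # compositional displacement lands on the background genes only
      pls <- colSums(w[planted_idx, , drop = FALSE])
      bgs <- colSums(w) - pls
      x <- bgs / pmax(1 - pls, 0.1)
      w[planted_idx, ] <- sweep(w[planted_idx, , drop = FALSE], 2, x, "*")
      w <- sweep(w, 2, colSums(w), "/")
      mu <- w * rep(lib[cols], each = n_genes)
      m <- matrix(
        stats::rnbinom(n_genes * length(cols), mu = mu, size = rep(1 / disp, length(cols))),
        n_genes, length(cols)
      )
      dimnames(m) <- list(genes, meta$sample_id[cols])
      m
    }

    # pass 1: healthy controls, then measure realized HC log-CPM sd per gene
    hc_cols <- which(meta$group == "HC")
    hc_counts <- draw_counts(hc_cols, 0)
    hc_em <- log_cpm(expression_matrix(hc_counts, "counts"))
    sd_hc <- apply(hc_em$values, 1, stats::sd)
    sd_hc[sd_hc == 0] <- stats::median(sd_hc[sd_hc > 0])

    # pass 2: patients, planted genes shifted by delta_z (in HC-sd units)
    patient_cols <- which(meta$group != "HC")
    pat_shift <- matrix(0, n_genes, length(patient_cols))
    for (ef in effects) {
      gi <- match(ef$genes, genes)
      dz <- numeric(length(patient_cols))
      for (j in seq_along(patient_cols)) {
        mrow <- meta[patient_cols[j], ]
        dz[j] <- if (mrow$group == "LN") {
          ef$delta_z[[mrow$subgroup]]
        } else if (ef$module_name %in% names(nonrenal_delta)) {
          nonrenal_delta[[ef$module_name]]
        } else {
          0
        }
      }
      pat_shift[gi, ] <- outer(sd_hc[gi], dz)
    }
    pat_counts <- draw_counts(patient_cols, pat_shift)

    counts <- cbind(hc_counts, pat_counts)[, meta$sample_id]
    list(
      counts = expression_matrix(counts, "counts"),
      meta = validate_metadata(meta),
      effects = effects
    )
  })
}

#' Generate toy signaling pathways for drug targets
#'
#' Per target, a signed DAG receptor -> intermediates -> effectors whose
#' receptor node maps to the target gene and whose effector genes belong to
#' the stated module. Deterministic construction (no randomness).
#'
#' @param targets Data frame with columns `target_gene` and `module`.
#' @param effects List of `PlantedModuleEffect`s supplying module gene sets.
#' @param universe Expression gene universe; targets absent from it are
#'   rejected.
#' @param n_intermediate,n_effector Layer sizes (defaults 2 and 4; total
#'   node count stays in 5-30).
#' @param genes_per_node Module genes assigned to each intermediate/effector
#'   node (default 5).
#' @param cyclic Add a feedback edge from the last effector to the first
#'   intermediate. Requires `damping`.
#' @param damping Damping factor for cyclic propagation; requesting a cycle
#'   without one is an error.
#' @return Named list of `PathwayGraph`s (one per target).
#' @export
generate_pathways <- function(targets, effects, universe,
                              n_intermediate = 2, n_effector = 4,
                              genes_per_node = 5, cyclic = FALSE, damping = NULL) {
  if (cyclic && is.null(damping)) {
    stop("cyclic pathway requested without a damping configuration")
  }
  if (!all(c("target_gene", "module") %in% names(targets))) {
    stop("targets need columns target_gene, module")
  }
  out <- list()
  for (i in seq_len(nrow(targets))) {
    tg <- targets$target_gene[i]
    mod <- targets$module[i]
    if (!tg %in% universe) stop("target gene '", tg, "' absent from the expression universe")
    if (!mod %in% names(effects)) stop("unknown module '", mod, "' for target ", tg)
    pool <- setdiff(effects[[mod]]$genes, tg)
    need <- (n_intermediate + n_effector) * genes_per_node
    if (length(pool) < need) stop("module '", mod, "' too small for the requested pathway")
    chunks <- split(pool[seq_len(need)], rep(seq_len(n_intermediate + n_effector), each = genes_per_node))
    ids <- c(
      "R1",
      if (n_intermediate > 0) paste0("I", seq_len(n_intermediate)),
      paste0("E", seq_len(n_effector))
    )
    roles <- c(
      "receptor",
      rep("intermediate", n_intermediate),
      rep("effector", n_effector)
    )
    node_genes <- c(list(R1 = tg), stats::setNames(chunks, ids[-1]))
    if (n_intermediate > 0) {
      inter <- paste0("I", seq_len(n_intermediate))
      eff <- paste0("E", seq_len(n_effector))
      owner <- inter[rep_len(seq_len(n_intermediate), n_effector)]
      edges <- rbind(
        data.frame(from = "R1", to = inter, sign = 1, stringsAsFactors = FALSE),
        data.frame(from = owner, to = eff, sign = 1, stringsAsFactors = FALSE)
      )
    } else {
      edges <- data.frame(
        from = "R1", to = paste0("E", seq_len(n_effector)),
        sign = 1, stringsAsFactors = FALSE
      )
    }
    if (cyclic && n_intermediate > 0) {
      edges <- rbind(edges, data.frame(
        from = paste0("E", n_effector),
        to = "I1", sign = 1, stringsAsFactors = FALSE
      ))
    }
    nm <- paste0("path_", tg)
    out[[nm]] <- pathway_graph(
      name = nm,
      nodes = data.frame(id = ids, role = roles, stringsAsFactors = FALSE),
      edges = edges,
      node_genes = node_genes,
      target_annotation = stats::setNames("R1", tg)
    )
  }
  out
}

#' Serology panel specification
#'
#' @param panel Data frame with columns `analyte`, `module`, `slope`,
#'   `type` (`continuous` / `binary`) and `positivity_rate` (binary only).
#' @param noise_sd Gaussian noise standard deviation (> 0).
#' @return List of class `SerologySpec`.
#' @export
serology_spec <- function(panel, noise_sd = 0.5) {
  need <- c("analyte", "module", "slope", "type", "positivity_rate")
  if (!all(need %in% names(panel))) stop("panel needs columns ", paste(need, collapse = ", "))
  if (noise_sd <= 0) stop("noise_sd must be positive")
  structure(list(panel = panel, noise_sd = noise_sd), class = "SerologySpec")
}

#' Default serology panel
#'
#' Continuous cytokines loading on the planted modules (mirroring the
#' qualitative cytokine-module associations of the study) plus binary
#' autoantibody-style analytes, and one null analyte.
#' @return A `SerologySpec`.
#' @export
default_serology_spec <- function() {
  serology_spec(data.frame(
    analyte = c("TNF_alpha", "IP10", "BAFF", "IgG_total", "IL6", "CCL2_null", "anti_dsDNA", "anti_Sm"),
    module = c("IFN", "IFN", "BCELL", "PLASMA", "PLASMA", "IFN", "PLASMA", "BCELL"),
    slope = c(1, 0.8, 0.8, 1, 0.6, 0, 1, 0.5),
    type = c(rep("continuous", 6), "binary", "binary"),
    positivity_rate = c(rep(NA, 6), 0.5, 0.25),
    stringsAsFactors = FALSE
  ))
}

#' Generate a serology table from module scores
#'
#' `value = slope * module_z + N(0, noise_sd)`; binary analytes are called
#' positive above the `1 - positivity_rate` quantile of the realized values.
#'
#' @param scores A `ModuleScoreMatrix`.
#' @param spec A `SerologySpec`; every loading must reference a module
#'   present in the score matrix.
#' @param seed RNG seed.
#' @return Long data frame: `sample_id`, `analyte`, `value`, `positive`
#'   (NA for continuous analytes).
#' @export
generate_serology <- function(scores, spec, seed = 1) {
  stopifnot(inherits(spec, "SerologySpec"))
  z <- scores$z
  missing <- setdiff(unique(spec$panel$module), rownames(z))
  if (length(missing)) {
    stop("serology loadings reference unknown modules: ", paste(missing, collapse = ", "))
  }
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(spec$panel)), function(i) {
      p <- spec$panel[i, ]
      val <- p$slope * z[p$module, ] + stats::rnorm(ncol(z), 0, spec$noise_sd)
      pos <- if (p$type == "binary") {
        val > stats::quantile(val, 1 - p$positivity_rate, names = FALSE)
      } else {
        NA
      }
      data.frame(
        sample_id = colnames(z), analyte = p$analyte, value = unname(val),
        positive = pos, stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
}

#' Default drug targets and drug-gene interaction snapshot
#'
#' Toy counterparts of the study's selected targets: an IFNAR-like receptor
#' gene in the IFN module (anifrolumab), a CD38-like gene in the plasma-cell
#' module (daratumumab) and a CD19-like gene in the B-cell module. All gene
#' ids are synthetic.
#' @return `default_drug_targets()`: data frame `drug`, `target_gene`,
#'   `module`. `default_drug_interactions()`: data frame `drug`, `gene`,
#'   `interaction`, `source`.
#' @export
default_drug_targets <- function() {
  data.frame(
    drug = c("anifrolumab", "daratumumab", "cd19_mab"),
    target_gene = c("IFN.001", "PLASMA.001", "BCELL.001"),
    module = c("IFN", "PLASMA", "BCELL"),
    stringsAsFactors = FALSE
  )
}

#' @rdname default_drug_targets
#' @export
default_drug_interactions <- function() {
  data.frame(
    drug = c(
      "anifrolumab", "daratumumab", "cd19_mab",
      "ifn_agonist", "bcell_growth_factor", "plasma_binder"
    ),
    gene = c("IFN.001", "PLASMA.001", "BCELL.001", "IFN.002", "BCELL.002", "PLASMA.002"),
    interaction = c("inhibitor", "inhibitor", "inhibitor", "stimulator", "stimulator", "other"),
    source = "synthetic_snapshot",
    stringsAsFactors = FALSE
  )
}

#' Default regulator target sets (regulon GMT)
#'
#' One dominant regulator per planted module (targets = a subset of the
#' module) plus background regulators with unrelated targets.
#' @param effects Planted module effects.
#' @return Named list of target gene sets.
#' @export
default_regulons <- function(effects = default_module_effects()) {
  list(
    IRF7_like = effects$IFN$genes[1:40],
    PAX5_like = effects$BCELL$genes[1:40],
    PRDM1_like = effects$PLASMA$genes[1:40],
    NULL_REG1 = sprintf("G%04d", 1:40),
    NULL_REG2 = sprintf("G%04d", 41:80)
  )
}
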