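# End-to-end orchestration: synthetic (or user-supplied) data -> preprocess
# -> differential expression -> ORA -> coexpression modules (discovery /
# replication) -> dysregulation z-scores and subgroups -> serology
# association -> regulators and drugs -> pathway perturbation, with a
# provenance manifest. Deterministic per seed.

#' Pipeline configuration
#'
#' Stage parameters default to the study's stated constants where one exists
#' (FDR alpha 0.05, |log2FC| gate 0.58, 1:5 control matching, |z| > 1
#' prominence, k = 3 subgroups, inhibition factor 0.1, expected-count rule 5).
#'
#' @param seed Global seed; per-stage child seeds are derived from it.
#' @param alpha FDR threshold for significance.
#' @param lfc Fold-change gate on |log2FC|.
#' @param match_ratio Controls per case.
#' @param min_cpm,min_fraction Low-count filter.
#' @param z_prominence Module prominence gate on subgroup-mean |z|.
#' @param k_subgroups Number of patient clusters.
#' @param inhibition_factor Multiplication factor simulating inhibition.
#' @param expected_count_rule Expected-count threshold switching Fisher /
#'   chi-square.
#' @param jaccard_min Module replication Jaccard gate.
#' @param network `NetworkParams` for module detection.
#' @param cohort `CohortSpec` for the synthetic study.
#' @param effects Planted module effects.
#' @param targets Drug target table (`drug`, `target_gene`, `module`).
#' @param ifn_reference Name of the IFN reference set used to orient
#'   subgroup labels.
#' @return List of class `PipelineConfig`.
#' @export
pipeline_config <- function(seed = 1, alpha = 0.05, lfc = 0.58, match_ratio = 5,
                            min_cpm = 1, min_fraction = 0.1, z_prominence = 1,
                            k_subgroups = 3, inhibition_factor = 0.1,
                            expected_count_rule = 5, jaccard_min = 0.25,
                            network = network_params(),
                            cohort = cohort_spec(seed = seed),
                            effects = default_module_effects(),
                            targets = default_drug_targets(),
                            ifn_reference = "IFN") {
  cfg <- list(
    seed = as.integer(seed), alpha = alpha, lfc = lfc, match_ratio = match_ratio,
    min_cpm = min_cpm, min_fraction = min_fraction, z_prominence = z_prominence,
    k_subgroups = k_subgroups, inhibition_factor = inhibition_factor,
    expected_count_rule = expected_count_rule, jaccard_min = jaccard_min,
    network = network, cohort = cohort, effects = effects, targets = targets,
    ifn_reference = ifn_reference
  )
  stopifnot(inherits(cfg$network, "NetworkParams"), inherits(cfg$cohort, "CohortSpec"))
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read and validate a pipeline configuration from YAML
#'
#' Scalar parameters override the defaults of [pipeline_config()]; any file
#' paths listed under `paths:` are checked for existence before any compute.
#'
#' @param path YAML file.
#' @return A `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$paths)) {
    missing <- Filter(function(p) !file.exists(p), unlist(raw$paths))
    if (length(missing)) {
      stop("configured input path(s) do not exist: ", paste(missing, collapse = ", "))
    }
  }
  scalars <- intersect(names(raw), c(
    "seed", "alpha", "lfc", "match_ratio", "min_cpm", "min_fraction",
    "z_prominence", "k_subgroups", "inhibition_factor", "expected_count_rule",
    "jaccard_min", "ifn_reference"
  ))
  cfg <- do.call(pipeline_config, raw[scalars])
  cfg$paths <- raw$paths
  cfg
}

child_seed <- function(seed, stage) {
  (as.double(seed) * 1000003 + stage) %% 2147483647
}

#' Run the full stratification and druggability pipeline
#'
#' Executes the stages on a synthetic study generated from the config, and
#' optionally writes every table plus a provenance manifest to `out_dir`.
#' Re-running with the same config and seed reproduces byte-identical
#' outputs.
#'
#' @param config A `PipelineConfig`.
#' @param out_dir Output directory (created if needed); NULL for no files.
#' @return (Invisibly) a list with every stage's result: `data`, `logcpm`,
#'   `matched`, `de`, `partition`, `gated`, `ora`, `modules`, `scores`,
#'   `serology`, `associations`, `regulators`, `drugs`, `perturbation`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  data <- stage("simulate", generate_cohort(config$cohort, config$effects))
  meta <- data$meta
  reference_sets <- lapply(config$effects, `[[`, "genes")

  prep <- stage("preprocess", {
    counts <- collapse_duplicate_symbols(data$counts)
    counts <- filter_low_counts(counts, config$min_cpm, config$min_fraction)
    log_cpm(counts)
  })

  matched <- stage("match", {
    pool <- meta[meta$group == "HC", ]
    list(
      ln = match_controls(meta[meta$group == "LN", ], pool, config$match_ratio),
      nonrenal = match_controls(meta[meta$group == "SLE_nonrenal", ], pool, config$match_ratio)
    )
  })

  de <- stage("dge", {
    sub_ln <- meta[meta$group == "LN" | meta$sample_id %in% matched$ln, ]
    sub_nr <- meta[meta$group == "SLE_nonrenal" | meta$sample_id %in% matched$nonrenal, ]
    list(
      ln = fit_dge(prep[, sub_ln$sample_id], sub_ln, "LN", alpha = config$alpha),
      nonrenal = fit_dge(prep[, sub_nr$sample_id], sub_nr, "SLE_nonrenal", alpha = config$alpha)
    )
  })
  partition <- venn_partition(
    de$ln$gene_id[de$ln$significant],
    de$nonrenal$gene_id[de$nonrenal$significant]
  )
  gated <- list(
    ln = gate_fc(de$ln, config$lfc),
    nonrenal = gate_fc(de$nonrenal, config$lfc)
  )
  enrichment <- stage("ora", {
    if (length(partition$a_specific)) {
      ora(partition$a_specific, reference_sets, universe = de$ln$gene_id, min_size = 10)
    } else {
      NULL
    }
  })

  modules <- stage("modules", {
    ln_ids <- meta$sample_id[meta$group == "LN"]
    disc_ids <- meta$sample_id[meta$group == "LN" & meta$cohort == "discovery"]
    repl_ids <- meta$sample_id[meta$group == "LN" & meta$cohort == "replication"]
    expressed <- prep[, ln_ids]
    ok <- apply(expressed$values, 1, stats::sd) > 0
    expressed <- expressed[ok, ]
    # residualize technical/demographic covariates (coefficients estimated
    # on the full sample set, so small patient cohorts lose no precision)
    # so that shared covariate axes do not masquerade as coexpression
    adj <- adjust_covariates(prep[ok, ], meta)
    adj_disc <- adj[, disc_ids]
    adj_repl <- adj[, repl_ids]
    adj_disc <- adj_disc[apply(adj_disc$values, 1, stats::sd) > 0, ]
    adj_repl <- adj_repl[apply(adj_repl$values, 1, stats::sd) > 0, ]
    disc <- detect_modules(adj_disc, config$network, cohort = "discovery")
    repl <- detect_modules(adj_repl, config$network, cohort = "replication")
    disc <- replicate_modules(disc, repl, gene_ids(expressed), config$jaccard_min, config$alpha)
    replicated <- Filter(function(m) isTRUE(m$replicated), disc)
    if (!length(replicated)) stop("no replicated modules")
    # annotation profiles over the same adjusted matrix the eigengenes live on
    annotate_modules(replicated, reference_sets, adj_disc)
  })

  scores <- stage("zscore", {
    ln_ids <- meta$sample_id[meta$group == "LN"]
    msm <- module_score_matrix(prep, matched$ln, ln_ids, modules)
    wc <- ward_cluster(msm$z, k = config$k_subgroups)
    ifn_name <- grep(config$ifn_reference, rownames(msm$z), value = TRUE)[1]
    if (is.na(ifn_name)) stop("no module annotated to the IFN reference")
    msm <- label_ifn_subgroups(msm, wc$labels, ifn_name)
    msm$tree <- wc$tree
    msm$prominent <- prominent_modules(msm, msm$subgroup, config$z_prominence)
    msm$ifn_module <- ifn_name
    msm
  })

  sero_spec <- default_serology_spec()
  # only analytes whose module was recovered can be simulated
  sero_spec$panel <- sero_spec$panel[sero_spec$panel$module %in% rownames(scores$z), ]
  serology <- stage("serology", {
    generate_serology(scores, sero_spec, seed = child_seed(config$seed, 7))
  })
  associations <- stage("associate", {
    cont <- serology[serology$analyte %in%
      sero_spec$panel$analyte[sero_spec$panel$type == "continuous"], ]
    bin <- serology[!is.na(serology$positive), ]
    rbind(
      cbind(associate_serology(scores, cont, "continuous"), mode = "continuous"),
      cbind(associate_serology(scores, bin, "binary"), mode = "binary")
    )
  })

  regulators <- stage("regulators", {
    regs <- default_regulons(config$effects)
    sets <- module_gene_sets(modules)
    out <- lapply(names(sets), function(nm) {
      cbind(module_name = nm, rank_regulators(sets[[nm]], regs, gene_ids(prep)))
    })
    do.call(rbind, out)
  })

  drugs <- stage("drugs", {
    interactions <- default_drug_interactions()
    sets <- module_gene_sets(modules)
    ln_ids <- meta$sample_id[meta$group == "LN"]
    out <- list()
    for (nm in intersect(scores$prominent, names(sets))) {
      gz <- gene_z(prep, matched$ln, ln_ids, sets[[nm]])
      for (sg in unique(scores$subgroup)) {
        mz <- rowMeans(gz[, names(scores$subgroup)[scores$subgroup == sg], drop = FALSE])
        ann <- annotate_drugs(sets[[nm]], mz, sg, interactions)
        if (nrow(ann)) out[[length(out) + 1L]] <- cbind(module_name = nm, ann)
      }
    }
    if (length(out)) do.call(rbind, out) else NULL
  })

  perturbation <- stage("perturb", {
    graphs <- generate_pathways(config$targets, config$effects, gene_ids(prep))
    scaled <- normalize_to_reference(prep, matched$ln)
    ln_ids <- meta$sample_id[meta$group == "LN"]
    res <- list()
    for (i in seq_len(nrow(config$targets))) {
      tg <- config$targets$target_gene[i]
      graph <- graphs[[paste0("path_", tg)]]
      sc <- vapply(ln_ids, function(s) {
        simulate_inhibition(graph, node_values(graph, scaled, s), tg,
          factor = config$inhibition_factor
        )$score
      }, numeric(1))
      resp <- classify_responders(sc)
      res[[i]] <- data.frame(
        patient_id = ln_ids, target = config$targets$drug[i],
        score = unname(sc), responder = unname(resp), stringsAsFactors = FALSE
      )
    }
    results <- do.call(rbind, res)
    report <- subgroup_response_report(results, scores$subgroup)
    list(results = results, report = report, graphs = graphs)
  })

  manifest <- list(
    package = "nephrostrat",
    version = as.character(utils::packageVersion("nephrostrat")),
    seed = config$seed,
    parameters = config[c(
      "alpha", "lfc", "match_ratio", "min_cpm", "min_fraction", "z_prominence",
      "k_subgroups", "inhibition_factor", "expected_count_rule", "jaccard_min"
    )],
    network = unclass(config$network),
    cohort = unclass(config$cohort)
  )

  out <- list(
    data = data, logcpm = prep, matched = matched, de = de,
    partition = partition, gated = gated, ora = enrichment, modules = modules,
    scores = scores, serology = serology, associations = associations,
    regulators = regulators, drugs = drugs, perturbation = perturbation,
    manifest = manifest
  )
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  invisible(out)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(out_dir, f)
  write_counts_tsv(res$logcpm, fp("logcpm.tsv"))
  write_tsv_table(res$data$meta, fp("metadata.tsv"))
  write_tsv_table(res$de$ln, fp("dge_ln_vs_hc.tsv"))
  write_tsv_table(res$de$nonrenal, fp("dge_nonrenal_vs_hc.tsv"))
  if (!is.null(res$ora)) write_tsv_table(res$ora, fp("ora_ln_specific.tsv"))
  write_gmt(module_gene_sets(res$modules), fp("modules.gmt"))
  z <- data.frame(module = rownames(res$scores$z), res$scores$z, check.names = FALSE)
  write_tsv_table(z, fp("module_scores.tsv"))
  write_tsv_table(
    data.frame(
      patient_id = names(res$scores$subgroup),
      subgroup = unname(res$scores$subgroup)
    ),
    fp("subgroups.tsv")
  )
  write_tsv_table(res$serology, fp("serology.tsv"))
  write_tsv_table(res$associations, fp("serology_associations.tsv"))
  write_tsv_table(res$regulators, fp("regulators.tsv"))
  if (!is.null(res$drugs)) write_tsv_table(res$drugs, fp("drug_annotations.tsv"))
  write_tsv_table(res$perturbation$results, fp("response_scores.tsv"))
  write_tsv_table(res$perturbation$report$proportions, fp("responder_proportions.tsv"))
  if (!is.null(res$perturbation$report$tests)) {
    write_tsv_table(res$perturbation$report$tests, fp("responder_tests.tsv"))
  }
  files <- list.files(out_dir, full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "manifest.json"))
  manifest <- res$manifest
  manifest$checksums <- as.list(tools::md5sum(files))
  names(manifest$checksums) <- basename(files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(out_dir)
}
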