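# End-to-end orchestration: simulate -> normalize -> differential ->
# signatures -> consensus network / key-driver analysis -> phenotype
# association, from a single validated config, with a run log and a
# machine-readable JSON report.

.default_config <- function() {
  list(
    seed = 1L,
    output_dir = "tmtkda_run",
    stages = list(simulate = TRUE, normalize = TRUE, differential = TRUE,
                  signatures = TRUE, network = TRUE, phenotype = TRUE),
    differential_fdr = 0.05,
    kda_fdr = 0.01,
    min_support = 2L,
    hops = 1L,
    top_k = 15L,
    design = list(),
    sim = list(),
    network_sim = list(),
    phenotype_effects = NULL,
    plex_paths = NULL,
    reference_channels = NULL,
    metadata_path = NULL,
    network_paths = NULL)
}

#' Validate and complete a pipeline configuration
#'
#' Fills defaults (differential FDR 0.05, KDA FDR 0.01, consensus support
#' 2, 1-hop neighborhoods), rejects unknown keys and out-of-range
#' thresholds, and checks stage-toggle consistency (each enabled stage
#' must be able to obtain its inputs from an earlier stage or a path).
#'
#' @param config Named list (e.g. parsed from YAML).
#' @return The completed config (class `pipeline_config`).
#' @export
validate_config <- function(config = list()) {
  if (inherits(config, "pipeline_config")) return(config)
  defaults <- .default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  unknown_stage <- setdiff(names(cfg$stages), names(defaults$stages))
  if (length(unknown_stage) > 0) {
    stopf("unknown stage toggle(s): %s", paste(unknown_stage, collapse = ", "))
  }
  cfg$stages <- utils::modifyList(defaults$stages, cfg$stages)
  for (th in c("differential_fdr", "kda_fdr")) {
    assert_scalar_number(cfg[[th]], th, lower = .Machine$double.eps, upper = 1)
  }
  assert_scalar_number(cfg$seed, "seed", lower = -2^31 + 10, upper = 2^31 - 10)
  assert_scalar_number(cfg$min_support, "min_support", lower = 1)
  assert_scalar_number(cfg$hops, "hops", lower = 1)
  assert_scalar_number(cfg$top_k, "top_k", lower = 1)
  st <- cfg$stages
  if (st$normalize && !st$simulate && is.null(cfg$plex_paths)) {
    stopf("normalize stage enabled without the simulate stage and without plex_paths")
  }
  if (st$normalize && !st$simulate && is.null(cfg$metadata_path)) {
    stopf("normalize stage enabled without the simulate stage and without metadata_path")
  }
  if (st$differential && !st$normalize) {
    stopf("conflicting stage toggles: differential requires the normalize stage")
  }
  if (st$signatures && !st$differential) {
    stopf("conflicting stage toggles: signatures requires the differential stage")
  }
  if (st$network && !st$signatures) {
    stopf("conflicting stage toggles: network requires the signatures stage")
  }
  if (st$network && !st$simulate && is.null(cfg$network_paths)) {
    stopf("network stage enabled without the simulate stage and without network_paths")
  }
  if (st$phenotype && !st$simulate) {
    stopf("conflicting stage toggles: phenotype requires the simulate stage")
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#' @param path Path to a YAML config.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in fixed order (simulate, normalize,
#' differential, signatures, network, phenotype), writing every
#' intermediate artifact (TSV/JSON/Newick) plus a run log and a JSON
#' report under `config$output_dir`. The report contains only quantities
#' recomputable from the stage outputs; identical config + seed give a
#' byte-identical report.
#'
#' @param config A `pipeline_config` (or a plain list, validated first).
#' @return Invisibly, the report list (also written to `report.json`).
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "run.log")
  cat(sprintf("tmtkda pipeline (seed %d)\n", cfg$seed), file = log_path)
  log <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path, append = TRUE)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(conditionMessage(e), file.path(out, sprintf("FAILED_%s", name)))
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  # echo of the effective configuration
  cfg_plain <- unclass(cfg)
  jsonlite::write_json(cfg_plain, file.path(out, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  report <- list(seed = cfg$seed)
  st <- cfg$stages
  design <- do.call(experiment_design, cfg$design)

  sim <- NULL
  netsim <- NULL
  if (st$simulate) run_stage("simulate", {
    params <- do.call(sim_params, utils::modifyList(cfg$sim, list(seed = cfg$seed)))
    sim <- simulate_tmt_experiment(design, params)
    for (tb in sim$plexes) {
      write_plex_table(tb, file.path(out, sprintf("%s.tsv", tb$plex_id)))
    }
    write_tsv(sim$metadata, file.path(out, "metadata.tsv"))
    write_tsv(sim$truth$differential, file.path(out, "truth_differential.tsv"))
    pf <- sim$truth$plex_factors
    if (!is.matrix(pf)) {
      write_tsv(data.frame(plex = names(pf), factor = unname(pf)),
                file.path(out, "truth_plex_factors.tsv"))
    }
    if (st$network) {
      proteins <- rownames(sim$plexes[[1]]$intensities)
      ns_defaults <- list(n_nodes = length(proteins), nodes = proteins,
                          signature_genes = sim$truth$differential$protein,
                          n_planted_drivers = 10L, enrichment = 5,
                          seed = cfg$seed + 1L)
      netsim <- do.call(simulate_network, utils::modifyList(ns_defaults, cfg$network_sim))
      write_edge_lists(netsim$networks, file.path(out, "networks.tsv"))
      write_tsv(data.frame(gene = netsim$truth$planted_drivers),
                file.path(out, "truth_drivers.tsv"))
    }
    log("simulate: %d proteins, %d samples, %d plexes",
        params$n_proteins, nrow(sim$metadata), length(sim$plexes))
  })

  norm <- NULL
  if (st$normalize) run_stage("normalize", {
    n_ref <- design$reference_channels_per_plex
    ref <- cfg$reference_channels %||%
      (if (n_ref > 0) sprintf("C%d", seq_len(n_ref)) else character())
    if (st$simulate) {
      paths <- file.path(out, sprintf("%s.tsv", names(sim$plexes)))
      metadata <- read_tsv(file.path(out, "metadata.tsv"))
    } else {
      paths <- cfg$plex_paths
      metadata <- read_tsv(cfg$metadata_path)
    }
    tables <- lapply(paths, read_plex_table, reference_channels = ref)
    norm <- quantify_plexes(tables, metadata)
    write_normalized_matrix(norm, file.path(out, "normalized_matrix.tsv"))
    irs_df <- data.frame(protein = rownames(norm$irs_factors), norm$irs_factors,
                         check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv(irs_df, file.path(out, "irs_factors.tsv"))
    jsonlite::write_json(list(provenance = norm$provenance,
                              sl_factors = norm$sl_factors),
                         file.path(out, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    report$proteins_quantified <- nrow(norm$values)
    log("normalize: %d complete-case proteins across %d samples",
        nrow(norm$values), ncol(norm$values))
  })

  contrasts <- NULL
  if (st$differential) run_stage("differential", {
    specs <- contrast_specs(design$genotypes, design$diets)
    contrasts <- lapply(specs, function(sp) run_contrast(norm, sp))
    for (ct in contrasts) {
      write_contrast_table(ct, file.path(out, sprintf("contrast_%s.tsv", attr(ct, "label"))))
    }
    report$significant_per_contrast <- lapply(
      contrasts, function(ct) sum(ct$q_value < cfg$differential_fdr))
    contrasts <- contrasts
    log("differential: 9 contrasts at FDR < %g", cfg$differential_fdr)
  })

  sigs <- NULL
  if (st$signatures) run_stage("signatures", {
    sigs <- lapply(contrasts, threshold_signature, q_cut = cfg$differential_fdr)
    for (sg in sigs) {
      write_signature(sg, file.path(out, sprintf("signature_%s.tsv", sg$label)))
    }
    core <- core_signature(sigs[c("a", "b", "c")])
    write_signature(core, file.path(out, "signature_core.tsv"))
    venn_genotype <- venn_partition(sigs[c("a", "b", "c")])
    venn_diet <- venn_partition(sigs[c("d", "f")])
    jsonlite::write_json(list(genotype_contrasts = as.list(venn_genotype),
                              diet_response = as.list(venn_diet)),
                         file.path(out, "venn.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    h <- cluster_samples(norm)
    write_dendrogram(h, file.path(out, "sample_dendrogram.nwk"))
    report$core_signature_size <- length(core$members)
    report$venn_genotype_contrasts <- as.list(venn_genotype)
    sigs <- sigs
    log("signatures: core size %d", length(core$members))
  })

  if (st$network) run_stage("network", {
    networks <- if (st$simulate) netsim$networks else read_edge_lists(cfg$network_paths)
    cons <- consensus_network(networks, min_support = cfg$min_support)
    write_tsv(cons$edges, file.path(out, "consensus_edges.tsv"))
    kda <- list()
    for (lab in c("a", "b", "c")) {
      res <- key_driver_analysis(cons, sigs[[lab]], hops = cfg$hops,
                                 q_cut = cfg$kda_fdr, top_k = cfg$top_k)
      write_tsv(attr(res, "audit"), file.path(out, sprintf("kda_audit_%s.tsv", lab)))
      kda[[lab]] <- res$gene
    }
    jsonlite::write_json(kda, file.path(out, "key_drivers.json"),
                         digits = NA, pretty = TRUE)
    report$consensus_network <- list(nodes = length(cons$nodes),
                                      edges = nrow(cons$edges))
    report$key_drivers <- kda
    log("network: consensus %d nodes / %d edges", length(cons$nodes), nrow(cons$edges))
  })

  if (st$phenotype) run_stage("phenotype", {
    eff <- cfg$phenotype_effects %||%
      default_phenotype_effects(design$genotypes, design$diets)
    ph <- simulate_phenotypes(sim$metadata, eff, seed = cfg$seed + 2L)
    write_tsv(ph$glucose, file.path(out, "glucose_curves.tsv"))
    write_tsv(ph$metabolites, file.path(out, "metabolites.tsv"))
    write_tsv(ph$proteins, file.path(out, "phenotype_proteins.tsv"))
    times <- eff$times
    tcols <- sprintf("t%d", times)
    auc <- apply(ph$glucose[, tcols], 1, auc_baseline, times = times)
    auc_df <- data.frame(sample_id = ph$glucose$sample_id,
                         genotype = ph$glucose$genotype,
                         diet = ph$glucose$diet, auc = auc,
                         stringsAsFactors = FALSE)
    write_tsv(auc_df, file.path(out, "glucose_auc.tsv"))
    grp <- split(auc_df$auc, paste(auc_df$genotype, auc_df$diet, sep = "."))
    av <- anova_tukey(grp)
    write_tsv(av$pairwise, file.path(out, "auc_tukey.tsv"))
    assoc <- associate_metabolite_protein(
      ph$metabolites, ph$proteins,
      pairs = data.frame(metabolite = "aa2", protein = "dhtkd1",
                         stringsAsFactors = FALSE))
    glu_assoc <- correlate(ph$metabolites$aa2, ph$glucose$t0,
                           x_name = "aa2", y_name = "fasting_glucose")
    write_tsv(rbind(assoc, glu_assoc), file.path(out, "associations.tsv"))
    report$phenotype <- list(
      anova_F = av$F, anova_p = av$p_value,
      auc_group_means = lapply(grp, mean),
      metabolite_protein = list(r = assoc$r, r_squared = assoc$r_squared,
                                p_value = assoc$p_value, n = assoc$n),
      metabolite_glucose = list(r = glu_assoc$r, r_squared = glu_assoc$r_squared,
                                p_value = glu_assoc$p_value, n = glu_assoc$n))
    log("phenotype: ANOVA F = %.3f on AUC, metabolite-protein r = %.3f",
        av$F, assoc$r)
  })

  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
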