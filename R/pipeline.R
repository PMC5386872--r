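#' Run the full analysis pipeline on a synthetic study
#'
#' Generates every input with the synthetic-data module, writes them to
#' `out_dir`, then runs the complete analysis: stringency filtering and
#' compendium merge, Table-style summaries, gold-standard extrapolation
#' (both ratio modes), cross-species conservation calls, profiles and
#' candidate projection, ancestral reconstruction over the species tree,
#' metabolic reaction coverage, abundance-matched enrichment comparisons,
#' and p-site prioritization. Every output lands in `out_dir` as TSV/JSON
#' (plus FASTA/Newick inputs); the master seed and all generator parameters
#' are logged to stderr and to `run_log.json`.
#'
#' @param config a [sim_config()]; its `seed` drives every random stream.
#' @param out_dir output directory, created if needed.
#' @return invisibly, a list with the main in-memory results (`compendium`,
#'   `summary`, `extrapolation`, `conservation_calls`, `profiles`,
#'   `candidates`, `coverage`, `enrichment`, `priority`, `phenotypes`,
#'   `truth`).
#' @export
run_pipeline <- function(config = sim_config(), out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  exp_dir <- file.path(out_dir, "experiments")
  dir.create(exp_dir, showWarnings = FALSE)
  message("run_pipeline: seed = ", config$seed)
  message("run_pipeline: parameters = ",
          paste(names(config), unlist(lapply(config, paste, collapse = ",")),
                sep = "=", collapse = "; "))

  # --- synthetic inputs -----------------------------------------------
  proteome <- gen_proteome(config)
  write_proteome_fasta(proteome, file.path(out_dir, "proteome.fasta"))
  sim <- simulate_phospho_experiments(proteome, config)
  for (eid in unique(sim$records$experiment_id)) {
    write_tsv(sim$records[sim$records$experiment_id == eid, ],
              file.path(exp_dir, paste0(eid, ".tsv")))
  }
  write_tsv(sim$ltp, file.path(out_dir, "ltp.tsv"))
  domains <- gen_domains(proteome, config)
  write_tsv(domains, file.path(out_dir, "domains.tsv"))

  # --- compendium ------------------------------------------------------
  filtered <- filter_peptides(sim$records, proteome = proteome)
  comp <- merge_datasets(filtered, ltp = sim$ltp, proteome = proteome,
                         domains = domains, label = "synthetic")
  write_compendium(comp, file.path(out_dir, "compendium.tsv"))
  phospho_ids <- unique(comp$sites$protein_id)

  model_tab <- gen_metabolic_model(proteome, config)
  write_tsv(model_tab, file.path(out_dir, "model.tsv"))
  model <- load_gene_reaction_table(model_tab)

  summ <- summarize_counts(comp, metabolic_genes = model$genes)
  write_tsv(summ, file.path(out_dir, "summary.tsv"))

  # --- gold-standard extrapolation ------------------------------------
  part <- partition_gold_overlap(comp, sim$ltp)
  extrap <- list(
    unit_ratio = unclass(extrapolate_functional_fraction(part, "unit_ratio")),
    empirical_ratio =
      unclass(extrapolate_functional_fraction(part, "empirical_ratio")),
    partition = unclass(part)
  )
  jsonlite::write_json(extrap, file.path(out_dir, "extrapolation.json"),
                       auto_unbox = TRUE, digits = NA)

  # --- cross-species conservation -------------------------------------
  orth_sp <- gen_ortholog_species(proteome, sim$truth$true_sites,
                                  site_key(comp$sites$protein_id,
                                           comp$sites$position),
                                  config)
  write_proteome_fasta(orth_sp$target_proteome,
                       file.path(out_dir, "target_proteome.fasta"))
  orthologs <- resolve_orthologs(orth_sp$synteny, orth_sp$best_hit)
  write_tsv(orthologs, file.path(out_dir, "orthologs.tsv"))
  target_comp <- compendium_from_sites(orth_sp$target_sites,
                                       orth_sp$target_proteome,
                                       label = "synthetic-target")
  write_compendium(target_comp, file.path(out_dir, "target_compendium.tsv"))

  calls <- call_conservation(comp, target_comp, orthologs)
  write_tsv(calls, file.path(out_dir, "conservation_calls.tsv"))
  pw_profile <- pairwise_conservation_profile(calls, model$genes)
  candidates <- project_candidate_sites(target_comp, comp, orthologs)
  write_tsv(candidates, file.path(out_dir, "candidate_sites.tsv"))

  # --- ancestral reconstruction over the species tree -----------------
  tree <- gen_species_tree(config)
  ape::write.tree(tree, file.path(out_dir, "species_tree.nwk"))
  anc_sc <- gen_ancestral_scenario(tree, comp$sites$residue, config)
  callset <- reconstruct_ancestral(tree, anc_sc$leaf_states, "parsimony")
  site_info <- data.frame(metabolic = comp$sites$protein_id %in% model$genes,
                          confidence = comp$sites$confidence)
  anc_profile <- ancestor_conservation_profile(callset, site_info)
  profiles <- rbind(pw_profile, anc_profile)
  write_tsv(profiles, file.path(out_dir, "conservation_profiles.tsv"))

  # --- metabolic coverage ---------------------------------------------
  hc_ids <- unique(comp$sites$protein_id[comp$sites$confidence == "HC"])
  cov_all <- reaction_coverage(model, phospho_ids, "ALL")
  cov_hc <- reaction_coverage(model, hc_ids, "HC")
  jsonlite::write_json(
    list(ALL = cov_all[setdiff(names(cov_all), "per_reaction")],
         HC = cov_hc[setdiff(names(cov_hc), "per_reaction")]),
    file.path(out_dir, "metabolic_coverage.json"),
    auto_unbox = TRUE, digits = NA)
  write_tsv(cov_all$per_reaction, file.path(out_dir, "reactions.tsv"))

  # --- abundance-matched enrichment -----------------------------------
  features <- gen_feature_table(proteome, phospho_ids, config)
  write_tsv(features, file.path(out_dir, "features.tsv"))
  negative <- build_negative_set(setdiff(names(proteome), phospho_ids),
                                 phospho_ids)
  abund <- stats::setNames(features$abundance, features$protein_id)
  matched <- abundance_matched_subsample(phospho_ids, negative, abund,
                                         seed = derive_seed(config$seed,
                                                            "features") + 1L)
  enrich_raw <- compare_feature_groups(
    features, phospho_ids, negative,
    numeric_features = c("abundance", "half_life", "ppi_count",
                         "genetic_interaction_count", "kinase_target_count",
                         "length", "disorder_length"),
    binary_features = c("essential", "ubiquitinated", "wgd_paralog"))
  enrich_raw$comparison <- "phospho_vs_negative"
  enrich_pac <- compare_feature_groups(
    features, matched$a, matched$b,
    numeric_features = c("ppi_count", "kinase_target_count",
                         "disorder_length"),
    binary_features = c("essential", "ubiquitinated"))
  enrich_pac$comparison <- "abundance_controlled"
  enrichment <- rbind(enrich_raw, enrich_pac)
  write_tsv(enrichment, file.path(out_dir, "enrichment.tsv"))

  # --- prioritization --------------------------------------------------
  phen <- gen_phenotypes(proteome, config)
  write_tsv(phen, file.path(out_dir, "phenotype_map.tsv"))
  anc_root_ok <- callset$conserved[, ncol(callset$conserved), drop = TRUE]
  records <- annotate_flags(
    comp, domains = domains,
    essential = features$protein_id[features$essential],
    conservation_calls = calls,
    ancestor_conserved = site_key(comp$sites$protein_id,
                                  comp$sites$position)[anc_root_ok],
    metabolic_genes = model$genes, phenotype_map = phen)
  priority <- tier_rank(records)
  write_tsv(priority, file.path(out_dir, "priority.tsv"))
  phen_tab <- phenotype_tabulate(records)
  write_tsv(phen_tab, file.path(out_dir, "phenotype_table.tsv"))

  # --- ground truth + run log -----------------------------------------
  jsonlite::write_json(
    list(true_keys = sim$truth$true_keys,
         spurious_keys = sim$truth$spurious_keys,
         ltp_keys = sim$truth$ltp_keys,
         functional_fraction = sim$truth$functional_fraction,
         retained = orth_sp$truth$retained,
         candidates = orth_sp$truth$candidates,
         seed = config$seed),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(config), file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  message("run_pipeline: wrote outputs to ", out_dir)

  invisible(list(
    compendium = comp, summary = summ, extrapolation = extrap,
    conservation_calls = calls, profiles = profiles,
    candidates = candidates, coverage = list(ALL = cov_all, HC = cov_hc),
    enrichment = enrichment, priority = priority, phenotypes = phen_tab,
    matched = matched, truth = list(phospho = sim$truth,
                                    ortholog = orth_sp$truth)
  ))
}
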