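test_that("generators are pure functions of config and seed", {
  cfg <- sim_config(seed = 19, n_proteins = 60, n_sites = 300)
  expect_identical(gen_proteome(cfg), gen_proteome(cfg))
  s1 <- simulate_phospho_experiments(gen_proteome(cfg), cfg)
  s2 <- simulate_phospho_experiments(gen_proteome(cfg), cfg)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$truth$true_keys, s2$truth$true_keys)
  expect_identical(gen_metabolic_model(gen_proteome(cfg), cfg),
                   gen_metabolic_model(gen_proteome(cfg), cfg))
  # byte-identical FASTA files from the same seed
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_proteome_fasta(gen_proteome(cfg), f1)
  write_proteome_fasta(gen_proteome(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))

  # an empty proteome is not a crash
  empty <- gen_proteome(sim_config(n_proteins = 0))
  expect_length(empty, 0)
})

test_that("proteome composition matches the configured S/T/Y frequencies", {
  cfg <- sim_config(seed = 2, n_proteins = 500,
                    sty_freq = c(S = 0.08, T = 0.06, Y = 0.03))
  prot <- gen_proteome(cfg)
  ch <- unlist(strsplit(prot, ""))
  for (r in c("S", "T", "Y")) {
    expect_lt(abs(mean(ch == r) - cfg$sty_freq[[r]]), 0.02)
  }
})

test_that("detection model yields binomial support for true sites", {
  # full detection, no noise: every experiment holds exactly the true sites
  cfg0 <- sim_config(seed = 8, n_proteins = 80, n_sites = 200,
                     functional_fraction = 1, detection_prob = 1,
                     noisy_record_rate = 0, multi_match_rate = 0)
  prot0 <- gen_proteome(cfg0)
  sim0 <- simulate_phospho_experiments(prot0, cfg0)
  for (e in unique(sim0$records$experiment_id)) {
    keys <- with(sim0$records[sim0$records$experiment_id == e, ],
                 paste(protein_id, position, sep = ":"))
    expect_setequal(keys, sim0$truth$true_keys)
  }

  # detection 0.3 over 20 experiments: expected support 6 per true site
  cfg <- sim_config(seed = 8, n_proteins = 200, n_sites = 1500,
                    detection_prob = 0.3, noisy_record_rate = 0,
                    multi_match_rate = 0)
  prot <- gen_proteome(cfg)
  sim <- simulate_phospho_experiments(prot, cfg)
  key <- paste(sim$records$protein_id, sim$records$position, sep = ":")
  sup <- table(key)
  tsup <- as.vector(sup[sim$truth$true_keys])
  tsup[is.na(tsup)] <- 0
  m <- mean(tsup)
  se <- sqrt(20 * 0.3 * 0.7 / length(tsup))
  expect_lt(abs(m - 6), 4 * se + 0.05)

  # spurious support concentrates on 1-2 experiments
  ssup <- as.vector(sup[intersect(names(sup), sim$truth$spurious_keys)])
  expect_gte(mean(ssup <= 2), 0.95)

  # the LTP subset is sampled from the genuine sites at the set coverage
  expect_true(all(sim$truth$ltp_keys %in% sim$truth$true_keys))
  expect_equal(length(sim$truth$ltp_keys),
               round(cfg$ltp_coverage * length(sim$truth$true_keys)))
})

test_that("ortholog generator plants retention, interchange and homology truth", {
  # zero divergence: identical proteomes and an identity map
  cfg0 <- sim_config(seed = 13, n_proteins = 40, n_sites = 200,
                     sub_prob = 0, indel_rate = 0, retention_prob = 1,
                     st_exchange_prob = 0, target_extra_rate = 0)
  prot <- gen_proteome(cfg0)
  sim <- simulate_phospho_experiments(prot, cfg0)
  orth0 <- gen_ortholog_species(prot, sim$truth$true_sites, character(), cfg0)
  expect_identical(unname(orth0$target_proteome),
                   unname(prot))
  expect_identical(orth0$truth$homolog_map[["P0001"]],
                   seq_len(nchar(prot[["P0001"]])))

  # planted interchange fraction recovered within binomial error
  cfg <- sim_config(seed = 13, n_proteins = 150, n_sites = 1500,
                    retention_prob = 0.6)
  prot <- gen_proteome(cfg)
  sim <- simulate_phospho_experiments(prot, cfg)
  orth <- gen_ortholog_species(prot, sim$truth$true_sites, character(), cfg)
  ret <- orth$truth$retained
  st <- ret[ret$residue %in% c("S", "T"), ]
  obs <- mean(st$interchange)
  tol <- 3 * sqrt(0.12 * 0.88 / nrow(st))
  expect_lt(abs(obs - 0.12), tol)

  # the generator's own truth is internally consistent: the residue at the
  # mapped position is swapped exactly for flagged sites
  tres <- mapply(function(p, t) {
    substring(orth$target_proteome[[paste0("O_", p)]], t, t)
  }, ret$protein_id, ret$target_position)
  expect_true(all((tres != ret$residue) == ret$interchange))
  # retained sites all appear in the target site table
  tk <- paste(orth$target_sites$protein_id, orth$target_sites$position,
              sep = ":")
  expect_true(all(paste0("O_", ret$protein_id, ":", ret$target_position)
                  %in% tk))
})

test_that("feature generator plants group effects and missingness", {
  cfg <- sim_config(seed = 29, n_proteins = 600)
  prot <- gen_proteome(cfg)
  phos <- sample(names(prot), 300)
  f <- gen_feature_table(prot, phos, cfg)
  expect_equal(nrow(f), 600)
  # missingness close to the configured fraction
  expect_lt(abs(mean(is.na(f$abundance)) - cfg$abundance_missing_frac), 0.05)
  # planted direction of effects
  isp <- f$protein_id %in% phos
  expect_gt(mean(f$abundance[isp], na.rm = TRUE),
            mean(f$abundance[!isp], na.rm = TRUE))
  expect_gt(mean(f$ppi_count[isp]), mean(f$ppi_count[!isp]))
  expect_gt(mean(f$ubiquitinated[isp]), mean(f$ubiquitinated[!isp]))
  expect_equal(f$length, unname(nchar(prot)))

  # zero planted effect: matched rank test stays non-significant in at
  # least 95 of 100 seeded runs (type-I behavior of the matching pipeline)
  rej <- 0
  for (i in 1:100) {
    set.seed(5000 + i)
    a <- stats::setNames(10^rnorm(120, 3.0, 0.5), paste0("a", 1:120))
    b <- stats::setNames(10^rnorm(100, 3.0, 0.5), paste0("b", 1:100))
    mm <- abundance_matched_subsample(names(a), names(b), c(a, b),
                                      seed = 6000 + i)
    p <- suppressWarnings(stats::wilcox.test(c(a, b)[mm$a],
                                             c(a, b)[mm$b]))$p.value
    rej <- rej + (p < 0.05)
  }
  expect_lte(rej, 5)
})

test_that("metabolic model generator respects the configured degree", {
  cfg <- sim_config(seed = 37, n_proteins = 300, n_reactions = 200,
                    genes_per_reaction_mean = 2.5)
  prot <- gen_proteome(cfg)
  tab <- gen_metabolic_model(prot, cfg)
  deg <- table(tab$reaction_id)
  expect_equal(length(deg), 200)
  expect_lt(abs(mean(deg) - 2.5), 3 * sqrt(1.5 / 200) + 0.05)
  # ten reactions with exactly one gene each: full coverage equals ten
  cfg1 <- sim_config(seed = 37, n_proteins = 50, n_reactions = 10,
                     genes_per_reaction_mean = 1)
  tab1 <- gen_metabolic_model(gen_proteome(cfg1), cfg1)
  m1 <- load_gene_reaction_table(tab1)
  expect_true(all(lengths(m1$reactions) == 1))
  expect_equal(reaction_coverage(m1, m1$genes)$n_reactions_covered, 10)
})

test_that("ancestral scenario generator plants per-branch retention", {
  cfg <- sim_config(seed = 41, ancestral_retention = 0.9, n_species = 6)
  tr <- gen_species_tree(cfg)
  sc <- gen_ancestral_scenario(tr, rep("S", 3000), cfg)
  expect_equal(dim(sc$leaf_states), c(3000, 6))
  # the root is always present by construction
  expect_true(all(sc$node_presence[, 1]))
  # leaf survival matches q^depth within binomial error
  depths <- ape::node.depth.edgelength(ape::compute.brlen(tr, 1))[1:6]
  for (t in seq_len(6)) {
    expected <- 0.9^depths[t]
    obs <- mean(sc$leaf_states[, tr$tip.label[t]] == "S")
    expect_lt(abs(obs - expected),
              4 * sqrt(expected * (1 - expected) / 3000) + 0.01)
  }
})

test_that("simulation config validates probabilities and shapes", {
  expect_error(sim_config(functional_fraction = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(sty_freq = c(S = 0.5, T = 0.4, Y = 0.2)), "sum")
  expect_error(sim_config(indel_mean_len = 0.2), "indel_mean_len")
})
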