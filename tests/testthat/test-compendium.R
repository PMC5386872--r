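test_that("filter_peptides enforces stringency, uniqueness and residue consistency", {
  rec <- rbind(
    toy_records("e1", "P1", 2, "S", id_prob = 0.995, loc_prob = 0.992),
    toy_records("e1", "P1", 3, "T", id_prob = 0.98, loc_prob = 1.0),
    toy_records("e1", "P1", 4, "Y", id_prob = 1.0, loc_prob = 0.97),
    toy_records("e1", "P2", 4, "S", n_matches = 2L),
    toy_records("e2", "P1", 7, "S")
  )
  out <- filter_peptides(rec, 0.99, 0.99)
  expect_equal(nrow(out), 2)
  expect_equal(out$position, c(2, 7))          # order preserving
  expect_equal(rec$position, c(2, 3, 4, 4, 7)) # input untouched

  # residue/proteome disagreement is dropped with a warning, not an error
  bad <- toy_records("e1", "P1", 5, "S")  # P1[5] is A
  expect_warning(out2 <- filter_peptides(rbind(rec, bad),
                                         proteome = toy_proteome()),
                 "disagrees")
  expect_equal(nrow(out2), 2)

  expect_equal(nrow(filter_peptides(rec[0, ])), 0)
  expect_error(filter_peptides(rec[, -3]), "missing column")
})

test_that("merge_datasets counts distinct experiments and applies the HC rule", {
  prot <- toy_proteome()
  rec <- rbind(
    toy_records(c("e1", "e2", "e3"), "P1", 2, "S"),   # 3 experiments -> HC
    toy_records(c("e1", "e1"), "P1", 7, "S"),         # duplicate rows -> 1
    toy_records("e2", "P2", 4, "S")                   # once, but in LTP
  )
  ltp <- data.frame(protein_id = c("P2", "P2"), position = c(4, 10),
                    residue = c("S", "S"))
  comp <- merge_datasets(rec, ltp = ltp, proteome = prot)
  s <- comp$sites
  key <- paste(s$protein_id, s$position)

  expect_equal(s$htp_support[key == "P1 2"], 3)
  expect_equal(s$confidence[key == "P1 2"], "HC")
  expect_equal(s$htp_support[key == "P1 7"], 1)   # distinct-experiment count
  expect_equal(s$confidence[key == "P1 7"], "ALL")
  expect_equal(s$confidence[key == "P2 4"], "HC") # LTP rescues single hit
  # LTP-only site enters with zero HTP support, HC
  expect_equal(s$htp_support[key == "P2 10"], 0)
  expect_true(s$ltp[key == "P2 10"])
  expect_equal(anyDuplicated(key), 0)

  # LTP site on a non-acceptor residue is rejected with a warning
  expect_warning(
    comp2 <- merge_datasets(rec, proteome = prot,
                            ltp = data.frame(protein_id = "P3", position = 3,
                                             residue = "S")),
    "rejected")
  expect_false("P3" %in% comp2$sites$protein_id)

  # records conflicting with the proteome residue are dropped in merge
  expect_warning(
    comp3 <- merge_datasets(rbind(rec, toy_records("e1", "P3", 3, "S")),
                            proteome = prot),
    "conflicts")
  expect_false("P3" %in% comp3$sites$protein_id)

  expect_error(merge_datasets(toy_records("e1", "NOPE", 1, "S"),
                              proteome = prot), "not in proteome")
})

test_that("merging is idempotent and HC is monotone in added evidence", {
  prot <- toy_proteome()
  rec <- rbind(
    toy_records(c("e1", "e2"), "P1", 2, "S"),
    toy_records("e1", "P2", 4, "S"),
    toy_records(c("e1", "e2", "e3"), "P2", 11, "T")
  )
  c1 <- merge_datasets(rec, proteome = prot)
  c2 <- merge_datasets(rbind(rec, rec), proteome = prot)  # replayed input
  expect_identical(c1$sites, c2$sites)

  # adding one experiment that re-reports a site only raises support
  c3 <- merge_datasets(rbind(rec, toy_records("e9", "P1", 2, "S")),
                       proteome = prot)
  k <- paste(c1$sites$protein_id, c1$sites$position)
  k3 <- paste(c3$sites$protein_id, c3$sites$position)
  expect_true(all(c3$sites$htp_support[match(k, k3)] >= c1$sites$htp_support))
  was_hc <- c1$sites$confidence == "HC"
  expect_true(all(c3$sites$confidence[match(k[was_hc], k3)] == "HC"))
  expect_equal(c3$sites$htp_support[k3 == "P1 2"], 3)
  expect_equal(c3$sites$confidence[k3 == "P1 2"], "HC")
})

test_that("summary counts equal a brute-force recount on a synthetic fixture", {
  cfg <- sim_config(seed = 11, n_proteins = 120, n_sites = 500)
  prot <- gen_proteome(cfg)
  sim <- simulate_phospho_experiments(prot, cfg)
  domains <- gen_domains(prot, cfg)
  comp <- merge_datasets(filter_peptides(sim$records, proteome = prot),
                         ltp = sim$ltp, proteome = prot, domains = domains)
  met <- sample(names(prot), 30)
  summ <- summarize_counts(comp, metabolic_genes = met)

  # independent recount straight off the site table
  s <- comp$sites
  recount <- function(stratum, part) {
    rows <- s
    if (stratum == "HC") rows <- rows[rows$confidence == "HC", ]
    inmet <- rows$protein_id %in% met
    if (part == "metabolic") rows <- rows[inmet, ]
    if (part == "non_metabolic") rows <- rows[!inmet, ]
    c(nrow(rows), sum(rows$in_domain), length(unique(rows$protein_id)))
  }
  for (i in seq_len(nrow(summ))) {
    rc <- recount(summ$stratum[i], summ$partition[i])
    expect_equal(summ$n_sites[i], rc[1])
    expect_equal(summ$n_in_domain[i], rc[2])
    expect_equal(summ$n_proteins[i], rc[3])
    if (rc[3] > 0) {
      expect_equal(summ$mean_sites_per_protein[i],
                   round_half_up(rc[1] / rc[3], 1))
    }
  }
  # partitions are disjoint and exhaustive
  for (st in c("ALL", "HC")) {
    rows <- summ[summ$stratum == st, ]
    expect_equal(rows$n_sites[rows$partition == "metabolic"] +
                   rows$n_sites[rows$partition == "non_metabolic"],
                 rows$n_sites[rows$partition == "all"])
  }
  # every residue matches the proteome sequence (checked exhaustively)
  expect_true(all(substring(prot[s$protein_id], s$position, s$position) ==
                    s$residue))
  # support never exceeds the number of experiments
  expect_true(all(s$htp_support <= length(comp$experiment_ids)))

  # one site in one protein: all means 1, empty HC stratum flagged
  one <- merge_datasets(toy_records("e1", "P1", 2, "S"),
                        proteome = toy_proteome())
  s1 <- summarize_counts(one)
  expect_equal(s1$mean_sites_per_protein[s1$stratum == "ALL" &
                                           s1$partition == "all"], 1.0)
  hc_all <- s1[s1$stratum == "HC" & s1$partition == "all", ]
  expect_true(hc_all$empty)
  expect_equal(hc_all$mean_sites_per_protein, 0)
})

test_that("compendium TSV round-trips through write/read", {
  prot <- toy_proteome()
  rec <- rbind(toy_records(c("e1", "e2", "e3"), "P1", 2, "S"),
               toy_records("e2", "P2", 4, "S"))
  comp <- merge_datasets(rec, proteome = prot,
                         domains = data.frame(protein_id = "P1", start = 1,
                                              end = 5, domain_name = "d"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_compendium(comp, path)
  back <- read_compendium(path, prot)
  expect_equal(back$sites$htp_support, comp$sites$htp_support)
  expect_equal(back$sites$confidence, comp$sites$confidence)
  expect_equal(back$sites$in_domain, comp$sites$in_domain)
})
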