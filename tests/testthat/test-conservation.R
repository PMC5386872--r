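test_that("ortholog resolution prefers synteny and breaks best-hit ties", {
  syn <- data.frame(gene_a = c("g1", "g3"), gene_b = c("t1", "t3"))
  bh <- data.frame(gene_a = c("g1", "g2", "g4", "g4"),
                   gene_b = c("tX", "t2", "tB", "tA"),
                   score = c(900, 500, 700, 700))
  out <- resolve_orthologs(syn, bh)
  expect_equal(out$gene_b[out$gene_a == "g1"], "t1")      # synteny wins
  expect_equal(out$evidence[out$gene_a == "g1"], "synteny")
  expect_equal(out$gene_b[out$gene_a == "g2"], "t2")      # best-hit fill
  expect_equal(out$gene_b[out$gene_a == "g4"], "tA")      # lexicographic tie
  expect_equal(anyDuplicated(out$gene_a), 0)

  expect_error(resolve_orthologs(
    data.frame(gene_a = c("g1", "g1"), gene_b = c("t1", "t9"))), "g1")
})

test_that("global alignment matches the brute-force Gotoh oracle", {
  mat <- phoscompendium:::resolve_submat("BLOSUM62")

  # identical sequences: identity map, zero gaps
  m <- align_global("MSTYK", "MSTYK")
  expect_equal(m$a_to_b, 1:5)
  expect_false(grepl("-", m$aligned_a, fixed = TRUE))

  # single deletion: one gapped column, score equals the DP oracle
  m2 <- align_global("ACDEFG", "ACEFG")
  expect_equal(sum(strsplit(m2$aligned_b, "")[[1]] == "-"), 1)
  expect_equal(m2$score, gotoh_score("ACDEFG", "ACEFG", mat))

  # optimality: forcing an extra gap can never raise the score
  forced <- score_gapped("ACDEFG-", "AC-EFGG", mat)  # arbitrary worse layout
  expect_gte(align_global("ACDEFG", "ACEFGG")$score, forced)

  # ambiguity residue X is neutral
  expect_equal(align_global("AXA", "AWA")$score,
               mat["A", "A"] * 2)
  expect_error(align_global("", "ACD"), "non-empty")

  # randomized small-instance equivalence over a reduced alphabet
  alpha <- c("A", "C", "D", "S", "T")
  set.seed(42)
  for (i in 1:25) {
    a <- paste(sample(alpha, sample(1:8, 1), replace = TRUE), collapse = "")
    b <- paste(sample(alpha, sample(1:8, 1), replace = TRUE), collapse = "")
    expect_equal(align_global(a, b)$score, gotoh_score(a, b, mat),
                 info = paste(a, b))
  }
})

test_that("site mapping round-trips and rejects out-of-range positions", {
  m <- align_global("ACDEFG", "ACEFG")
  expect_true(is.na(map_site(m, 3)))           # D column is a B gap
  expect_equal(map_site(m, 5), 4)
  # round trip on every non-gap column
  for (p in which(!is.na(m$a_to_b))) {
    expect_equal(m$b_to_a[m$a_to_b[p]], p)
  }
  expect_error(map_site(m, 0), "out of range")
  expect_error(map_site(m, 7), "out of range")
})

test_that("conservation categories follow the classification rules and partition", {
  expect_equal(classify_site_conservation("S", "S", TRUE), "phospho_conserved")
  expect_equal(classify_site_conservation("S", "T", TRUE), "interchange_ST")
  expect_equal(classify_site_conservation("T", "S", TRUE), "interchange_ST")
  expect_equal(classify_site_conservation("S", "Y", TRUE), "phospho_conserved")
  expect_equal(classify_site_conservation("S", "T", FALSE), "residue_conserved")
  expect_equal(classify_site_conservation("S", "A", FALSE), "not_conserved")
  expect_equal(classify_site_conservation("S", NA, FALSE), "not_conserved")
  expect_equal(classify_site_conservation("S", "-", TRUE), "not_conserved")

  # categories partition classified sites
  set.seed(9)
  res <- sample(c("S", "T", "Y"), 200, replace = TRUE)
  tgt <- sample(c("S", "T", "Y", "A", "K", NA), 200, replace = TRUE)
  ph <- sample(c(TRUE, FALSE), 200, replace = TRUE)
  cat_ <- classify_site_conservation(res, tgt, ph)
  expect_equal(length(cat_), 200)
  expect_true(all(cat_ %in% c("phospho_conserved", "interchange_ST",
                              "residue_conserved", "not_conserved")))
  expect_equal(sum(table(cat_)), 200)
})

test_that("Fitch/Sankoff parsimony equals exhaustive labeling on small trees", {
  # all leaves identical -> every ancestor fixed, zero changes
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  cs <- reconstruct_ancestral(tr, c(a = "S", b = "S", c = "S", d = "S"))
  expect_true(all(cs$states == "S"))
  expect_equal(cs$changes, 0)

  # textbook case: S,S,T,A needs 2 changes; every state reaches the
  # minimum at the root, so the optimistic conserved flag is TRUE
  cs2 <- reconstruct_ancestral(tr, c(a = "S", b = "S", c = "T", d = "A"))
  expect_equal(cs2$changes,
               enum_parsimony(tr, c(a = "S", b = "S", c = "T", d = "A")))
  expect_setequal(cs2$state_sets[[1]][[1]], c("A", "S", "T"))
  expect_true(cs2$conserved[1, 1])
  # the (a,b) cherry is unambiguously serine
  expect_equal(cs2$state_sets[[1]][[2]], "S")

  # missing leaves contribute nothing
  cs3 <- reconstruct_ancestral(tr, c(a = "S", b = NA, c = "T", d = NA))
  expect_equal(cs3$changes,
               enum_parsimony(tr, c(a = "S", b = NA, c = "T", d = NA)))

  # randomized equivalence with the exhaustive-labeling oracle, and with
  # phangorn's independent Fitch implementation, on trees of 4-5 leaves
  set.seed(7)
  for (i in 1:12) {
    n <- sample(4:5, 1)
    tr_i <- ape::rtree(n)
    st <- stats::setNames(sample(c("S", "T", "A"), n, replace = TRUE),
                          tr_i$tip.label)
    got <- reconstruct_ancestral(tr_i, st)$changes
    expect_equal(got, enum_parsimony(tr_i, st), info = paste("case", i))
    pd <- phangorn::phyDat(matrix(st, ncol = 1,
                                  dimnames = list(names(st), NULL)),
                           type = "USER", levels = c("S", "T", "A"))
    expect_equal(got, phangorn::parsimony(tr_i, pd), info = paste("ph", i))
  }

  # multifurcations are accepted in parsimony mode
  star <- ape::read.tree(text = "(a:1,b:1,c:1);")
  cs4 <- reconstruct_ancestral(star, c(a = "S", b = "S", c = "T"))
  expect_equal(cs4$changes, 1)
  expect_equal(cs4$state_sets[[1]][[1]], "S")
})

test_that("ML reconstruction handles simple cases and rejects polytomies", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  ml <- reconstruct_ancestral(tr, c(a = "S", b = "S", c = "S", d = "S"), "ml")
  expect_true(all(ml$states == "S"))
  expect_true(all(ml$conserved))

  ml2 <- reconstruct_ancestral(tr, c(a = "S", b = "S", c = "S", d = "A"), "ml")
  expect_equal(unname(ml2$states[1, 1]), "S")  # root favors the majority

  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  expect_error(reconstruct_ancestral(star, c(a = "S", b = "S", c = "T",
                                             d = "A"), "ml"), "polytomies")

  # parsimony and ML agree on identical-residue columns (both conserved)
  for (r in c("S", "T", "Y")) {
    st <- stats::setNames(rep(r, 4), tr$tip.label)
    expect_identical(reconstruct_ancestral(tr, st, "parsimony")$states,
                     reconstruct_ancestral(tr, st, "ml")$states)
  }
})

test_that("ancestral profiles aggregate conserved flags per stratum cell", {
  tr <- ape::read.tree(text = "((a:1,b:1)A2:1,(c:1,d:1)A3:1)A1;")
  leaf <- rbind(c(a = "S", b = "S", c = "S", d = "S"),
                c(a = "S", b = "A", c = "A", d = "A"),
                c(a = "T", b = "T", c = "A", d = "A"),
                c(a = "Y", b = "Y", c = "Y", d = "A"))
  cs <- reconstruct_ancestral(tr, leaf)
  info <- data.frame(metabolic = c(TRUE, TRUE, FALSE, FALSE),
                     confidence = c("HC", "ALL", "HC", "ALL"))
  prof <- ancestor_conservation_profile(cs, info)

  # hand recount for the root, metabolic, ALL stratum: sites 1-2
  root_met <- prof[prof$node == "A1" & prof$stratum == "ALL" &
                     prof$partition == "metabolic", ]
  expect_equal(root_met$n_sites, 2)
  expect_equal(root_met$n_conserved, sum(cs$conserved[1:2, "A1"]))
  expect_equal(root_met$pct_conserved,
               percent_of(root_met$n_conserved, 2, 1))

  # HC metabolic cell has exactly site 1 (all-S): fully conserved
  hc_met <- prof[prof$node == "A1" & prof$stratum == "HC" &
                   prof$partition == "metabolic", ]
  expect_equal(hc_met$pct_conserved, 100)

  # empty cells report NA, never zero
  info2 <- data.frame(metabolic = rep(FALSE, 4),
                      confidence = rep("ALL", 4))
  prof2 <- ancestor_conservation_profile(cs, info2)
  expect_true(all(is.na(prof2$pct_conserved[prof2$partition == "metabolic"])))
  # all-conserved scenario: 100 percent at every node
  cs_all <- reconstruct_ancestral(tr, leaf[c(1, 1), ])
  prof3 <- ancestor_conservation_profile(
    cs_all, data.frame(metabolic = c(TRUE, FALSE),
                       confidence = c("ALL", "ALL")))
  expect_true(all(prof3$pct_conserved[!is.na(prof3$pct_conserved)] == 100))
})

test_that("cross-species calls and candidate projection work on a hand fixture", {
  qprot <- c(Q1 = "MKSTAYSAAT")
  tprot <- c(T1 = "MKSTAYSAAT")  # identical ortholog
  qsites <- data.frame(protein_id = "Q1", position = c(3, 7),
                       htp_support = c(3, 1))
  tsites <- data.frame(protein_id = "T1", position = c(3, 4, 10),
                       htp_support = 3)
  qc <- compendium_from_sites(qsites, qprot)
  tc <- compendium_from_sites(tsites, tprot)
  orth <- data.frame(gene_a = "Q1", gene_b = "T1", evidence = "synteny")

  calls <- call_conservation(qc, tc, orth)
  expect_equal(calls$category[calls$position == 3], "phospho_conserved")
  expect_equal(calls$category[calls$position == 7], "residue_conserved")

  # candidates: target sites at 4 (T) and 10 (T) project onto query
  # positions absent from the query compendium; position 3 is already known
  cand <- project_candidate_sites(tc, qc, orth)
  expect_setequal(cand$position, c(4, 10))
  expect_false(3 %in% cand$position)

  # a target site homologous to a non-acceptor query residue is no candidate
  qprot2 <- c(Q1 = "MKSTAYAAAT")  # position 7 now A
  qc2 <- compendium_from_sites(qsites[1, ], qprot2)
  tc2 <- compendium_from_sites(data.frame(protein_id = "T1", position = 7,
                                          htp_support = 3),
                               c(T1 = "MKSTAYSAAT"))
  expect_equal(nrow(project_candidate_sites(tc2, qc2, orth)), 0)
})

test_that("pairwise and ancestral inference agree on identical-residue columns", {
  # an identically conserved, phosphorylated column is conserved under both
  qprot <- c(Q1 = "AASAA")
  tprot <- c(T1 = "AASAA")
  qc <- compendium_from_sites(data.frame(protein_id = "Q1", position = 3,
                                         htp_support = 3), qprot)
  tc <- compendium_from_sites(data.frame(protein_id = "T1", position = 3,
                                         htp_support = 3), tprot)
  calls <- call_conservation(qc, tc, data.frame(gene_a = "Q1", gene_b = "T1"))
  expect_equal(calls$category, "phospho_conserved")

  tr <- ape::read.tree(text = "(q:1,t:1);")
  cs <- reconstruct_ancestral(tr, c(q = "S", t = "S"))
  expect_true(cs$conserved[1, 1])
})
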