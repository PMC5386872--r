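#' Configuration for the synthetic-data generators
#'
#' One object holds every tunable of the simulated study. Defaults emulate
#' the structure of a multi-experiment yeast-scale phosphoproteomics study,
#' scaled to desk size: 20 HTP experiments whose per-experiment detection
#' probability (0.125) makes detected genuine sites split roughly 1:1
#' between high (3+) and low (1-2) experiment support, and - together with
#' the spurious sites, which almost all sit at support 1-2 - makes about
#' two thirds of all compendium sites low-support; spurious sites rarely
#' recur across experiments; a curated LTP subset sampled from the genuine sites;
#' a diverged ortholog proteome with tunable p-site retention and
#' serine/threonine interchange (default 0.12); log-normal protein
#' abundance, higher for phosphoproteins; and a random bipartite
#' gene-reaction model. See the package vignette for the reasoning behind
#' each default.
#'
#' A single master `seed` is expanded into independent named per-generator
#' streams (`derive_seed`), so invoking one generator never perturbs the
#' draws of another.
#'
#' @param seed master integer seed.
#' @param n_proteins number of proteins in the simulated proteome.
#' @param length_meanlog,length_sdlog,min_length log-normal protein length
#'   distribution (amino acids).
#' @param sty_freq named frequencies of S, T and Y in the proteome.
#' @param n_sites target number of unique p-sites in the compendium.
#' @param functional_fraction fraction of compendium sites that are genuine.
#' @param n_experiments number of HTP experiments.
#' @param detection_prob per-experiment detection probability of a genuine
#'   site (scalar or one value per experiment).
#' @param noisy_record_rate fraction of extra records emitted below the
#'   stringency thresholds (removed by filtering).
#' @param multi_match_rate fraction of extra records matching two proteins
#'   (removed by the uniqueness rule).
#' @param ltp_coverage fraction of genuine sites present in the curated LTP
#'   gold standard.
#' @param sub_prob per-residue substitution probability in the ortholog.
#' @param indel_rate per-residue probability of starting an indel.
#' @param indel_mean_len mean indel length (geometric-like, >= 1).
#' @param retention_prob probability that a genuine site is retained as
#'   phosphorylated in the ortholog species.
#' @param st_exchange_prob probability that a retained S/T site switches
#'   S <-> T.
#' @param target_extra_rate number of extra target-only p-sites (planted
#'   undiscovered query candidates), as a fraction of retained sites.
#' @param synteny_fraction fraction of ortholog pairs carrying synteny
#'   evidence (the rest are best hits).
#' @param n_species number of species in the simulated tree.
#' @param ancestral_retention per-branch probability that a site's
#'   phospho-acceptor residue survives.
#' @param abundance_meanlog10_phospho,abundance_meanlog10_negative,abundance_sdlog10
#'   log10-normal abundance parameters per group.
#' @param abundance_missing_frac fraction of abundance values missing.
#' @param ppi_lambda_phospho,ppi_lambda_negative Poisson means of
#'   protein-protein interaction counts.
#' @param kinase_lambda_phospho,kinase_lambda_negative Poisson means of
#'   kinase-target counts.
#' @param gi_lambda_phospho,gi_lambda_negative Poisson means of genetic
#'   interaction counts.
#' @param ubiq_prob_phospho,ubiq_prob_negative ubiquitination probabilities.
#' @param essential_prob_phospho,essential_prob_negative essentiality
#'   probabilities.
#' @param wgd_prob_phospho,wgd_prob_negative WGD-paralog probabilities.
#' @param halflife_meanlog_phospho,halflife_meanlog_negative,halflife_sdlog
#'   log-normal protein half-life (minutes).
#' @param disorder_frac_phospho,disorder_frac_negative expected disordered
#'   fraction of protein length.
#' @param domain_prob probability that a protein has an annotated domain.
#' @param n_phenotype_terms,phenotype_rate phenotype vocabulary size and
#'   per-protein annotation probability.
#' @param n_reactions,genes_per_reaction_mean,metabolic_fraction metabolic
#'   model size: reactions, mean genes per reaction, fraction of the
#'   proteome in the model.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1,
                       n_proteins = 400,
                       length_meanlog = log(420), length_sdlog = 0.4,
                       min_length = 60,
                       sty_freq = c(S = 0.085, T = 0.059, Y = 0.034),
                       n_sites = 3000,
                       functional_fraction = 0.66,
                       n_experiments = 20,
                       detection_prob = 0.125,
                       noisy_record_rate = 0.05,
                       multi_match_rate = 0.02,
                       ltp_coverage = 0.15,
                       sub_prob = 0.15,
                       indel_rate = 0.01,
                       indel_mean_len = 2,
                       retention_prob = 0.35,
                       st_exchange_prob = 0.12,
                       target_extra_rate = 0.15,
                       synteny_fraction = 0.9,
                       n_species = 6,
                       ancestral_retention = 0.9,
                       abundance_meanlog10_phospho = 3.55,
                       abundance_meanlog10_negative = 2.95,
                       abundance_sdlog10 = 0.55,
                       abundance_missing_frac = 0.1,
                       ppi_lambda_phospho = 1.2, ppi_lambda_negative = 0.5,
                       kinase_lambda_phospho = 1.2,
                       kinase_lambda_negative = 0.35,
                       gi_lambda_phospho = 2.0, gi_lambda_negative = 1.5,
                       ubiq_prob_phospho = 0.45, ubiq_prob_negative = 0.21,
                       essential_prob_phospho = 0.22,
                       essential_prob_negative = 0.15,
                       wgd_prob_phospho = 0.28, wgd_prob_negative = 0.19,
                       halflife_meanlog_phospho = log(40),
                       halflife_meanlog_negative = log(55),
                       halflife_sdlog = 0.8,
                       disorder_frac_phospho = 0.35,
                       disorder_frac_negative = 0.18,
                       domain_prob = 0.6,
                       n_phenotype_terms = 10, phenotype_rate = 0.2,
                       n_reactions = 150, genes_per_reaction_mean = 2.5,
                       metabolic_fraction = 0.15) {
  cfg <- as.list(environment())
  probs <- c(cfg$functional_fraction, cfg$detection_prob,
             cfg$noisy_record_rate, cfg$multi_match_rate, cfg$ltp_coverage,
             cfg$sub_prob, cfg$indel_rate, cfg$retention_prob,
             cfg$st_exchange_prob, cfg$synteny_fraction,
             cfg$ancestral_retention, cfg$abundance_missing_frac,
             cfg$ubiq_prob_phospho, cfg$ubiq_prob_negative,
             cfg$essential_prob_phospho, cfg$essential_prob_negative,
             cfg$wgd_prob_phospho, cfg$wgd_prob_negative, cfg$domain_prob,
             cfg$phenotype_rate, cfg$metabolic_fraction, unlist(sty_freq))
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities and fractions must lie in [0, 1]")
  }
  if (sum(sty_freq) >= 1) stop("sty_freq must sum to less than 1")
  if (cfg$length_sdlog <= 0 || cfg$abundance_sdlog10 <= 0) {
    stop("scale parameters must be positive")
  }
  if (cfg$indel_mean_len < 1) stop("indel_mean_len must be >= 1")
  structure(cfg, class = "sim_config")
}

.aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
           "Q", "R", "S", "T", "V", "W", "Y")

aa_probs <- function(sty_freq) {
  p <- rep((1 - sum(sty_freq)) / 17, 20)
  names(p) <- .aa20
  p[names(sty_freq)] <- sty_freq
  p
}

#' Generate a random proteome
#'
#' Residues are drawn i.i.d. with the configured S/T/Y composition (all
#' other amino acids share the remaining mass uniformly); lengths are
#' log-normal. Byte-identical output for a given config.
#'
#' @param config a `sim_config`.
#' @return named character vector of sequences (`P0001`, `P0002`, ...).
#' @export
gen_proteome <- function(config) {
  if (config$n_proteins == 0) return(stats::setNames(character(), character()))
  withr::with_seed(derive_seed(config$seed, "proteome"), {
    lens <- pmax(config$min_length,
                 round(stats::rlnorm(config$n_proteins, config$length_meanlog,
                                     config$length_sdlog)))
    p <- aa_probs(config$sty_freq)
    seqs <- vapply(lens, function(L) {
      paste(sample(.aa20, L, replace = TRUE, prob = p), collapse = "")
    }, "")
    stats::setNames(seqs, sprintf("P%04d", seq_len(config$n_proteins)))
  })
}

# All S/T/Y positions of a proteome as a data.frame.
sty_positions <- function(proteome) {
  per <- lapply(names(proteome), function(id) {
    ch <- strsplit(proteome[[id]], "")[[1]]
    pos <- which(ch %in% c("S", "T", "Y"))
    if (length(pos) == 0) return(NULL)
    data.frame(protein_id = id, position = pos, residue = ch[pos],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per)
  rownames(out) <- NULL
  out
}

#' Simulate per-experiment phosphopeptide records with planted truth
#'
#' Plants `functional_fraction * n_sites` genuine p-sites on S/T/Y residues.
#' Each genuine site is detected independently in each experiment with the
#' configured detection probability; each experiment additionally reports
#' spurious sites drawn from the remaining S/T/Y positions at a rate sized
#' so the expected number of distinct spurious sites is
#' `(1 - functional_fraction) * n_sites` (individual spurious sites rarely
#' recur across experiments). Passing records carry identification and
#' localization probabilities above 0.99; configurable fractions of
#' low-localization and multi-protein records are added to exercise the
#' stringency filters. An LTP gold-standard subset is sampled from the
#' genuine sites at `ltp_coverage`, independently of detection.
#'
#' @param proteome named character vector from [gen_proteome()].
#' @param config a `sim_config`.
#' @return list with `records` (all experiments, filter-ready), `ltp`
#'   (gold-standard data.frame), and `truth` (list: `true_keys`,
#'   `spurious_keys`, `ltp_keys`, `true_sites` data.frame, seed).
#' @export
simulate_phospho_experiments <- function(proteome, config) {
  sty <- sty_positions(proteome)
  n_true <- round(config$functional_fraction * config$n_sites)
  if (is.null(sty) || nrow(sty) < config$n_sites) {
    stop("proteome has too few S/T/Y positions for the requested n_sites")
  }
  m <- config$n_experiments
  det <- rep_len(config$detection_prob, m)

  withr::with_seed(derive_seed(config$seed, "phospho"), {
    idx_true <- sample(nrow(sty), n_true)
    true_sites <- sty[idx_true, , drop = FALSE]
    decoy <- sty[-idx_true, , drop = FALSE]
    true_key <- site_key(true_sites$protein_id, true_sites$position)

    n_spurious_total <- round((1 - config$functional_fraction) *
                                config$n_sites)
    spur_per_exp <- ceiling(n_spurious_total / m)

    recs <- vector("list", m)
    spurious_seen <- character()
    for (e in seq_len(m)) {
      eid <- sprintf("e%02d", e)
      hit <- stats::rbinom(n_true, 1, det[e]) == 1
      tt <- true_sites[hit, , drop = FALSE]
      sp <- decoy[sample(nrow(decoy), spur_per_exp), , drop = FALSE]
      spurious_seen <- union(spurious_seen,
                             site_key(sp$protein_id, sp$position))
      good <- rbind(tt, sp)
      n_good <- nrow(good)
      rec <- data.frame(
        experiment_id = eid,
        protein_id = good$protein_id, position = good$position,
        residue = good$residue,
        id_prob = stats::runif(n_good, 0.991, 1),
        loc_prob = stats::runif(n_good, 0.991, 1),
        n_matches = 1L, stringsAsFactors = FALSE
      )
      n_noisy <- round(config$noisy_record_rate * n_good)
      if (n_noisy > 0) {
        nz <- sty[sample(nrow(sty), n_noisy), , drop = FALSE]
        rec <- rbind(rec, data.frame(
          experiment_id = eid, protein_id = nz$protein_id,
          position = nz$position, residue = nz$residue,
          id_prob = stats::runif(n_noisy, 0.991, 1),
          loc_prob = stats::runif(n_noisy, 0.3, 0.985),
          n_matches = 1L, stringsAsFactors = FALSE
        ))
      }
      n_multi <- round(config$multi_match_rate * n_good)
      if (n_multi > 0) {
        mm <- sty[sample(nrow(sty), n_multi), , drop = FALSE]
        rec <- rbind(rec, data.frame(
          experiment_id = eid, protein_id = mm$protein_id,
          position = mm$position, residue = mm$residue,
          id_prob = stats::runif(n_multi, 0.991, 1),
          loc_prob = stats::runif(n_multi, 0.991, 1),
          n_matches = 2L, stringsAsFactors = FALSE
        ))
      }
      recs[[e]] <- rec
    }
    records <- do.call(rbind, recs)
    rownames(records) <- NULL

    n_ltp <- round(config$ltp_coverage * n_true)
    ltp_idx <- sample(n_true, n_ltp)
    ltp <- true_sites[ltp_idx, c("protein_id", "position", "residue")]
    rownames(ltp) <- NULL

    list(
      records = records, ltp = ltp,
      truth = list(
        true_keys = true_key,
        spurious_keys = spurious_seen,
        ltp_keys = site_key(ltp$protein_id, ltp$position),
        true_sites = true_sites,
        functional_fraction = config$functional_fraction,
        seed = config$seed
      )
    )
  })
}

#' Generate a diverged ortholog species with planted homology truth
#'
#' Evolves each query protein into an ortholog: residues substitute with
#' probability `sub_prob`, indels start with probability `indel_rate` (mean
#' length `indel_mean_len`), and the true homologous-position map is
#' recorded. A `retention_prob` fraction of the genuine query p-sites is
#' retained as phosphorylated in the ortholog; retained positions are
#' protected from substitution and deletion except that retained S/T sites
#' switch S <-> T with probability `st_exchange_prob` (planted
#' interchanges). Extra target-only p-sites are planted at positions whose
#' query homolog is an unphosphorylated S/T/Y, as ground truth for
#' candidate-site projection.
#'
#' @param proteome query proteome (named character vector).
#' @param true_sites data.frame of genuine query sites (`protein_id`,
#'   `position`, `residue`).
#' @param query_site_keys character keys of every site in the *query
#'   compendium* (detected sites), used to place candidate sites outside it.
#' @param config a `sim_config`.
#' @return list with `target_proteome`, `target_sites` (target-species site
#'   table: `protein_id`, `position`, `residue`, `htp_support`), `synteny`
#'   and `best_hit` ortholog tables, and `truth` (per-protein `homolog_map`
#'   integer vectors with NA for deleted positions, `indel_positions`
#'   per protein, `retained` data.frame with `interchange` flags, and
#'   `candidates` data.frame of planted undiscovered query sites).
#' @export
gen_ortholog_species <- function(proteome, true_sites, query_site_keys,
                                 config) {
  withr::with_seed(derive_seed(config$seed, "ortholog"), {
    n_true <- nrow(true_sites)
    retained_flag <- stats::runif(n_true) < config$retention_prob
    retained <- true_sites[retained_flag, , drop = FALSE]
    ret_by_prot <- split(retained$position, retained$protein_id)

    p_bg <- aa_probs(config$sty_freq)
    target_seqs <- character(length(proteome))
    names(target_seqs) <- names(proteome)
    homolog_map <- vector("list", length(proteome))
    names(homolog_map) <- names(proteome)
    indel_positions <- vector("list", length(proteome))
    names(indel_positions) <- names(proteome)
    interchange_key <- character()

    for (id in names(proteome)) {
      ch <- strsplit(proteome[[id]], "")[[1]]
      L <- length(ch)
      prot <- ret_by_prot[[id]]
      protected <- logical(L)
      if (!is.null(prot)) protected[prot] <- TRUE

      # deletions: geometric-length runs started at unprotected positions
      del <- logical(L)
      starts <- which(stats::runif(L) < config$indel_rate / 2 & !protected)
      for (s0 in starts) {
        len <- 1 + stats::rpois(1, config$indel_mean_len - 1)
        run <- s0:min(L, s0 + len - 1)
        run <- run[!protected[run]]
        if (length(run) > 1 && any(diff(run) > 1)) {
          run <- run[seq_len(which(diff(run) > 1)[1])]  # stop at protection
        }
        del[run] <- TRUE
      }

      # substitutions / S<->T interchange on the surviving positions
      new <- ch
      sub <- stats::runif(L) < config$sub_prob & !protected & !del
      if (any(sub)) {
        new[sub] <- vapply(new[sub], function(r) {
          sample(setdiff(.aa20, r), 1, prob = p_bg[setdiff(.aa20, r)])
        }, "")
      }
      if (!is.null(prot)) {
        st <- prot[ch[prot] %in% c("S", "T")]
        swap <- st[stats::runif(length(st)) < config$st_exchange_prob]
        if (length(swap) > 0) {
          new[swap] <- ifelse(ch[swap] == "S", "T", "S")
          interchange_key <- c(interchange_key, site_key(id, swap))
        }
      }

      # insertions after unprotected surviving positions
      keep <- which(!del)
      ins_after <- integer(length(keep))
      ins_here <- stats::runif(length(keep)) < config$indel_rate / 2 &
        !protected[keep]
      ins_after[ins_here] <- 1 + stats::rpois(sum(ins_here),
                                              config$indel_mean_len - 1)

      tpos <- seq_along(keep) + c(0, cumsum(ins_after)[-length(keep)])
      qmap <- rep(NA_integer_, L)
      qmap[keep] <- as.integer(tpos)

      pieces <- character(length(keep))
      for (i in seq_along(keep)) {
        extra <- if (ins_after[i] > 0) {
          paste(sample(.aa20, ins_after[i], replace = TRUE, prob = p_bg),
                collapse = "")
        } else ""
        pieces[i] <- paste0(new[keep[i]], extra)
      }
      target_seqs[id] <- paste(pieces, collapse = "")
      homolog_map[[id]] <- qmap
      edges <- sort(unique(c(which(del),
                             keep[ins_after > 0], keep[ins_after > 0] + 1)))
      indel_positions[[id]] <- edges[edges >= 1 & edges <= L]
    }
    names(target_seqs) <- paste0("O_", names(proteome))

    # retained sites, mapped to target coordinates
    if (nrow(retained) > 0) {
      ret_tpos <- mapply(function(p, pos) homolog_map[[p]][pos],
                         retained$protein_id, retained$position)
      ret_res <- mapply(function(p, t) substr(target_seqs[[paste0("O_", p)]],
                                              t, t),
                        retained$protein_id, ret_tpos)
    } else {
      ret_tpos <- integer()
      ret_res <- character()
    }
    target_sites <- data.frame(
      protein_id = if (nrow(retained) > 0) {
        paste0("O_", retained$protein_id)
      } else character(),
      position = as.integer(ret_tpos), residue = as.character(ret_res),
      htp_support = rep(3L, nrow(retained)), stringsAsFactors = FALSE
    )

    # planted target-only sites = undiscovered query candidates
    n_extra <- round(config$target_extra_rate * nrow(retained))
    cand <- NULL
    if (n_extra > 0) {
      pools <- lapply(names(proteome), function(id) {
        ch <- strsplit(proteome[[id]], "")[[1]]
        qm <- homolog_map[[id]]
        tseq <- target_seqs[[paste0("O_", id)]]
        qpos <- which(ch %in% c("S", "T", "Y") & !is.na(qm))
        if (length(qpos) == 0) return(NULL)
        tres <- substr(rep(tseq, length(qpos)), qm[qpos], qm[qpos])
        ok <- tres %in% c("S", "T", "Y") &
          !(site_key(id, qpos) %in% query_site_keys)
        if (!any(ok)) return(NULL)
        data.frame(protein_id = id, position = qpos[ok],
                   residue = ch[qpos[ok]], target_position = qm[qpos][ok],
                   target_residue = tres[ok], stringsAsFactors = FALSE)
      })
      pool <- do.call(rbind, pools)
      # avoid positions already emitted as retained target sites
      tkey <- site_key(paste0("O_", pool$protein_id), pool$target_position)
      pool <- pool[!(tkey %in% site_key(target_sites$protein_id,
                                        target_sites$position)), ,
                   drop = FALSE]
      n_extra <- min(n_extra, nrow(pool))
      cand <- pool[sample(nrow(pool), n_extra), , drop = FALSE]
      rownames(cand) <- NULL
      target_sites <- rbind(target_sites, data.frame(
        protein_id = paste0("O_", cand$protein_id),
        position = cand$target_position, residue = cand$target_residue,
        htp_support = 3L, stringsAsFactors = FALSE
      ))
    }

    # ortholog evidence tables: mostly synteny, remainder best hits
    ids <- names(proteome)
    is_syn <- stats::runif(length(ids)) < config$synteny_fraction
    synteny <- data.frame(gene_a = ids[is_syn],
                          gene_b = paste0("O_", ids[is_syn]),
                          stringsAsFactors = FALSE)
    best_hit <- data.frame(gene_a = ids[!is_syn],
                           gene_b = paste0("O_", ids[!is_syn]),
                           score = round(stats::runif(sum(!is_syn), 100, 900)),
                           stringsAsFactors = FALSE)

    retained$target_position <- as.integer(ret_tpos)
    retained$interchange <- site_key(retained$protein_id,
                                     retained$position) %in% interchange_key
    rownames(retained) <- NULL

    # retained sites absent from the query compendium (e.g. never detected)
    # are also genuine candidate projections, alongside the planted extras
    undet <- retained[!site_key(retained$protein_id, retained$position) %in%
                        query_site_keys, , drop = FALSE]
    if (nrow(undet) > 0) {
      undet_res <- mapply(function(p, t) {
        substring(target_seqs[[paste0("O_", p)]], t, t)
      }, undet$protein_id, undet$target_position)
      undet_cand <- data.frame(
        protein_id = undet$protein_id, position = undet$position,
        residue = undet$residue, target_position = undet$target_position,
        target_residue = as.character(undet_res), stringsAsFactors = FALSE
      )
      cand <- rbind(cand, undet_cand)
    }
    if (!is.null(cand)) rownames(cand) <- NULL

    list(
      target_proteome = target_seqs,
      target_sites = target_sites,
      synteny = synteny, best_hit = best_hit,
      truth = list(homolog_map = homolog_map,
                   indel_positions = indel_positions,
                   retained = retained, candidates = cand,
                   seed = config$seed)
    )
  })
}

#' Generate a random rooted species tree with named ancestors
#'
#' @param config a `sim_config` (`n_species` tips).
#' @return a rooted `phylo` with tip labels `sp1..spN` and internal node
#'   labels `A1..A(N-1)`.
#' @export
gen_species_tree <- function(config) {
  withr::with_seed(derive_seed(config$seed, "tree"), {
    tr <- ape::rtree(config$n_species, tip.label =
                       paste0("sp", seq_len(config$n_species)))
    tr$node.label <- paste0("A", seq_len(tr$Nnode))
    tr
  })
}

#' Simulate phospho-acceptor retention of sites along a species tree
#'
#' Each site starts present at the root with its query residue; along every
#' branch it survives with probability `ancestral_retention`, and once lost
#' it stays lost (the residue becomes a random non-acceptor amino acid).
#' The true presence state at every internal node is recorded, giving
#' ground truth for ancestral-reconstruction estimators.
#'
#' @param tree rooted `phylo` (see [gen_species_tree()]).
#' @param site_residues character vector of root residues (S/T/Y), one per
#'   site.
#' @param config a `sim_config`.
#' @return list with `leaf_states` (sites x tips residue matrix),
#'   `node_presence` (sites x internal-nodes logical matrix, TRUE = the
#'   acceptor residue survives at that ancestor) and `node_labels`.
#' @export
gen_ancestral_scenario <- function(tree, site_residues, config) {
  q <- config$ancestral_retention
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  n_sites <- length(site_residues)
  non_sty <- setdiff(.aa20, c("S", "T", "Y"))

  tree <- stats::reorder(tree, "cladewise")  # parents precede children
  withr::with_seed(derive_seed(config$seed, "ancestral"), {
    pres <- matrix(FALSE, n_sites, n_tip + n_node)
    pres[, n_tip + 1] <- TRUE  # root
    for (e in seq_len(nrow(tree$edge))) {
      parent <- tree$edge[e, 1]
      child <- tree$edge[e, 2]
      survive <- stats::runif(n_sites) < q
      pres[, child] <- pres[, parent] & survive
    }
    leaf_states <- matrix(NA_character_, n_sites, n_tip,
                          dimnames = list(NULL, tree$tip.label))
    for (t in seq_len(n_tip)) {
      lost <- !pres[, t]
      leaf_states[, t] <- site_residues
      if (any(lost)) {
        leaf_states[lost, t] <- sample(non_sty, sum(lost), replace = TRUE)
      }
    }
    node_labels <- if (!is.null(tree$node.label)) tree$node.label else {
      paste0("N", seq_len(n_node) + n_tip)
    }
    node_presence <- pres[, n_tip + seq_len(n_node), drop = FALSE]
    colnames(node_presence) <- node_labels
    list(leaf_states = leaf_states, node_presence = node_presence,
         node_labels = node_labels)
  })
}

#' Generate a per-protein feature table with planted group effects
#'
#' Phosphoproteins receive higher log-normal abundance, more interactions
#' and higher ubiquitination/WGD rates than background proteins, per the
#' config; a configurable fraction of abundance values is missing at
#' random. Protein length is taken from the proteome.
#'
#' @param proteome named character vector of sequences.
#' @param phospho_ids character vector of phosphoprotein ids.
#' @param config a `sim_config`.
#' @return data.frame with one row per protein: `protein_id`, `abundance`,
#'   `half_life`, `essential`, `ubiquitinated`, `ppi_count`,
#'   `genetic_interaction_count`, `kinase_target_count`, `length`,
#'   `disorder_length`, `wgd_paralog`.
#' @export
gen_feature_table <- function(proteome, phospho_ids, config) {
  ids <- names(proteome)
  n <- length(ids)
  is_p <- ids %in% phospho_ids
  pick <- function(p_val, n_val) ifelse(is_p, p_val, n_val)

  withr::with_seed(derive_seed(config$seed, "features"), {
    abund <- 10^stats::rnorm(n, pick(config$abundance_meanlog10_phospho,
                                     config$abundance_meanlog10_negative),
                             config$abundance_sdlog10)
    abund[stats::runif(n) < config$abundance_missing_frac] <- NA
    len <- nchar(proteome)
    data.frame(
      protein_id = ids,
      abundance = abund,
      half_life = stats::rlnorm(n, pick(config$halflife_meanlog_phospho,
                                        config$halflife_meanlog_negative),
                                config$halflife_sdlog),
      essential = stats::runif(n) < pick(config$essential_prob_phospho,
                                         config$essential_prob_negative),
      ubiquitinated = stats::runif(n) < pick(config$ubiq_prob_phospho,
                                             config$ubiq_prob_negative),
      ppi_count = stats::rpois(n, pick(config$ppi_lambda_phospho,
                                       config$ppi_lambda_negative)),
      genetic_interaction_count = stats::rpois(n,
                                               pick(config$gi_lambda_phospho,
                                                    config$gi_lambda_negative)),
      kinase_target_count = stats::rpois(n,
                                         pick(config$kinase_lambda_phospho,
                                              config$kinase_lambda_negative)),
      length = unname(len),
      disorder_length = stats::rbinom(n, unname(len),
                                      pick(config$disorder_frac_phospho,
                                           config$disorder_frac_negative)),
      wgd_paralog = stats::runif(n) < pick(config$wgd_prob_phospho,
                                           config$wgd_prob_negative),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate random domain intervals for a proteome
#'
#' Each protein carries one domain with probability `domain_prob`; the
#' interval is uniform within the sequence, 1-based inclusive.
#'
#' @param proteome named character vector.
#' @param config a `sim_config`.
#' @return data.frame (`protein_id`, `start`, `end`, `domain_name`).
#' @export
gen_domains <- function(proteome, config) {
  withr::with_seed(derive_seed(config$seed, "phenotype") + 50L, {
    has <- stats::runif(length(proteome)) < config$domain_prob
    ids <- names(proteome)[has]
    lens <- nchar(proteome[has])
    width <- pmax(20L, round(lens * stats::runif(length(ids), 0.15, 0.4)))
    start <- pmax(1L, 1L + floor(stats::runif(length(ids)) *
                                   pmax(1, lens - width)))
    data.frame(protein_id = ids, start = as.integer(start),
               end = as.integer(pmin(lens, start + width - 1L)),
               domain_name = paste0("DOM_", seq_along(ids)),
               stringsAsFactors = FALSE)
  })
}

#' Generate a random protein-phenotype annotation map
#'
#' @param proteome named character vector.
#' @param config a `sim_config`.
#' @return data.frame (`protein_id`, `term`).
#' @export
gen_phenotypes <- function(proteome, config) {
  withr::with_seed(derive_seed(config$seed, "phenotype"), {
    ids <- names(proteome)
    terms <- paste0("phenotype_", seq_len(config$n_phenotype_terms))
    hit <- stats::runif(length(ids)) < config$phenotype_rate
    annotated <- ids[hit]
    n_terms <- 1 + stats::rpois(length(annotated), 0.4)
    do.call(rbind, lapply(seq_along(annotated), function(i) {
      data.frame(protein_id = annotated[i],
                 term = sample(terms, min(n_terms[i], length(terms))),
                 stringsAsFactors = FALSE)
    }))
  })
}

#' Generate a random bipartite gene-reaction association table
#'
#' A `metabolic_fraction` of the proteome becomes the model gene set; each
#' reaction draws `1 + Poisson(genes_per_reaction_mean - 1)` genes without
#' replacement. Reproducible from the config seed.
#'
#' @param proteome named character vector (gene universe).
#' @param config a `sim_config`.
#' @return data.frame (`reaction_id`, `gene_id`).
#' @export
gen_metabolic_model <- function(proteome, config) {
  withr::with_seed(derive_seed(config$seed, "metabolic"), {
    genes <- sample(names(proteome),
                    max(2, round(config$metabolic_fraction *
                                   length(proteome))))
    k <- 1 + stats::rpois(config$n_reactions,
                          config$genes_per_reaction_mean - 1)
    k <- pmin(k, length(genes))
    do.call(rbind, lapply(seq_len(config$n_reactions), function(r) {
      data.frame(reaction_id = sprintf("r%03d", r),
                 gene_id = sample(genes, k[r]), stringsAsFactors = FALSE)
    }))
  })
}
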