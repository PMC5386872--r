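#' Resolve ortholog pairs from synteny and best-hit evidence
#'
#' Synteny-derived pairs take precedence; best-hit pairs fill in only the
#' query genes absent from the synteny table. Conflicting synteny
#' assignments for one query gene are an error. Among equal-score best hits
#' the lexicographically smaller partner wins (deterministic tie-break).
#'
#' @param synteny data.frame with `gene_a`, `gene_b` (synteny-supported
#'   pairs); may be NULL or empty.
#' @param best_hit data.frame with `gene_a`, `gene_b` and optionally
#'   `score`; may be NULL or empty.
#' @return data.frame (`gene_a`, `gene_b`, `evidence`), one row per
#'   `gene_a`, sorted by `gene_a`.
#' @export
resolve_orthologs <- function(synteny = NULL, best_hit = NULL) {
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      evidence = character(), stringsAsFactors = FALSE)
  out <- empty
  if (!is.null(synteny) && nrow(synteny) > 0) {
    syn <- unique(data.frame(gene_a = as.character(synteny$gene_a),
                             gene_b = as.character(synteny$gene_b),
                             stringsAsFactors = FALSE))
    dup <- unique(syn$gene_a[duplicated(syn$gene_a)])
    if (length(dup) > 0) {
      stop("conflicting synteny pairs for gene(s): ",
           paste(utils::head(dup, 10), collapse = ", "))
    }
    syn$evidence <- "synteny"
    out <- syn
  }
  if (!is.null(best_hit) && nrow(best_hit) > 0) {
    bh <- data.frame(gene_a = as.character(best_hit$gene_a),
                     gene_b = as.character(best_hit$gene_b),
                     score = if ("score" %in% names(best_hit)) {
                       as.numeric(best_hit$score)
                     } else 0,
                     stringsAsFactors = FALSE)
    bh <- bh[!(bh$gene_a %in% out$gene_a), , drop = FALSE]
    bh <- bh[order(bh$gene_a, -bh$score, bh$gene_b), , drop = FALSE]
    bh <- bh[!duplicated(bh$gene_a), , drop = FALSE]
    if (nrow(bh) > 0) {
      bh$evidence <- "best_hit"
      out <- rbind(out, bh[, c("gene_a", "gene_b", "evidence")])
    }
  }
  out <- out[order(out$gene_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Substitution matrix with the ambiguity code X scored as neutral (0).
resolve_submat <- function(substitution_matrix) {
  if (is.character(substitution_matrix)) {
    e <- new.env()
    utils::data(list = substitution_matrix, package = "Biostrings", envir = e)
    substitution_matrix <- get(substitution_matrix, envir = e)
  }
  if ("X" %in% rownames(substitution_matrix)) {
    substitution_matrix["X", ] <- 0
    substitution_matrix[, "X"] <- 0
  }
  substitution_matrix
}

#' Optimal global pairwise protein alignment with affine gaps
#'
#' Needleman-Wunsch-style global alignment with affine gap penalties
#' (a gap of length L costs `gap_open + L * gap_extend`) and terminal gaps
#' penalized. Defaults are BLOSUM62 scores with open 10 / extend 1; the
#' ambiguity residue X is scored as neutral (0 against everything).
#' Alignment is delegated to [Biostrings::pairwiseAlignment()]; the result
#' is repackaged as an explicit residue-level position map.
#'
#' @param seq_a,seq_b non-empty amino-acid sequences (single strings).
#' @param substitution_matrix a score matrix or the name of one shipped with
#'   Biostrings (default `"BLOSUM62"`).
#' @param gap_open,gap_extend affine gap parameters (positive costs).
#' @return an object of class `alignment_map`: list with gapped strings
#'   `aligned_a`, `aligned_b`, the integer map `a_to_b` (1-based position in
#'   A to position in B, NA where A aligns to a gap), `b_to_a`, and `score`.
#' @export
#' @examples
#' m <- align_global("ACDEFG", "ACEFG")
#' m$a_to_b  # position 3 (D) maps to NA, the rest shift by one
align_global <- function(seq_a, seq_b, substitution_matrix = "BLOSUM62",
                         gap_open = 10, gap_extend = 1) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) {
    stop("sequences must be non-empty")
  }
  mat <- resolve_submat(substitution_matrix)
  pa <- Biostrings::pairwiseAlignment(
    pattern = seq_a, subject = seq_b, type = "global",
    substitutionMatrix = mat, gapOpening = gap_open, gapExtension = gap_extend
  )
  alignment_map_from_strings(
    as.character(Biostrings::alignedPattern(pa)),
    as.character(Biostrings::alignedSubject(pa)),
    score = Biostrings::score(pa)
  )
}

# Build the position maps from a pair of equal-length gapped strings.
alignment_map_from_strings <- function(aligned_a, aligned_b, score = NA_real_) {
  ca <- strsplit(aligned_a, "")[[1]]
  cb <- strsplit(aligned_b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  pa <- cumsum(ca != "-")
  pb <- cumsum(cb != "-")
  a_to_b <- ifelse(cb[ca != "-"] == "-", NA_integer_, pb[ca != "-"])
  b_to_a <- ifelse(ca[cb != "-"] == "-", NA_integer_, pa[cb != "-"])
  structure(
    list(aligned_a = aligned_a, aligned_b = aligned_b,
         a_to_b = as.integer(a_to_b), b_to_a = as.integer(b_to_a),
         score = score),
    class = "alignment_map"
  )
}

#' Align many ortholog pairs in one call
#'
#' Vectorized wrapper around the same aligner used by [align_global()],
#' returning one `alignment_map` per pair.
#'
#' @param seqs_a,seqs_b character vectors of equal length.
#' @inheritParams align_global
#' @return named list of `alignment_map` objects (names from `seqs_a`).
#' @export
align_global_many <- function(seqs_a, seqs_b,
                              substitution_matrix = "BLOSUM62",
                              gap_open = 10, gap_extend = 1) {
  stopifnot(length(seqs_a) == length(seqs_b))
  if (length(seqs_a) == 0) return(list())
  mat <- resolve_submat(substitution_matrix)
  pa <- Biostrings::pairwiseAlignment(
    pattern = seqs_a, subject = seqs_b, type = "global",
    substitutionMatrix = mat, gapOpening = gap_open, gapExtension = gap_extend
  )
  as_ <- as.character(Biostrings::alignedPattern(pa))
  bs_ <- as.character(Biostrings::alignedSubject(pa))
  sc <- Biostrings::score(pa)
  out <- lapply(seq_along(seqs_a), function(i) {
    alignment_map_from_strings(as_[i], bs_[i], sc[i])
  })
  names(out) <- names(seqs_a)
  out
}

#' @export
print.alignment_map <- function(x, ...) {
  cat("global alignment, score", x$score, "\n")
  cat("  A:", substr(x$aligned_a, 1, 60), "\n")
  cat("  B:", substr(x$aligned_b, 1, 60), "\n")
  invisible(x)
}

#' Map a residue position through an alignment
#'
#' @param alignment an `alignment_map`.
#' @param position 1-based position(s) in the ungapped A sequence.
#' @return integer vector of homologous 1-based positions in B; `NA` where
#'   the position falls in a B gap.
#' @export
map_site <- function(alignment, position) {
  n <- length(alignment$a_to_b)
  if (any(position < 1 | position > n)) {
    stop("position out of range 1..", n)
  }
  alignment$a_to_b[position]
}

#' Classify the conservation fate of a p-site in an ortholog
#'
#' Categories partition the classified sites:
#' \describe{
#'   \item{phospho_conserved}{the homologous position is phosphorylated in
#'     the target compendium (same phospho-acceptor residue, or S vs Y etc).}
#'   \item{interchange_ST}{phospho-conserved, but the acceptor switched
#'     between serine and threonine across the two species.}
#'   \item{residue_conserved}{the homologous residue is S/T/Y but carries no
#'     phosphorylation evidence in the target.}
#'   \item{not_conserved}{the homologous residue is neither S, T nor Y, or
#'     the site falls in an alignment gap.}
#' }
#'
#' @param site_residue character vector of query residues (S/T/Y).
#' @param target_residue character vector of homologous target residues;
#'   `NA` or `"-"` marks an alignment gap.
#' @param target_phospho logical vector: is the homologous position
#'   phosphorylated in the target compendium?
#' @return character vector of categories.
#' @export
#' @examples
#' classify_site_conservation("S", "T", TRUE)   # "interchange_ST"
#' classify_site_conservation("S", "S", FALSE)  # "residue_conserved"
classify_site_conservation <- function(site_residue, target_residue,
                                       target_phospho) {
  stopifnot(all(site_residue %in% c("S", "T", "Y")))
  n <- max(length(site_residue), length(target_residue))
  site_residue <- rep_len(site_residue, n)
  target_residue <- rep_len(target_residue, n)
  target_phospho <- rep_len(as.logical(target_phospho), n)

  gap <- is.na(target_residue) | target_residue == "-"
  sty <- !gap & target_residue %in% c("S", "T", "Y")
  phos <- sty & target_phospho
  swap <- phos & site_residue != target_residue &
    site_residue %in% c("S", "T") & target_residue %in% c("S", "T")

  out <- rep("not_conserved", n)
  out[sty] <- "residue_conserved"
  out[phos] <- "phospho_conserved"
  out[swap] <- "interchange_ST"
  out
}

#' Project a query compendium onto a target species and classify every site
#'
#' Runs the pairwise comparative pipeline: for each query protein with an
#' ortholog, globally align the two sequences, map every query p-site to its
#' homologous target position, and classify its conservation against the
#' target compendium. Query proteins without an ortholog are excluded (their
#' sites do not appear in the output, and so never enter profile
#' denominators).
#'
#' @param query_compendium,target_compendium `phos_compendium` objects; the
#'   target's proteome must contain the ortholog partners.
#' @param orthologs data.frame from [resolve_orthologs()] with `gene_a`
#'   (query protein id) and `gene_b` (target protein id).
#' @inheritParams align_global
#' @return data.frame of conservation calls: `protein_id`, `position`,
#'   `residue`, `confidence`, `target_gene`, `target_position`,
#'   `target_residue`, `category`.
#' @export
call_conservation <- function(query_compendium, target_compendium, orthologs,
                              substitution_matrix = "BLOSUM62",
                              gap_open = 10, gap_extend = 1) {
  qs <- query_compendium$sites
  orth <- orthologs[orthologs$gene_a %in% qs$protein_id &
                      orthologs$gene_a %in% names(query_compendium$proteome) &
                      orthologs$gene_b %in% names(target_compendium$proteome), ,
                    drop = FALSE]
  if (nrow(orth) == 0) {
    return(data.frame(protein_id = character(), position = integer(),
                      residue = character(), confidence = character(),
                      target_gene = character(), target_position = integer(),
                      target_residue = character(), category = character(),
                      stringsAsFactors = FALSE))
  }
  alns <- align_global_many(
    stats::setNames(query_compendium$proteome[orth$gene_a], orth$gene_a),
    target_compendium$proteome[orth$gene_b],
    substitution_matrix, gap_open, gap_extend
  )
  tkey <- site_key(target_compendium$sites$protein_id,
                   target_compendium$sites$position)

  per_prot <- lapply(seq_len(nrow(orth)), function(i) {
    qa <- orth$gene_a[i]
    qb <- orth$gene_b[i]
    rows <- qs[qs$protein_id == qa, , drop = FALSE]
    tp <- map_site(alns[[qa]], rows$position)
    tres <- ifelse(is.na(tp), NA_character_,
                   substring(target_compendium$proteome[[qb]], tp, tp))
    tphos <- !is.na(tp) & site_key(qb, tp) %in% tkey
    data.frame(
      protein_id = rows$protein_id, position = rows$position,
      residue = rows$residue, confidence = rows$confidence,
      target_gene = qb, target_position = tp, target_residue = tres,
      category = classify_site_conservation(rows$residue, tres, tphos),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, per_prot)
  rownames(out) <- NULL
  out
}

#' Ancestral phospho-acceptor state reconstruction over a species tree
#'
#' Given the residues observed at the homologous position of one or more
#' p-sites across extant species, infers the residue state at every internal
#' node (ancestor) of a rooted species tree.
#'
#' `method = "parsimony"` runs unit-cost Sankoff dynamic programming, whose
#' per-node sets of minimal-cost states coincide with Fitch bottom-up state
#' sets on binary trees and generalize them to multifurcations. A node's
#' `conserved` flag is optimistic: TRUE when its minimal-cost state set
#' intersects \{S, T, Y\}. The deterministically resolved single state is the
#' alphabetically smallest member of the set. The minimum number of residue
#' changes per site is returned as `changes`.
#'
#' `method = "ml"` performs marginal maximum-likelihood reconstruction under
#' an equal-rates substitution model with the tree's branch lengths fixed
#' (via [ape::ace()]); it requires a binary tree and rejects polytomies.
#' Missing leaves are dropped before fitting and pruned-tree nodes are
#' mapped back to the original node labels.
#'
#' @param tree a rooted `phylo` tree whose tips are species; internal nodes
#'   are addressed by `tree$node.label` when present, otherwise as
#'   `"N<number>"`.
#' @param leaf_states a character matrix (sites x species, colnames = tip
#'   labels) of observed residues, or a named vector for a single site.
#'   `NA` marks a missing observation, which contributes no information.
#' @param method `"parsimony"` (default) or `"ml"`.
#' @return an object of class `ancestral_callset`: list with `tree`,
#'   `method`, `node_labels`, `states` (sites x nodes resolved states),
#'   `state_sets` (parsimony only; list of per-site lists), `conserved`
#'   (logical sites x nodes matrix) and `changes` (parsimony only).
#' @export
reconstruct_ancestral <- function(tree, leaf_states,
                                  method = c("parsimony", "ml")) {
  method <- match.arg(method)
  if (is.null(dim(leaf_states))) {
    leaf_states <- matrix(leaf_states, nrow = 1,
                          dimnames = list(NULL, names(leaf_states)))
  }
  if (is.null(colnames(leaf_states)) ||
      !all(tree$tip.label %in% colnames(leaf_states))) {
    stop("leaf_states must have one named column per tree tip")
  }
  leaf_states <- leaf_states[, tree$tip.label, drop = FALSE]
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  node_labels <- if (!is.null(tree$node.label) &&
                     all(nzchar(tree$node.label))) {
    tree$node.label
  } else {
    paste0("N", seq_len(n_node) + n_tip)
  }

  if (method == "parsimony") {
    res <- sankoff_sets(tree, leaf_states)
  } else {
    if (!ape::is.binary(tree)) {
      stop("ml reconstruction requires a fully resolved (binary) tree; ",
           "resolve polytomies or use method = \"parsimony\"")
    }
    res <- ml_states(tree, leaf_states)
  }
  colnames(res$states) <- node_labels
  colnames(res$conserved) <- node_labels
  structure(
    list(tree = tree, method = method, node_labels = node_labels,
         states = res$states, state_sets = res$state_sets,
         conserved = res$conserved, changes = res$changes),
    class = "ancestral_callset"
  )
}

# Unit-cost Sankoff over all sites; handles multifurcations and missing
# leaves (zero cost vector = no information).
sankoff_sets <- function(tree, leaf_states) {
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  tr <- stats::reorder(tree, "postorder")
  edge <- tr$edge
  n_sites <- nrow(leaf_states)

  states_out <- matrix(NA_character_, n_sites, n_node)
  conserved_out <- matrix(FALSE, n_sites, n_node)
  changes <- numeric(n_sites)
  state_sets <- vector("list", n_sites)

  for (s in seq_len(n_sites)) {
    obs <- leaf_states[s, ]
    alphabet <- sort(unique(obs[!is.na(obs)]))
    if (length(alphabet) == 0) {
      state_sets[[s]] <- rep(list(character()), n_node)
      changes[s] <- 0
      next
    }
    k <- length(alphabet)
    big <- 1e9
    cost <- matrix(0, n_tip + n_node, k)
    for (t in seq_len(n_tip)) {
      if (!is.na(obs[t])) {
        cost[t, ] <- big
        cost[t, match(obs[t], alphabet)] <- 0
      } # missing leaf: all-zero row, contributes nothing
    }
    for (e in seq_len(nrow(edge))) {
      parent <- edge[e, 1]
      child <- edge[e, 2]
      child_cost <- cost[child, ]
      m <- min(child_cost)
      # min over child states of cost + 0/1 change
      contrib <- pmin(child_cost, m + 1)
      cost[parent, ] <- cost[parent, ] + contrib
    }
    sets <- vector("list", n_node)
    for (v in seq_len(n_node)) {
      cv <- cost[n_tip + v, ]
      sets[[v]] <- alphabet[cv == min(cv)]
      states_out[s, v] <- sets[[v]][1]
      conserved_out[s, v] <- any(sets[[v]] %in% c("S", "T", "Y"))
    }
    state_sets[[s]] <- sets
    root <- n_tip + 1
    changes[s] <- min(cost[root, ])
  }
  list(states = states_out, conserved = conserved_out,
       state_sets = state_sets, changes = changes)
}

# Marginal ML states per site via ape::ace (equal-rates model, fixed branch
# lengths). Ties and single-state sites resolved alphabetically.
ml_states <- function(tree, leaf_states) {
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  n_sites <- nrow(leaf_states)
  states_out <- matrix(NA_character_, n_sites, n_node)
  conserved_out <- matrix(FALSE, n_sites, n_node)

  for (s in seq_len(n_sites)) {
    obs <- leaf_states[s, ]
    present <- !is.na(obs)
    if (sum(present) == 0) next
    alphabet <- sort(unique(obs[present]))
    if (length(alphabet) == 1) {
      states_out[s, ] <- alphabet
      conserved_out[s, ] <- alphabet %in% c("S", "T", "Y")
      next
    }
    if (all(present)) {
      sub_tree <- tree
      node_map <- seq_len(n_node)
    } else {
      if (sum(present) < 3) {
        # too few observed leaves for a meaningful fit; leave NA
        next
      }
      sub_tree <- ape::drop.tip(tree, tree$tip.label[!present])
      node_map <- match_pruned_nodes(tree, sub_tree)
    }
    fit <- ape::ace(obs[sub_tree$tip.label], sub_tree, type = "discrete",
                    model = "ER")
    lik <- fit$lik.anc
    colnames(lik) <- levels(factor(obs[sub_tree$tip.label]))
    for (v in seq_len(nrow(lik))) {
      orig <- node_map[v]
      if (is.na(orig)) next
      best <- colnames(lik)[lik[v, ] == max(lik[v, ])]
      st <- sort(best)[1]
      states_out[s, orig] <- st
      conserved_out[s, orig] <- st %in% c("S", "T", "Y")
    }
  }
  list(states = states_out, conserved = conserved_out,
       state_sets = NULL, changes = NULL)
}

# Map internal nodes of a pruned tree to internal nodes of the original by
# matching descendant tip sets (restricted to retained tips).
match_pruned_nodes <- function(tree, sub_tree) {
  n_tip <- length(tree$tip.label)
  orig_desc <- lapply(seq_len(tree$Nnode) + n_tip, function(v) {
    tips <- ape::extract.clade(tree, v)$tip.label
    sort(intersect(tips, sub_tree$tip.label))
  })
  n_tip_sub <- length(sub_tree$tip.label)
  vapply(seq_len(sub_tree$Nnode) + n_tip_sub, function(v) {
    tips <- sort(ape::extract.clade(sub_tree, v)$tip.label)
    hit <- which(vapply(orig_desc, identical, TRUE, y = tips))
    if (length(hit) == 0) NA_integer_ else hit[1]
  }, integer(1))
}

#' Per-ancestor conservation profile
#'
#' For each internal node of the tree and each confidence stratum crossed
#' with the metabolic partition, the percentage of p-sites whose inferred
#' ancestral state is a phospho-acceptor residue (S, T or Y). Cells with no
#' eligible sites are reported with `NA` percentages rather than 0.
#'
#' @param callset an `ancestral_callset` whose rows follow `site_info`.
#' @param site_info data.frame aligned with the callset's site rows, with
#'   logical column `metabolic` and character column `confidence`
#'   (`"ALL"`/`"HC"`).
#' @return data.frame: `node`, `stratum`, `partition`, `n_sites`,
#'   `n_conserved`, `pct_conserved` (one decimal, half-up; `NA` for empty
#'   cells).
#' @export
ancestor_conservation_profile <- function(callset, site_info) {
  stopifnot(nrow(site_info) == nrow(callset$conserved))
  out <- list()
  for (v in seq_along(callset$node_labels)) {
    flags <- callset$conserved[, v]
    for (stratum in c("ALL", "HC")) {
      rows <- if (stratum == "HC") site_info$confidence == "HC" else {
        rep(TRUE, nrow(site_info))
      }
      for (part in c("metabolic", "non_metabolic")) {
        sel <- rows & (if (part == "metabolic") site_info$metabolic else {
          !site_info$metabolic
        })
        n <- sum(sel)
        k <- sum(flags[sel])
        out[[length(out) + 1]] <- data.frame(
          node = callset$node_labels[v], stratum = stratum, partition = part,
          n_sites = n, n_conserved = k,
          pct_conserved = if (n == 0) NA_real_ else percent_of(k, n, 1),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, out)
}

#' Pairwise conservation profile against one extant species
#'
#' The two-species analogue of [ancestor_conservation_profile()]: the
#' percentage of classified query p-sites whose homologous residue in the
#' extant target species is S, T or Y (i.e. category `phospho_conserved`,
#' `interchange_ST` or `residue_conserved`).
#'
#' @param calls conservation calls from [call_conservation()].
#' @param metabolic_genes character vector defining the metabolic partition.
#' @return data.frame in the same shape as the ancestral profile, with
#'   `node` set to `"pairwise"`.
#' @export
pairwise_conservation_profile <- function(calls, metabolic_genes = character()) {
  conserved <- calls$category %in% c("phospho_conserved", "interchange_ST",
                                     "residue_conserved")
  info <- data.frame(metabolic = calls$protein_id %in% metabolic_genes,
                     confidence = calls$confidence)
  out <- list()
  for (stratum in c("ALL", "HC")) {
    rows <- if (stratum == "HC") info$confidence == "HC" else {
      rep(TRUE, nrow(info))
    }
    for (part in c("metabolic", "non_metabolic")) {
      sel <- rows & (if (part == "metabolic") info$metabolic else {
        !info$metabolic
      })
      n <- sum(sel)
      k <- sum(conserved[sel])
      out[[length(out) + 1]] <- data.frame(
        node = "pairwise", stratum = stratum, partition = part,
        n_sites = n, n_conserved = k,
        pct_conserved = if (n == 0) NA_real_ else percent_of(k, n, 1),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Project target-species p-sites onto undiscovered query candidates
#'
#' Emits query-species positions that are (i) homologous to a p-site of the
#' target compendium, (ii) carry a phospho-acceptor residue (S/T/Y) in the
#' query proteome, and (iii) are absent from the query compendium: candidate
#' p-sites suggested by cross-species evidence.
#'
#' @param target_compendium a `phos_compendium` (the species providing the
#'   evidence).
#' @param query_compendium a `phos_compendium` (the species receiving the
#'   candidates).
#' @param orthologs data.frame with `gene_a` = query id, `gene_b` = target
#'   id.
#' @inheritParams align_global
#' @return data.frame: `protein_id`, `position`, `residue` (query side),
#'   `target_gene`, `target_position`, `target_residue`.
#' @export
project_candidate_sites <- function(target_compendium, query_compendium,
                                    orthologs,
                                    substitution_matrix = "BLOSUM62",
                                    gap_open = 10, gap_extend = 1) {
  ts <- target_compendium$sites
  orth <- orthologs[orthologs$gene_b %in% ts$protein_id &
                      orthologs$gene_a %in% names(query_compendium$proteome) &
                      orthologs$gene_b %in% names(target_compendium$proteome), ,
                    drop = FALSE]
  empty <- data.frame(protein_id = character(), position = integer(),
                      residue = character(), target_gene = character(),
                      target_position = integer(), target_residue = character(),
                      stringsAsFactors = FALSE)
  if (nrow(orth) == 0) return(empty)
  # align target (pattern) onto query (subject)
  alns <- align_global_many(
    stats::setNames(target_compendium$proteome[orth$gene_b], orth$gene_b),
    query_compendium$proteome[orth$gene_a],
    substitution_matrix, gap_open, gap_extend
  )
  qkey <- site_key(query_compendium$sites$protein_id,
                   query_compendium$sites$position)

  per <- lapply(seq_len(nrow(orth)), function(i) {
    qa <- orth$gene_a[i]
    qb <- orth$gene_b[i]
    rows <- ts[ts$protein_id == qb, , drop = FALSE]
    qp <- map_site(alns[[qb]], rows$position)
    qres <- ifelse(is.na(qp), NA_character_,
                   substring(query_compendium$proteome[[qa]], qp, qp))
    keep <- !is.na(qp) & qres %in% c("S", "T", "Y") &
      !(site_key(qa, qp) %in% qkey)
    data.frame(
      protein_id = rep(qa, sum(keep)), position = qp[keep],
      residue = qres[keep],
      target_gene = rep(qb, sum(keep)), target_position = rows$position[keep],
      target_residue = rows$residue[keep], stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, c(per, list(empty)))
  out <- out[!duplicated(site_key(out$protein_id, out$position)), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
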