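# Independent oracles used to check the package's implementations.
# These are deliberately written as plain, slow reference algorithms with no
# shared code paths with the package internals.

# Gotoh affine-gap global alignment score by explicit dynamic programming.
# Convention: a gap of length L costs open + L * ext; terminal gaps are
# penalized.
gotoh_score <- function(a, b, mat, open = 10, ext = 1) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca)
  m <- length(cb)
  neg <- -1e9
  M <- matrix(neg, n + 1, m + 1)
  Ix <- matrix(neg, n + 1, m + 1)  # gap in b (consumes a)
  Iy <- matrix(neg, n + 1, m + 1)  # gap in a (consumes b)
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -(open + i * ext)
  for (j in seq_len(m)) Iy[1, j + 1] <- -(open + j * ext)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- mat[ca[i], cb[j]]
      M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, Ix[i, j + 1] - ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Iy[i + 1, j] - ext)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# Score a fixed (possibly suboptimal) gapped alignment under the same
# convention, for optimality checks.
score_gapped <- function(aligned_a, aligned_b, mat, open = 10, ext = 1) {
  ca <- strsplit(aligned_a, "")[[1]]
  cb <- strsplit(aligned_b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  s <- 0
  in_gap_a <- FALSE
  in_gap_b <- FALSE
  for (k in seq_along(ca)) {
    if (ca[k] == "-") {
      s <- s - ext - (!in_gap_a) * open
      in_gap_a <- TRUE
      in_gap_b <- FALSE
    } else if (cb[k] == "-") {
      s <- s - ext - (!in_gap_b) * open
      in_gap_b <- TRUE
      in_gap_a <- FALSE
    } else {
      s <- s + mat[ca[k], cb[k]]
      in_gap_a <- FALSE
      in_gap_b <- FALSE
    }
  }
  s
}

# Minimum parsimony change count by exhaustive enumeration of all internal
# labelings of a (small) tree. Leaves with NA state contribute no edges.
enum_parsimony <- function(tree, leaf_states) {
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  obs <- leaf_states[tree$tip.label]
  alphabet <- sort(unique(obs[!is.na(obs)]))
  if (length(alphabet) == 0) return(0)
  grid <- expand.grid(rep(list(alphabet), n_node), stringsAsFactors = FALSE)
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    lab <- c(obs, unlist(grid[r, ], use.names = FALSE))
    cost <- 0
    for (e in seq_len(nrow(tree$edge))) {
      p <- lab[tree$edge[e, 1]]
      c_ <- lab[tree$edge[e, 2]]
      if (is.na(c_)) next  # missing leaf: no information
      cost <- cost + (p != c_)
    }
    best <- min(best, cost)
  }
  best
}

# Exact hypergeometric upper tail P(X >= k) by literal enumeration of all
# choose(N, n) draws from a population of N with K special items.
hyper_enum_subsets <- function(k, n, K, N) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # items 1..K are the special ones
  mean(hits >= k)
}

# Exact tail as a sum of counting terms (enumeration over outcomes), used
# where subset enumeration is too large.
hyper_enum_terms <- function(k, n, K, N) {
  j <- k:min(n, K)
  if (length(j) == 0 || k > min(n, K)) return(0)
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

# Small deterministic proteome for hand-constructed fixtures.
toy_proteome <- function() {
  c(P1 = "MSTYASSTAYMKLS", P2 = "AAASTYAAASTYAA", P3 = "MKLVAAAGHI")
}

toy_records <- function(experiment_id, protein_id, position, residue,
                        id_prob = 0.995, loc_prob = 0.995, n_matches = 1L) {
  data.frame(experiment_id = experiment_id, protein_id = protein_id,
             position = position, residue = residue, id_prob = id_prob,
             loc_prob = loc_prob, n_matches = n_matches,
             stringsAsFactors = FALSE)
}
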