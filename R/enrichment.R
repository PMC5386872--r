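#' Update a negative phosphoproteome
#'
#' The negative phosphoproteome is the comparison background: proteins with
#' no phosphorylation evidence even under relaxed filtering. Given a prior
#' negative set, removes any protein that the current compendium now shows
#' to be phosphorylated.
#'
#' @param prior_negative character vector of protein ids with no prior
#'   phosphorylation evidence.
#' @param phosphoproteins character vector of phosphoprotein ids (typically
#'   `unique(compendium$sites$protein_id)`).
#' @param all_proteins optional character vector of every protein id;
#'   when supplied, `prior_negative` must be a subset of it.
#' @return the updated negative set (character vector).
#' @export
build_negative_set <- function(prior_negative, phosphoproteins,
                               all_proteins = NULL) {
  if (!is.null(all_proteins) &&
      !all(prior_negative %in% all_proteins)) {
    stop("prior_negative contains ids absent from all_proteins")
  }
  setdiff(prior_negative, phosphoproteins)
}

#' Abundance-matched subsampling of two protein groups
#'
#' Controls for protein abundance as a confounding factor: abundances are
#' log10-transformed, binned into `n_bins` equal-width bins spanning the
#' pooled range, and equal numbers of proteins (the per-bin minimum of the
#' two groups) are drawn uniformly without replacement from each bin.
#' Proteins without an abundance value are excluded before binning (their
#' count is reported in a message). Sampling is reproducible from `seed`.
#'
#' @param group_a,group_b character vectors of protein ids.
#' @param abundances named numeric vector of abundances (> 0); names are
#'   protein ids. `NA` marks missing.
#' @param n_bins number of bins, between 2 and 50 (default 9, the midpoint
#'   of the conventional 8-10).
#' @param seed integer seed; when NULL the current RNG state is used.
#' @return list with `a` and `b` (matched protein-id subsets), `bin_edges`,
#'   and `per_bin` (data.frame of per-bin group counts and the matched
#'   count).
#' @export
abundance_matched_subsample <- function(group_a, group_b, abundances,
                                        n_bins = 9, seed = NULL) {
  if (n_bins < 2 || n_bins > 50) stop("n_bins must be in [2, 50]")
  av <- abundances[group_a]
  bv <- abundances[group_b]
  n_missing <- sum(is.na(av)) + sum(is.na(bv)) +
    sum(!group_a %in% names(abundances)) + sum(!group_b %in% names(abundances))
  ga <- group_a[!is.na(av)]
  gb <- group_b[!is.na(bv)]
  av <- av[!is.na(av)]
  bv <- bv[!is.na(bv)]
  if (length(ga) == 0 || length(gb) == 0) {
    stop("both groups need at least one protein with an abundance value")
  }
  if (n_missing > 0) {
    message(n_missing, " protein(s) without abundance excluded from matching")
  }
  la <- log10(av)
  lb <- log10(bv)
  rng <- range(c(la, lb))
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin_a <- cut(la, edges, include.lowest = TRUE, labels = FALSE)
  bin_b <- cut(lb, edges, include.lowest = TRUE, labels = FALSE)

  draw <- function() {
    sel_a <- character()
    sel_b <- character()
    per_bin <- data.frame(bin = seq_len(n_bins), n_a = 0L, n_b = 0L,
                          n_matched = 0L)
    for (b in seq_len(n_bins)) {
      ia <- ga[bin_a == b]
      ib <- gb[bin_b == b]
      per_bin$n_a[b] <- length(ia)
      per_bin$n_b[b] <- length(ib)
      m <- min(length(ia), length(ib))
      per_bin$n_matched[b] <- m
      if (m == 0) next  # bin empty in at least one group: skipped
      sel_a <- c(sel_a, if (length(ia) == 1) ia else sample(ia, m))
      sel_b <- c(sel_b, if (length(ib) == 1) ib else sample(ib, m))
    }
    list(a = sel_a, b = sel_b, bin_edges = edges, per_bin = per_bin)
  }
  out <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  if (length(out$a) == 0) {
    stop("abundance matching produced an empty subsample; ",
         "the two groups occupy disjoint bins")
  }
  out
}

#' Compare a numeric protein feature between two groups
#'
#' Two-sided Wilcoxon rank-sum test plus descriptive statistics. The percent
#' difference is computed on group means as `(mean_a - mean_b) / mean_b *
#' 100` (one decimal, half-up); medians are reported alongside because the
#' test is rank-based.
#'
#' @param values_a,values_b numeric feature values for the two groups
#'   (`NA` dropped).
#' @param feature name recorded in the result.
#' @return one-row data.frame: `feature`, `n_a`, `n_b`, `mean_a`, `mean_b`,
#'   `median_a`, `median_b`, `pct_diff`, `test`, `statistic`, `p_value`.
#' @export
#' @examples
#' compare_numeric_feature(c(4, 4, 4), c(3.7, 3.7, 3.7), "sites")$pct_diff
compare_numeric_feature <- function(values_a, values_b, feature = "feature") {
  va <- values_a[!is.na(values_a)]
  vb <- values_b[!is.na(values_b)]
  if (length(va) == 0 || length(vb) == 0) {
    stop("feature '", feature, "': all values missing in one group")
  }
  wt <- suppressWarnings(stats::wilcox.test(va, vb, alternative = "two.sided"))
  data.frame(
    feature = feature, n_a = length(va), n_b = length(vb),
    mean_a = mean(va), mean_b = mean(vb),
    median_a = stats::median(va), median_b = stats::median(vb),
    pct_diff = round_half_up((mean(va) - mean(vb)) / mean(vb) * 100, 1),
    test = "wilcoxon", statistic = unname(wt$statistic),
    p_value = wt$p.value, stringsAsFactors = FALSE
  )
}

#' Compare a binary protein feature between two groups
#'
#' Chi-squared test with continuity correction on the 2x2 count table; when
#' a margin of the table is zero the chi-squared statistic is undefined and
#' Fisher's exact test is used instead (flagged in the output).
#'
#' @param flags_a,flags_b logical vectors (`NA` dropped).
#' @param feature name recorded in the result.
#' @return one-row data.frame: `feature`, `n_a`, `n_b`, `prop_a`, `prop_b`,
#'   `pct_diff` (on proportions), `test`, `statistic`, `p_value`,
#'   `exact_fallback`.
#' @export
compare_binary_feature <- function(flags_a, flags_b, feature = "feature") {
  fa <- flags_a[!is.na(flags_a)]
  fb <- flags_b[!is.na(flags_b)]
  if (length(fa) == 0 || length(fb) == 0) {
    stop("feature '", feature, "': one group is empty")
  }
  tab <- rbind(a = c(sum(fa), sum(!fa)), b = c(sum(fb), sum(!fb)))
  zero_margin <- any(colSums(tab) == 0) || any(rowSums(tab) == 0)
  if (zero_margin) {
    ft <- stats::fisher.test(tab)
    stat <- NA_real_
    p <- ft$p.value
    test <- "fisher_exact"
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    stat <- unname(ct$statistic)
    p <- ct$p.value
    test <- "chi_squared"
  }
  pa <- mean(fa)
  pb <- mean(fb)
  data.frame(
    feature = feature, n_a = length(fa), n_b = length(fb),
    prop_a = pa, prop_b = pb,
    pct_diff = if (pb > 0) round_half_up((pa - pb) / pb * 100, 1) else NA_real_,
    test = test, statistic = stat, p_value = p,
    exact_fallback = zero_margin, stringsAsFactors = FALSE
  )
}

#' Exact upper-tail hypergeometric probability
#'
#' `P(X >= k)` where `X` is the number of "special" items in a draw of `n`
#' from a population of `N` containing `K` special items. Computed exactly
#' in log space (numerically stable for large populations).
#'
#' @param k observed count of special items in the draw.
#' @param n draw size.
#' @param K number of special items in the population.
#' @param N population size.
#' @return the upper-tail probability, a single number in `[0, 1]`.
#' @export
#' @examples
#' hypergeometric_tail(3, 5, 4, 10)  # 66/252
hypergeometric_tail <- function(k, n, K, N) {
  if (!(k >= 0 && k <= n && n <= N && K >= 0 && K <= N)) {
    stop("require 0 <= k <= n <= N and 0 <= K <= N")
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Fig-2-style feature comparison across two protein groups
#'
#' Convenience wrapper running [compare_numeric_feature()] /
#' [compare_binary_feature()] over the declared columns of a feature table
#' for two id sets, optionally with Benjamini-Hochberg adjustment (off by
#' default; raw p-values are the convention for this analysis).
#'
#' @param features data.frame with a `protein_id` column plus feature
#'   columns.
#' @param group_a,group_b character vectors of protein ids.
#' @param numeric_features,binary_features column names to test.
#' @param adjust apply Benjamini-Hochberg adjustment across features
#'   (adds column `p_adjusted`).
#' @return data.frame with one row per feature.
#' @export
compare_feature_groups <- function(features, group_a, group_b,
                                   numeric_features = character(),
                                   binary_features = character(),
                                   adjust = FALSE) {
  fa <- features[features$protein_id %in% group_a, , drop = FALSE]
  fb <- features[features$protein_id %in% group_b, , drop = FALSE]
  rows <- list()
  for (f in numeric_features) {
    rows[[length(rows) + 1]] <-
      compare_numeric_feature(fa[[f]], fb[[f]], f)[
        , c("feature", "n_a", "n_b", "pct_diff", "test", "statistic",
            "p_value")]
  }
  for (f in binary_features) {
    rows[[length(rows) + 1]] <-
      compare_binary_feature(as.logical(fa[[f]]), as.logical(fb[[f]]), f)[
        , c("feature", "n_a", "n_b", "pct_diff", "test", "statistic",
            "p_value")]
  }
  out <- do.call(rbind, rows)
  if (isTRUE(adjust)) out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  out
}
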