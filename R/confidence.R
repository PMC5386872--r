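#' Partition the gold-standard overlap of an HTP compendium by support
#'
#' Intersects a curated gold-standard site list with the HTP-detected sites
#' of a compendium and splits that overlap into "high overlap" sites (seen
#' in at least `support_cutoff` HTP experiments) and "low overlap" sites
#' (seen in 1 to `support_cutoff - 1`). It also tallies the same split over
#' the full HTP compendium; sites carried only by LTP evidence
#' (`htp_support == 0`) are excluded from all HTP tallies.
#'
#' @param compendium a `phos_compendium`.
#' @param gold data.frame of gold-standard site keys (`protein_id`,
#'   `position`), or a character vector of `"protein:position"` keys.
#' @param support_cutoff minimum support defining "high" (default 3; must be
#'   at least 2).
#' @return an object of class `overlap_partition`: a list with `gold_total`,
#'   `gold_high`, `gold_low`, `htp_high`, `htp_low` and `support_cutoff`.
#' @export
partition_gold_overlap <- function(compendium, gold, support_cutoff = 3) {
  stopifnot(support_cutoff >= 2)
  s <- compendium$sites
  htp <- s[s$htp_support >= 1, , drop = FALSE]

  gkey <- if (is.character(gold)) unique(gold) else {
    unique(site_key(gold$protein_id, gold$position))
  }
  hkey <- site_key(htp$protein_id, htp$position)
  in_gold <- hkey %in% gkey
  if (!any(in_gold) && length(gkey) > 0) {
    warning("gold-standard set is disjoint from the HTP compendium; ",
            "partition counts are zero")
  }
  gsup <- htp$htp_support[in_gold]

  structure(
    list(
      gold_total = sum(in_gold),
      gold_high = sum(gsup >= support_cutoff),
      gold_low = sum(gsup >= 1 & gsup < support_cutoff),
      htp_high = sum(htp$htp_support >= support_cutoff),
      htp_low = sum(htp$htp_support < support_cutoff),
      support_cutoff = support_cutoff
    ),
    class = "overlap_partition"
  )
}

#' Construct an overlap partition from known counts
#'
#' Used when the partition counts are known (e.g. printed in a published
#' table) rather than recomputed from site-level data.
#'
#' @param gold_high,gold_low gold-overlap counts at and below the support
#'   cutoff.
#' @param htp_high,htp_low full-compendium counts at and below the cutoff.
#' @param support_cutoff cutoff the counts refer to (default 3).
#' @return an `overlap_partition`.
#' @export
#' @examples
#' overlap_partition(gold_high = 270, gold_low = 266,
#'                   htp_high = 4156, htp_low = 9088)
overlap_partition <- function(gold_high, gold_low, htp_high, htp_low,
                              support_cutoff = 3) {
  stopifnot(gold_high >= 0, gold_low >= 0, htp_high >= 0, htp_low >= 0)
  structure(
    list(gold_total = gold_high + gold_low, gold_high = gold_high,
         gold_low = gold_low, htp_high = htp_high, htp_low = htp_low,
         support_cutoff = support_cutoff),
    class = "overlap_partition"
  )
}

#' @export
print.overlap_partition <- function(x, ...) {
  cat("gold/HTP overlap partition (support cutoff ", x$support_cutoff,
      ")\n", sep = "")
  cat("  gold overlap:", x$gold_total, "=", x$gold_high, "high +",
      x$gold_low, "low\n")
  cat("  HTP compendium:", x$htp_high, "high /", x$htp_low, "low\n")
  invisible(x)
}

#' Extrapolate the functional fraction of low-evidence HTP p-sites
#'
#' Gold-standard sites detected by HTP experiments split into high-overlap
#' and low-overlap strata in a ratio `gold_low / gold_high`. Assuming the
#' gold standard samples genuine sites without regard to HTP support, that
#' ratio transfers to the whole compendium: for the `htp_high` sites that
#' the support cutoff already validates, `htp_high * ratio` of the low-
#' support sites are expected to be genuine. `mode = "unit_ratio"` rounds
#' the empirical ratio to exactly 1 (the convention when the observed ratio
#' is close to one); `mode = "empirical_ratio"` uses it as observed.
#'
#' @param partition an `overlap_partition`.
#' @param mode `"unit_ratio"` (default) or `"empirical_ratio"`.
#' @param validated_high count of sites treated as already validated when
#'   forming the total functional fraction; defaults to `htp_high`.
#' @param total denominator of the total functional fraction; defaults to
#'   `htp_high + htp_low`. The composition is configurable because the
#'   appropriate denominator (HTP-only vs gold-inclusive) depends on the
#'   question asked.
#' @return an `extrapolation_result`: list with `ratio`,
#'   `predicted_valid_low`, `fraction_low_valid`, `pct_low_valid` (integer
#'   percent, half-up), `fraction_total_functional`, `pct_total_functional`
#'   and `mode`.
#' @export
#' @examples
#' p <- overlap_partition(270, 266, htp_high = 4156, htp_low = 9088)
#' extrapolate_functional_fraction(p)$pct_low_valid  # 46
extrapolate_functional_fraction <- function(partition,
                                            mode = c("unit_ratio",
                                                     "empirical_ratio"),
                                            validated_high = NULL,
                                            total = NULL) {
  mode <- match.arg(mode)
  p <- partition
  if (p$htp_low <= 0) {
    stop("htp_low must be positive to extrapolate a low-overlap fraction")
  }
  ratio <- if (p$gold_high > 0) p$gold_low / p$gold_high else NA_real_
  if (mode == "empirical_ratio" && p$gold_high == 0) {
    stop("empirical_ratio mode requires gold_high > 0 ",
         "(no high-overlap gold sites observed)")
  }
  used_ratio <- if (mode == "unit_ratio") 1 else ratio
  predicted_valid_low <- min(p$htp_high * used_ratio, p$htp_low)
  fraction_low_valid <- predicted_valid_low / p$htp_low

  if (is.null(validated_high)) validated_high <- p$htp_high
  if (is.null(total)) total <- p$htp_high + p$htp_low
  fraction_total <- (validated_high + predicted_valid_low) / total

  structure(
    list(
      ratio = ratio,
      mode = mode,
      predicted_valid_low = predicted_valid_low,
      fraction_low_valid = fraction_low_valid,
      pct_low_valid = round_half_up(100 * fraction_low_valid),
      validated_high = validated_high,
      total = total,
      fraction_total_functional = fraction_total,
      pct_total_functional = round_half_up(100 * fraction_total)
    ),
    class = "extrapolation_result"
  )
}

#' @export
print.extrapolation_result <- function(x, ...) {
  cat("functional-fraction extrapolation (", x$mode, ")\n", sep = "")
  cat("  gold low/high ratio:",
      if (is.na(x$ratio)) "NA" else format(round(x$ratio, 3)), "\n")
  cat("  predicted valid low-overlap sites:",
      format(round(x$predicted_valid_low, 1)), "->", x$pct_low_valid,
      "% of low-overlap sites\n")
  cat("  total functional: ", x$pct_total_functional, "% of ", x$total,
      " sites\n", sep = "")
  invisible(x)
}
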