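#' Annotate every p-site with integrated evidence flags
#'
#' Builds one priority record per compendium site, with boolean flags
#' computed from the supplied annotation layers: `hc` (highly confident),
#' `in_domain` (inside a 1-based inclusive domain interval),
#' `essential_protein`, `phospho_conserved_cross_species` (classified
#' `phospho_conserved` or `interchange_ST` against another species),
#' `ancestor_conserved` (inferred phospho-acceptor at a reference ancestor),
#' `metabolic` (protein in the metabolic model), and `phenotype_linked`
#' (protein mapped to at least one phenotype term). Phenotype terms mapped
#' to proteins absent from the compendium proteome are ignored with a
#' warning. The output is deterministic.
#'
#' @param compendium a `phos_compendium`.
#' @param domains optional domain intervals (`protein_id`, `start`, `end`).
#' @param essential character vector of essential protein ids.
#' @param conservation_calls optional calls from [call_conservation()].
#' @param ancestor_conserved optional character vector of
#'   `"protein:position"` keys whose ancestral state is a phospho-acceptor.
#' @param metabolic_genes character vector of metabolic-model gene ids.
#' @param phenotype_map optional data.frame (`protein_id`, `term`).
#' @return data.frame of priority records: site key columns, `htp_support`,
#'   the seven flags, and `phenotype_terms` (`;`-separated, possibly empty).
#' @export
annotate_flags <- function(compendium, domains = NULL,
                           essential = character(),
                           conservation_calls = NULL,
                           ancestor_conserved = NULL,
                           metabolic_genes = character(),
                           phenotype_map = NULL) {
  s <- compendium$sites
  rec <- data.frame(
    protein_id = s$protein_id, position = s$position, residue = s$residue,
    htp_support = s$htp_support,
    hc = s$confidence == "HC",
    stringsAsFactors = FALSE
  )
  rec$in_domain <- if (!is.null(domains)) {
    site_in_domain(s$protein_id, s$position, domains)
  } else {
    s$in_domain
  }
  rec$essential_protein <- s$protein_id %in% essential

  rec$phospho_conserved_cross_species <- FALSE
  if (!is.null(conservation_calls) && nrow(conservation_calls) > 0) {
    ck <- conservation_calls[conservation_calls$category %in%
                               c("phospho_conserved", "interchange_ST"), ]
    keys <- site_key(ck$protein_id, ck$position)
    rec$phospho_conserved_cross_species <-
      site_key(rec$protein_id, rec$position) %in% keys
  }
  rec$ancestor_conserved <- if (!is.null(ancestor_conserved)) {
    site_key(rec$protein_id, rec$position) %in% ancestor_conserved
  } else FALSE
  rec$metabolic <- rec$protein_id %in% metabolic_genes

  rec$phenotype_terms <- ""
  if (!is.null(phenotype_map) && nrow(phenotype_map) > 0) {
    known <- phenotype_map$protein_id %in% names(compendium$proteome)
    if (any(!known)) {
      warning(sum(!known), " phenotype term(s) mapped to unknown protein(s)",
              " ignored")
      phenotype_map <- phenotype_map[known, , drop = FALSE]
    }
    terms <- vapply(split(as.character(phenotype_map$term),
                          phenotype_map$protein_id),
                    function(x) paste(sort(unique(x)), collapse = ";"), "")
    hit <- terms[rec$protein_id]
    rec$phenotype_terms <- ifelse(is.na(hit), "", hit)
  }
  rec$phenotype_linked <- nzchar(rec$phenotype_terms)
  rec
}

#' Tabulate p-sites and proteins per phenotype term
#'
#' For each phenotype term, counts p-sites and distinct proteins under four
#' strata: all sites, all sites within domains, HC sites, and HC sites
#' within domains. A final union row (`ALL_RELATED_phenotypes`) counts
#' unique sites/proteins across all terms (a protein annotated with two
#' terms counts once), so it is not a column sum.
#'
#' @param records priority records from [annotate_flags()].
#' @return data.frame with columns `term`, then
#'   `sites_all`, `proteins_all`, `sites_all_domain`, `proteins_all_domain`,
#'   `sites_hc`, `proteins_hc`, `sites_hc_domain`, `proteins_hc_domain`.
#' @export
phenotype_tabulate <- function(records) {
  linked <- records[records$phenotype_linked, , drop = FALSE]
  term_lists <- strsplit(linked$phenotype_terms, ";", fixed = TRUE)
  terms <- sort(unique(unlist(term_lists)))

  strata <- function(rows) {
    cellcount <- function(r) c(nrow(r), length(unique(r$protein_id)))
    hc <- rows[rows$hc, , drop = FALSE]
    c(cellcount(rows),
      cellcount(rows[rows$in_domain, , drop = FALSE]),
      cellcount(hc),
      cellcount(hc[hc$in_domain, , drop = FALSE]))
  }
  rows <- lapply(c(terms, "ALL_RELATED_phenotypes"), function(tm) {
    sel <- if (tm == "ALL_RELATED_phenotypes") {
      rep(TRUE, nrow(linked))
    } else {
      vapply(term_lists, function(x) tm %in% x, logical(1))
    }
    v <- strata(linked[sel, , drop = FALSE])
    data.frame(term = tm,
               sites_all = v[1], proteins_all = v[2],
               sites_all_domain = v[3], proteins_all_domain = v[4],
               sites_hc = v[5], proteins_hc = v[6],
               sites_hc_domain = v[7], proteins_hc_domain = v[8],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank priority records by weighted evidence flags
#'
#' Stable descending sort by the weighted sum of the evidence flags; ties
#' break by `htp_support` (descending), then protein id, then position. The
#' default weights are a documented package convention, fully configurable.
#'
#' @param records priority records from [annotate_flags()].
#' @param flag_weights named non-negative weights for any subset of the
#'   flag columns.
#' @return `records` with an added `score` column, in rank order.
#' @export
tier_rank <- function(records,
                      flag_weights = c(hc = 2, in_domain = 1,
                                       essential_protein = 2,
                                       phospho_conserved_cross_species = 2,
                                       ancestor_conserved = 2,
                                       metabolic = 1, phenotype_linked = 1)) {
  if (any(flag_weights < 0)) stop("flag weights must be non-negative")
  unknown <- setdiff(names(flag_weights), names(records))
  if (length(unknown) > 0) {
    stop("unknown flag column(s): ", paste(unknown, collapse = ", "))
  }
  score <- rep(0, nrow(records))
  for (f in names(flag_weights)) {
    score <- score + flag_weights[[f]] * as.numeric(records[[f]])
  }
  records$score <- score
  ord <- order(-score, -records$htp_support, records$protein_id,
               records$position, method = "radix")
  out <- records[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
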