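#' Filter phosphopeptide records by identification and localization stringency
#'
#' Applies the stringency criteria used to build a high-quality p-site
#' compendium: a record is kept only if its peptide-identification
#' probability and its site-localization probability both reach the chosen
#' thresholds (default 0.99/0.99) and the peptide maps uniquely to a single
#' protein. Optionally, records whose stated residue disagrees with the
#' proteome sequence at the stated position are dropped with a warning.
#'
#' @param records data.frame with columns `experiment_id`, `protein_id`,
#'   `position` (1-based), `residue` (S/T/Y), `id_prob`, `loc_prob`, and
#'   `n_matches` (number of proteins the peptide matches).
#' @param id_threshold minimum identification probability, in `[0, 1]`.
#' @param loc_threshold minimum localization probability, in `[0, 1]`.
#' @param proteome optional named character vector of protein sequences; when
#'   supplied, residue/position consistency is checked.
#' @return the retained rows of `records`, in input order; the input is not
#'   modified.
#' @export
#' @examples
#' rec <- data.frame(experiment_id = "e1", protein_id = "P1", position = 3,
#'                   residue = "S", id_prob = 0.995, loc_prob = 0.992,
#'                   n_matches = 1)
#' filter_peptides(rec)
filter_peptides <- function(records, id_threshold = 0.99, loc_threshold = 0.99,
                            proteome = NULL) {
  needed <- c("experiment_id", "protein_id", "position", "residue",
              "id_prob", "loc_prob", "n_matches")
  miss <- setdiff(needed, names(records))
  if (length(miss) > 0) {
    stop("records is missing column(s): ", paste(miss, collapse = ", "))
  }
  stopifnot(id_threshold >= 0, id_threshold <= 1,
            loc_threshold >= 0, loc_threshold <= 1)
  if (nrow(records) == 0) return(records)
  if (!all(records$residue %in% c("S", "T", "Y"))) {
    stop("residue must be one of S, T, Y")
  }
  if (any(records$position < 1)) stop("positions are 1-based and must be >= 1")

  keep <- records$id_prob >= id_threshold &
    records$loc_prob >= loc_threshold &
    records$n_matches == 1

  if (!is.null(proteome)) {
    obs <- substr(proteome[records$protein_id], records$position,
                  records$position)
    mismatch <- keep & (is.na(obs) | obs != records$residue)
    if (any(mismatch)) {
      warning(sum(mismatch), " record(s) dropped: residue disagrees with ",
              "the proteome sequence at the stated position")
      keep <- keep & !mismatch
    }
  }
  records[keep, , drop = FALSE]
}

#' Merge filtered per-experiment records into a unique p-site compendium
#'
#' Collapses filtered phosphopeptide records from any number of
#' high-throughput (HTP) experiments into one record per unique
#' (protein, position) p-site. A site's `htp_support` is the number of
#' *distinct* experiments reporting it (duplicate rows within one experiment
#' count once). Sites from a curated low-throughput (LTP) gold-standard list
#' are merged in and flagged; LTP-only sites enter with `htp_support = 0`.
#' A site is Highly Confident (`confidence == "HC"`) when it is supported by
#' at least `hc_min_experiments` HTP experiments and/or any LTP record;
#' all other sites carry `confidence == "ALL"`.
#'
#' The proteome is authoritative for residues: records whose residue
#' conflicts with the sequence are dropped with a warning, and LTP entries
#' falling on a non-S/T/Y residue are rejected with a warning.
#'
#' @param filtered data.frame of filtered records (see [filter_peptides()]),
#'   or a list of such data.frames (one per experiment).
#' @param ltp optional data.frame of gold-standard sites with columns
#'   `protein_id`, `position` (and optionally `residue`).
#' @param proteome named character vector of protein sequences; every
#'   `protein_id` must resolve here.
#' @param domains optional data.frame of 1-based inclusive domain intervals
#'   (`protein_id`, `start`, `end`, `domain_name`) used to set `in_domain`.
#' @param hc_min_experiments minimum distinct-experiment support for HC
#'   status (default 3).
#' @param label free-text label stored on the compendium.
#' @return an object of class `phos_compendium`: a list with `sites` (one
#'   row per unique site: `protein_id`, `position`, `residue`,
#'   `htp_support`, `ltp`, `confidence`, `in_domain`), `proteome`,
#'   `experiment_ids`, `hc_min_experiments` and `label`.
#' @export
merge_datasets <- function(filtered, ltp = NULL, proteome, domains = NULL,
                           hc_min_experiments = 3, label = "compendium") {
  if (is.list(filtered) && !is.data.frame(filtered)) {
    filtered <- do.call(rbind, filtered)
  }
  if (is.null(filtered) || nrow(filtered) == 0) {
    filtered <- data.frame(experiment_id = character(), protein_id = character(),
                           position = integer(), residue = character())
  }
  unknown <- setdiff(unique(filtered$protein_id), names(proteome))
  if (length(unknown) > 0) {
    stop("protein id(s) not in proteome: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }

  # proteome residue is authoritative; conflicting records are dropped
  if (nrow(filtered) > 0) {
    obs <- substr(proteome[filtered$protein_id], filtered$position,
                  filtered$position)
    bad <- is.na(obs) | obs != filtered$residue | !(obs %in% c("S", "T", "Y"))
    if (any(bad)) {
      warning(sum(bad), " record(s) dropped in merge: residue conflicts ",
              "with the proteome sequence")
      filtered <- filtered[!bad, , drop = FALSE]
    }
  }

  experiment_ids <- sort(unique(as.character(filtered$experiment_id)))

  key <- site_key(filtered$protein_id, filtered$position)
  # distinct-experiment support: collapse duplicate (experiment, site) rows
  ek <- !duplicated(paste(filtered$experiment_id, key))
  support <- table(key[ek])

  uk <- !duplicated(key)
  sites <- data.frame(
    protein_id = as.character(filtered$protein_id[uk]),
    position = as.integer(filtered$position[uk]),
    stringsAsFactors = FALSE
  )
  sites$htp_support <- as.integer(support[site_key(sites$protein_id,
                                                   sites$position)])
  sites$ltp <- FALSE

  if (!is.null(ltp) && nrow(ltp) > 0) {
    lres <- substr(proteome[as.character(ltp$protein_id)], ltp$position,
                   ltp$position)
    ok <- !is.na(lres) & lres %in% c("S", "T", "Y")
    if (any(!ok)) {
      warning(sum(!ok), " LTP site(s) rejected: position is not a S/T/Y ",
              "residue of the proteome")
    }
    ltp <- ltp[ok, , drop = FALSE]
    lkey <- unique(site_key(ltp$protein_id, ltp$position))
    skey <- site_key(sites$protein_id, sites$position)
    sites$ltp <- skey %in% lkey
    extra <- setdiff(lkey, skey)
    if (length(extra) > 0) {
      parts <- strsplit(extra, ":", fixed = TRUE)
      add <- data.frame(
        protein_id = vapply(parts, `[`, "", 1),
        position = as.integer(vapply(parts, `[`, "", 2)),
        htp_support = 0L, ltp = TRUE, stringsAsFactors = FALSE
      )
      sites <- rbind(sites, add)
    }
  }

  sites$residue <- substr(proteome[sites$protein_id], sites$position,
                          sites$position)
  sites$confidence <- ifelse(sites$htp_support >= hc_min_experiments |
                               sites$ltp, "HC", "ALL")
  sites$in_domain <- site_in_domain(sites$protein_id, sites$position, domains)
  sites <- sites[order(sites$protein_id, sites$position),
                 c("protein_id", "position", "residue", "htp_support",
                   "ltp", "confidence", "in_domain")]
  rownames(sites) <- NULL

  structure(
    list(sites = sites, proteome = proteome, experiment_ids = experiment_ids,
         hc_min_experiments = hc_min_experiments, label = label),
    class = "phos_compendium"
  )
}

#' Build a compendium object directly from a site table
#'
#' Convenience constructor for compendia whose evidence is already collapsed
#' to one row per site (for example a second species' site list), bypassing
#' the per-experiment merge.
#'
#' @param sites data.frame with `protein_id`, `position` and optionally
#'   `htp_support`, `ltp`.
#' @param proteome named character vector of sequences.
#' @param label free-text label.
#' @param hc_min_experiments HC support rule (default 3).
#' @return a `phos_compendium` object.
#' @export
compendium_from_sites <- function(sites, proteome, label = "compendium",
                                  hc_min_experiments = 3) {
  stopifnot(all(c("protein_id", "position") %in% names(sites)))
  sites <- sites[!duplicated(site_key(sites$protein_id, sites$position)), ,
                 drop = FALSE]
  out <- data.frame(
    protein_id = as.character(sites$protein_id),
    position = as.integer(sites$position),
    stringsAsFactors = FALSE
  )
  out$residue <- substr(proteome[out$protein_id], out$position, out$position)
  keep <- !is.na(out$residue) & out$residue %in% c("S", "T", "Y")
  if (any(!keep)) {
    warning(sum(!keep), " site(s) dropped: not a S/T/Y proteome residue")
  }
  out <- out[keep, , drop = FALSE]
  out$htp_support <- if ("htp_support" %in% names(sites)) {
    as.integer(sites$htp_support[keep])
  } else 1L
  out$ltp <- if ("ltp" %in% names(sites)) as.logical(sites$ltp[keep]) else FALSE
  out$confidence <- ifelse(out$htp_support >= hc_min_experiments | out$ltp,
                           "HC", "ALL")
  out$in_domain <- FALSE
  out <- out[order(out$protein_id, out$position), ]
  rownames(out) <- NULL
  structure(
    list(sites = out, proteome = proteome,
         experiment_ids = character(), hc_min_experiments = hc_min_experiments,
         label = label),
    class = "phos_compendium"
  )
}

#' @export
print.phos_compendium <- function(x, ...) {
  cat("p-site compendium:", x$label, "\n")
  cat("  ", nrow(x$sites), "unique p-sites in",
      length(unique(x$sites$protein_id)), "proteins;",
      sum(x$sites$confidence == "HC"), "highly confident\n")
  cat("  ", length(x$experiment_ids), "HTP experiment(s);",
      sum(x$sites$ltp), "LTP-supported site(s)\n")
  invisible(x)
}

#' Is a site inside an annotated domain interval?
#'
#' Intervals are 1-based and inclusive at both ends.
#'
#' @param protein_id character vector of protein ids.
#' @param position integer vector of 1-based positions.
#' @param domains data.frame (`protein_id`, `start`, `end`, ...) or NULL.
#' @return logical vector, FALSE everywhere when `domains` is NULL.
#' @export
site_in_domain <- function(protein_id, position, domains = NULL) {
  if (is.null(domains) || nrow(domains) == 0) {
    return(rep(FALSE, length(protein_id)))
  }
  dom_by_prot <- split(domains[, c("start", "end")], domains$protein_id)
  mapply(function(p, pos) {
    d <- dom_by_prot[[p]]
    !is.null(d) && any(pos >= d$start & pos <= d$end)
  }, protein_id, position, USE.NAMES = FALSE)
}

#' Summarize a compendium by confidence stratum and metabolic partition
#'
#' Produces the standard compendium summary: for each confidence stratum
#' (ALL = every site, HC = highly confident sites only) crossed with each
#' protein partition (all proteins, metabolic, non-metabolic), the number of
#' p-sites, the number falling in annotated domains, the number of
#' phosphoproteins, and the mean p-sites per phosphoprotein (one decimal,
#' half-up). An empty stratum reports mean 0 with `empty = TRUE`.
#'
#' @param compendium a `phos_compendium`.
#' @param metabolic_genes character vector of metabolic-model gene/protein
#'   ids defining the metabolic partition.
#' @param domains optional domain intervals; when supplied they override the
#'   `in_domain` flags stored on the compendium.
#' @return data.frame with one row per stratum x partition cell.
#' @export
summarize_counts <- function(compendium, metabolic_genes = character(),
                             domains = NULL) {
  s <- compendium$sites
  if (!is.null(domains)) {
    s$in_domain <- site_in_domain(s$protein_id, s$position, domains)
  }
  s$metabolic <- s$protein_id %in% metabolic_genes

  cell <- function(stratum, partition, rows) {
    n_sites <- nrow(rows)
    n_prot <- length(unique(rows$protein_id))
    data.frame(
      stratum = stratum, partition = partition,
      n_sites = n_sites,
      n_in_domain = sum(rows$in_domain),
      n_proteins = n_prot,
      mean_sites_per_protein = mean_sites_per_protein(n_sites, n_prot),
      empty = n_prot == 0,
      stringsAsFactors = FALSE
    )
  }

  out <- list()
  for (stratum in c("ALL", "HC")) {
    ss <- if (stratum == "HC") s[s$confidence == "HC", , drop = FALSE] else s
    out[[length(out) + 1]] <- cell(stratum, "all", ss)
    out[[length(out) + 1]] <- cell(stratum, "metabolic",
                                   ss[ss$metabolic, , drop = FALSE])
    out[[length(out) + 1]] <- cell(stratum, "non_metabolic",
                                   ss[!ss$metabolic, , drop = FALSE])
  }
  do.call(rbind, out)
}

#' Write / read a compendium site table as TSV
#'
#' @param compendium a `phos_compendium`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_compendium <- function(compendium, path) {
  write_tsv(compendium$sites, path)
}

#' @param path TSV path written by [write_compendium()].
#' @param proteome named character vector of sequences.
#' @param label label for the rebuilt object.
#' @rdname write_compendium
#' @export
read_compendium <- function(path, proteome, label = "compendium") {
  sites <- read_tsv(path)
  comp <- compendium_from_sites(sites, proteome, label = label)
  if ("in_domain" %in% names(sites)) {
    idx <- match(site_key(comp$sites$protein_id, comp$sites$position),
                 site_key(sites$protein_id, sites$position))
    comp$sites$in_domain <- as.logical(sites$in_domain)[idx]
  }
  comp
}
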