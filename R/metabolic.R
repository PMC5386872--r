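#' Load a genome-scale model's gene-reaction associations
#'
#' Builds a minimal metabolic-model representation from a two-column
#' reaction/gene table (the interchange format; conversion from SBML is a
#' one-off export left to model-curation tools). Gene-protein-reaction
#' boolean logic is deliberately flattened: a reaction is associated with
#' every gene listed for it, and downstream coverage treats a reaction as
#' phospho-controlled when any associated gene product is phosphorylated.
#'
#' @param rows data.frame with columns `reaction_id` and `gene_id`, or a
#'   path to a TSV with those columns. Duplicate rows collapse.
#' @return an object of class `metabolic_model`: list with `reactions`
#'   (named list, reaction id -> character vector of gene ids), `genes`
#'   (unique gene ids), `n_reactions`, `n_genes`.
#' @export
#' @examples
#' m <- load_gene_reaction_table(
#'   data.frame(reaction_id = c("r1", "r1", "r2"),
#'              gene_id = c("g1", "g2", "g1")))
#' m$n_reactions  # 2
load_gene_reaction_table <- function(rows) {
  if (is.character(rows) && length(rows) == 1) rows <- read_tsv(rows)
  stopifnot(all(c("reaction_id", "gene_id") %in% names(rows)))
  rid <- as.character(rows$reaction_id)
  gid <- as.character(rows$gene_id)
  bad <- which(is.na(rid) | !nzchar(rid) | is.na(gid) | !nzchar(gid))
  if (length(bad) > 0) {
    stop("empty reaction or gene id at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  keep <- !duplicated(paste(rid, gid))
  reactions <- split(gid[keep], rid[keep])
  genes <- sort(unique(gid))
  structure(
    list(reactions = reactions, genes = genes,
         n_reactions = length(reactions), n_genes = length(genes)),
    class = "metabolic_model"
  )
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("metabolic model:", x$n_reactions, "gene-assigned reactions,",
      x$n_genes, "genes\n")
  invisible(x)
}

#' Phospho-regulation coverage of a metabolic model
#'
#' Counts the reactions with at least one phosphorylated associated gene,
#' the phosphorylated model genes, and the percentage of model genes that
#' are phosphorylated (integer percent, half-up).
#'
#' @param model a `metabolic_model`.
#' @param phosphoproteins character vector of phosphoprotein ids (e.g. the
#'   proteins of a compendium, or of its HC stratum).
#' @param stratum_label label recorded in the report (e.g. `"ALL"`, `"HC"`).
#' @return list with `stratum`, `n_reactions_covered`,
#'   `n_phospho_metabolic`, `n_model_genes`, `pct_genes_phosphorylated`,
#'   and `per_reaction` (data.frame `reaction_id`, `phospho_controlled`).
#' @export
#' @examples
#' m <- load_gene_reaction_table(
#'   data.frame(reaction_id = c("r1", "r2"), gene_id = c("g1", "g2")))
#' reaction_coverage(m, "g1")$n_reactions_covered  # 1
reaction_coverage <- function(model, phosphoproteins,
                              stratum_label = "ALL") {
  phos_genes <- intersect(model$genes, phosphoproteins)
  covered <- vapply(model$reactions, function(g) any(g %in% phos_genes),
                    logical(1))
  list(
    stratum = stratum_label,
    n_reactions_covered = sum(covered),
    n_phospho_metabolic = length(phos_genes),
    n_model_genes = length(model$genes),
    pct_genes_phosphorylated = percent_of(length(phos_genes),
                                          max(length(model$genes), 1)),
    per_reaction = data.frame(reaction_id = names(model$reactions),
                              phospho_controlled = unname(covered),
                              stringsAsFactors = FALSE)
  )
}
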