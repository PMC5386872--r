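#' Round half away from zero
#'
#' Deterministic decimal rounding in which exact halves round up in absolute
#' value (0.45 -> 0.5 at one decimal, 45.5 -> 46 at zero decimals), unlike
#' [base::round()]'s round-half-even. All percentages and per-protein means
#' reported by this package use this convention.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits to keep.
#' @return `x` rounded to `digits` decimals, halves away from zero.
#' @export
#' @examples
#' round_half_up(5.65, 1)   # 5.7
#' round_half_up(45.5)      # 46
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # small epsilon guards binary-representation shortfall of exact halves
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Percentage of a count, rounded
#'
#' @param k numerator count.
#' @param n denominator count; must be positive.
#' @param digits decimals kept (default 0, i.e. integer percent).
#' @return `100 * k / n`, rounded half-up.
#' @export
#' @examples
#' percent_of(412, 909)  # 45
percent_of <- function(k, n, digits = 0) {
  stopifnot(is.numeric(k), is.numeric(n), all(n > 0))
  round_half_up(100 * k / n, digits)
}

#' Mean number of sites per protein
#'
#' Ratio of site count to protein count rounded half-up to one decimal, the
#' convention used in compendium summary tables. An empty protein stratum
#' yields 0 (flagged upstream) rather than a division failure.
#'
#' @param n_sites site count.
#' @param n_proteins protein count.
#' @return one-decimal mean, or 0 when `n_proteins` is 0.
#' @export
#' @examples
#' mean_sites_per_protein(14339 - 1668, 2633 - 412)  # 5.7
mean_sites_per_protein <- function(n_sites, n_proteins) {
  if (n_proteins == 0) return(0)
  round_half_up(n_sites / n_proteins, 1)
}

# Derive an independent per-stream seed from one master seed. Streams are
# named so adding a generator does not perturb the draws of existing ones.
.sim_streams <- c(
  proteome = 1L, phospho = 2L, ortholog = 3L, tree = 4L,
  ancestral = 5L, features = 6L, metabolic = 7L, phenotype = 8L
)

derive_seed <- function(seed, stream) {
  stopifnot(stream %in% names(.sim_streams))
  (as.integer(seed) %% 10000000L) * 100L + .sim_streams[[stream]]
}

#' Read a protein FASTA file as a named character vector
#'
#' @param path FASTA file path.
#' @return named character vector of amino-acid sequences.
#' @export
read_proteome_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  out <- as.character(aa)
  names(out) <- sub("\\s.*$", "", names(aa))
  out
}

#' Write a named character vector of protein sequences to FASTA
#'
#' @param proteome named character vector of sequences.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(proteome, path) {
  aa <- Biostrings::AAStringSet(proteome)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, ...)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

site_key <- function(protein_id, position) {
  paste(protein_id, position, sep = ":")
}
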