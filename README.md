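# phoscompendium

Tools for assembling and analyzing compendia of protein phosphorylation
sites (p-sites) from many high-throughput (HTP) phosphoproteomic
experiments.

HTP surveys identify thousands of p-sites per run, but sites seen in only
one or two experiments are plagued by technical and biological noise. This
package is for proteomics and systems-biology analysts who need to answer,
reproducibly: which sites are trustworthy, how many of the low-evidence
ones are likely genuine, which are conserved across species and ancestors,
how deeply phosphorylation penetrates a genome-scale metabolic model, what
distinguishes phosphoproteins from the never-phosphorylated background
once protein abundance is controlled for, and which individual sites
deserve wet-lab follow-up.

## What it computes

* **Compendium construction** — `filter_peptides()` applies the stringency
  rule (identification ≥ 0.99, localization ≥ 0.99, unique protein match);
  `merge_datasets()` collapses experiments into unique sites with
  distinct-experiment support. A site is *Highly Confident* (HC) when
  supported by ≥ 3 experiments and/or a curated low-throughput (LTP)
  record.
* **Gold-standard extrapolation** — the LTP ∩ HTP overlap splits into
  high-support (`g_hi`) and low-support (`g_lo`) sites. The ratio
  `r = g_lo / g_hi` transfers to the whole compendium, so with `H_hi`
  high- and `H_lo` low-support sites, `H_hi · r / H_lo` of the low-support
  stratum is predicted genuine (`extrapolate_functional_fraction()`, with
  a unit-ratio and an empirical-ratio mode).
* **Conservation** — ortholog resolution (synteny over best-hit), global
  affine-gap alignment (BLOSUM62, open 10 / extend 1), site projection,
  classification into phospho-conserved / S↔T interchange /
  residue-conserved / not-conserved, Fitch–Sankoff and maximum-likelihood
  ancestral acceptor reconstruction over a species tree, per-ancestor
  conservation profiles and candidate-site projection.
* **Metabolic coverage** — reactions controlled by ≥ 1 phosphorylated
  enzyme, and the phosphorylated fraction of model genes.
* **Enrichment** — abundance-matched subsampling (equal counts per log10
  bin) plus Wilcoxon / chi-squared / exact hypergeometric comparisons.
* **Prioritization** — seven evidence flags per site, weighted ranking,
  and phenotype tabulations.
* **Synthetic data** — seeded generators for every input with planted
  ground truth (`sim_config()`, `run_pipeline()`), so each estimator is
  validated by parameter recovery.

## Worked example

The headline extrapolation, on the published compendium counts (270/266
gold-overlap split; 4156 high- vs 9088 low-support HTP sites):

```r
library(phoscompendium)
p <- overlap_partition(gold_high = 270, gold_low = 266,
                       htp_high = 4156, htp_low = 9088)
extrapolate_functional_fraction(p, "unit_ratio")
#> functional-fraction extrapolation (unit_ratio)
#>   gold low/high ratio: 0.985
#>   predicted valid low-overlap sites: 4156 -> 46 % of low-overlap sites
#>   total functional: 63% of 13244 sites
```

Reading: the gold standard lands on high- and low-support sites in an
almost 1:1 ratio, so for each of the 4156 already-validated high-support
sites one low-support site is predicted genuine — 46% of the 9088
low-support sites, and about two thirds of the compendium overall.

A full synthetic study, generated and analyzed end to end:

```r
res <- run_pipeline(sim_config(seed = 1), out_dir = "sim_run")
res$compendium
#> p-site compendium: synthetic
#>    2870 unique p-sites in 397 proteins; 1100 highly confident
#>    20 HTP experiment(s); 297 LTP-supported site(s)
```

`sim_run/` then holds every input (FASTA, per-experiment TSVs, ortholog
table, Newick tree, feature table, model table) and every output
(compendium, summaries, extrapolation JSON, conservation calls/profiles,
candidate sites, coverage, enrichment, priorities) plus `truth.json` with
the planted ground truth and `run_log.json` with the seed and parameters.

Exact over-representation, e.g. metabolic enrichment among conserved
phosphorylation events (115 of 692 conserved events metabolic, vs 1668 of
14339 compendium-wide):

```r
hypergeometric_tail(115, 692, 1668, 14339)
#> [1] 4.039037e-05
```

(The exact tail; a continuity-corrected normal approximation at the same
counts gives 1.8e-05 — see the methods vignette.)

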