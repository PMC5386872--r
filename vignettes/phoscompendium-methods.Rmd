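---
title: "Methods: building, calibrating and stress-testing a p-site compendium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building, calibrating and stress-testing a p-site compendium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phoscompendium)
```

## The problem

High-throughput (HTP) mass-spectrometry surveys report thousands of
phosphorylation sites (p-sites) per experiment, but with substantial
technical and biological noise: a large fraction of sites seen in only one
or two experiments may be spurious or non-functional. `phoscompendium`
implements the full analysis chain around this problem: stringent
filtering and merging of many experiments into one compendium, calibration
of low-evidence sites against a curated gold standard, cross-species and
ancestral conservation mapping, coverage of a genome-scale metabolic
model, abundance-controlled enrichment comparisons, and evidence-based
prioritization. A synthetic-data module generates every input with known
ground truth so that each estimator can be validated by parameter
recovery rather than by eyeballing.

## Compendium construction

A phosphopeptide record enters the compendium only if its peptide
identification probability and its site localization probability both
reach 0.99 (the conventional stringency for high-quality compendia; both
thresholds are arguments of `filter_peptides()`) and the peptide maps to
exactly one protein. Records are collapsed to unique
(protein, 1-based position) sites; a site's support is the number of
*distinct* experiments reporting it, because evidence is counted per
experiment, not per spectrum — duplicate rows within one experiment count
once.

A site is Highly Confident (HC) when it has support $\ge 3$ or appears in
the curated low-throughput (LTP) gold standard; all sites form the ALL
stratum. The proteome sequence is authoritative: records whose stated
residue conflicts with the sequence are dropped with a warning, and LTP
entries at non-S/T/Y positions are rejected. Reported percentages round
half-up to integers and per-protein means to one decimal
(`round_half_up()`), matching how such tables are conventionally printed.

## Gold-standard extrapolation

Let the gold-overlap sites (gold standard $\cap$ HTP) split into
$g_{hi}$ with support $\ge 3$ and $g_{lo}$ with support 1–2, and the full
HTP compendium into $H_{hi}$ / $H_{lo}$. If the gold standard samples
genuine sites without regard to HTP support, the ratio
$r = g_{lo}/g_{hi}$ transfers to the compendium, so $H_{hi}\, r$ of the
low-support sites are expected to be genuine:

$$\widehat{F}_{low} = \frac{H_{hi}\, r}{H_{lo}}, \qquad
  \widehat{F}_{tot} = \frac{V + H_{hi}\, r}{T}.$$

`extrapolate_functional_fraction()` implements two modes: `unit_ratio`
rounds $r$ to exactly 1 (the convention when the observed ratio is close
to one, and the mode that reproduces printed worked examples) and
`empirical_ratio` uses $r$ as observed (the honest mode for analysis and
for parameter-recovery tests). The composition of the total fraction —
which validated count $V$ and which denominator $T$ — is deliberately an
argument pair rather than a constant, because the appropriate denominator
(HTP-only or gold-inclusive) depends on the question; the defaults use
$V = H_{hi}$ and $T = H_{hi} + H_{lo}$.

## Conservation mapping

Orthologs are resolved with synteny evidence taking precedence over best
sequence hits (`resolve_orthologs()`; equal-score best hits break ties
lexicographically, so resolution is deterministic). Ortholog pairs are
globally aligned with affine gap penalties; the aligner defaults —
BLOSUM62 scores, gap open 10, gap extend 1 (a gap of length $L$ costs
$10 + L$), terminal gaps penalized, the ambiguity residue X scored as
neutral — are configurable and logged, since published analyses name
their aligner but rarely its parameters. The alignment engine is
`Biostrings::pairwiseAlignment()`, repackaged into an explicit residue
position map; its optimality is cross-checked in the test suite against
an independent brute-force Gotoh dynamic program on small instances.

Each query p-site maps through its alignment to a homologous target
position and is classified into one of four categories that partition the
calls: `phospho_conserved` (homologous position phosphorylated in the
target compendium), `interchange_ST` (phospho-conserved with the acceptor
switched between serine and threonine), `residue_conserved` (S/T/Y in the
target without phosphorylation evidence), and `not_conserved` (other
residue, or alignment gap). Query proteins without an ortholog are
excluded from profile denominators entirely rather than counted as
not-conserved, since absence of an ortholog call is missing data, not
evidence of loss.

Ancestral acceptor states over a species tree are reconstructed two ways.
Parsimony mode runs unit-cost Sankoff dynamic programming; on binary
trees its per-node minimal-cost state sets are exactly Fitch bottom-up
sets, and the same recursion handles multifurcations. Ambiguity at a node
is resolved optimistically for the conservation flag — the flag is TRUE
when the minimal set intersects {S, T, Y} — while the single reported
state is the alphabetically smallest member (a deterministic, documented
tie-break). Maximum-likelihood mode performs marginal reconstruction
under an equal-rates model with the input tree's branch lengths held
fixed (via `ape::ace()`); re-estimating branch lengths or fitting richer
substitution models is out of scope, and polytomies are rejected with an
explicit error in this mode. Divergence dates are display metadata read
from the tree file, never computed.

## Metabolic coverage and enrichment comparisons

The metabolic model is a flattened gene–reaction bipartite table: a
reaction counts as phospho-controlled when *any* associated gene product
is phosphorylated. Full gene–protein–reaction boolean logic (isoenzyme
vs. complex semantics) is deliberately not parsed, matching how coverage
is conventionally counted; SBML import is a one-off export left to model
curation tools.

Group comparisons control for protein abundance, the dominant detection
confounder: abundances are log10-transformed, cut into 9 equal-width bins
over the pooled range (9 is the midpoint of the conventional 8–10; edge
placement is unspecified in the literature, so equal width is used and
documented), and equal numbers — the per-bin minimum — are drawn from
each bin without replacement, reproducibly from a seed. Proteins missing
abundance are excluded from matching and their count logged. Note a
useful by-product verified in the test suite: because matching equalizes
the bin occupancy of the two groups, the usual rank-sum test on matched
abundances becomes strongly conservative (its iid variance overstates the
stratified variance), so even a several-fold planted abundance shift is
neutralized.

Numeric features are compared with two-sided Wilcoxon rank-sum tests;
percent differences are computed on group means (medians are reported
alongside, since the test is rank-based). Binary features use the
chi-squared test with continuity correction, falling back to Fisher's
exact test (flagged) when a margin is zero. Raw p-values are reported by
convention; a Benjamini–Hochberg option exists but is off by default.
Over-representation uses the exact hypergeometric upper tail
(`hypergeometric_tail()`), computed in log space and checked against
literal draw enumeration in the tests. Worth noting: at the worked
example's published counts (115 of 692 conserved events metabolic,
against 1668 of 14339), the exact tail is $4.0\times10^{-5}$, whereas a
continuity-corrected normal approximation gives $1.8\times10^{-5}$ —
reports of "$p < 2\times10^{-5}$" at such counts are consistent only with
the approximate route. The package always reports the exact tail.

## Prioritization

`annotate_flags()` attaches seven boolean evidence flags per site (HC,
in-domain with 1-based inclusive intervals, essential protein,
cross-species phospho-conserved, ancestor-conserved, metabolic,
phenotype-linked). `tier_rank()` orders sites by a weighted flag sum with
deterministic tie-breaks (support, then site key). The default weights
(hc 2, in_domain 1, essential 2, each conservation flag 2, metabolic 1,
phenotype 1) are a package convention — essentiality, confidence and
conservation are the strongest independent indicators of functional
relevance — and are fully configurable. Phenotype tabulations count
sites and distinct proteins per term under four strata, with a union row
counting each site/protein once across terms.

## The synthetic study and its calibration

`sim_config()` fixes the simulated study. Defaults, chosen once:

* **20 experiments, detection probability 0.125 per genuine site.** With
  support $\sim \mathrm{Binomial}(20, 0.125)$, detected genuine sites
  split close to 1:1 between support $\ge 3$ and support 1–2 — the split
  observed in curated gold-standard overlaps — and, once spurious sites
  (which almost all sit at support 1–2) are added, about two thirds of
  all compendium sites are low-support, as HTP compendia show.
* **Functional fraction 0.66** of the target 3000 unique sites (10,000 in
  the recovery test); spurious sites are drawn per experiment from the
  unused S/T/Y positions — only S/T/Y, consistent with enrichment-based
  protocols — at a rate sized so distinct spurious sites make up the
  remaining third.
* **LTP coverage 0.15** of genuine sites, sampled independently of
  detection (curation is not an HTP protocol).
* **Ortholog divergence**: substitution 0.15/residue, indel start 0.01
  with mean length 2, p-site retention 0.35, S↔T exchange 0.12 among
  retained S/T acceptors (the published two-species interchange
  fraction). Retained acceptor positions are protected from substitution
  and deletion so the planted retention is exact; homologous positions,
  indel footprints and planted "undiscovered" candidate sites are all
  recorded as ground truth.
* **Abundance**: log10-normal, mean 3.55 (phospho) vs 2.95 (background),
  sd 0.55 — a roughly four-fold planted shift, matching the reported
  abundance advantage of phosphoproteins — with 10% missing at random.
  Count features (PPIs, kinase targets) are Poisson with higher rates in
  the phospho group; binary features (ubiquitination, essentiality, WGD
  paralogy) use published-range rates.
* **Metabolic model**: 150 reactions over 15% of the proteome, genes per
  reaction $1 + \mathrm{Poisson}(1.5)$.
* A single master seed expands into named independent streams (one per
  generator), so adding a generator never perturbs another's draws, and
  every pipeline output logs the seed and full parameter set.

What the generator does *not* emulate: spectra and retention times,
protocol-specific enrichment chemistry, kinase-motif sequence context
around sites, correlated detection across related experiments, and
phylogenetic correlation of feature values. Passing recovery tests
therefore demonstrates estimator correctness under the stated noise
model, not robustness to every bias of real data.

## Numerical conventions and test scale

Rounding of reported figures is half-up (never banker's); ties in
best-hit resolution, ancestral-state resolution and priority ranking
break deterministically as documented above; degenerate inputs (empty
strata, empty groups, zero gold overlap in empirical mode, out-of-range
positions) raise explicit errors or flagged zero rows rather than NaN.

The test suite validates estimators at sizes a desk machine handles in
minutes: functional-fraction recovery on a 10,000-site compendium
(±5 percentage points against the realized planted fraction),
alignment-based projection of ~1200 planted sites at divergence 0.2
(≥ 99% recovered more than 5 residues from any indel footprint — gap
placement immediately around indels is genuinely ambiguous), interchange
recovery within binomial error, exhaustive small-instance equivalence for
the aligner (pairs of length ≤ 8) and the parsimony engine (trees of
≤ 5 leaves), exact-tail equivalence against draw enumeration for all
populations up to 25, and 100 seeded abundance-matching runs. The default
end-to-end pipeline (400 proteins, 3000 sites, 20 experiments) runs in
well under a minute apiece for every stage.

```{r example, eval = FALSE}
res <- run_pipeline(sim_config(seed = 1), out_dir = "sim_run")
res$extrapolation$unit_ratio$pct_low_valid
```

## Known limitations

* The extrapolation assumes the gold standard samples genuine sites
  independently of HTP support; protocol-specific capture biases are not
  modelled beyond the two-stratum ratio.
* Peptides spanning multiple candidate acceptors are assumed pre-split
  into per-site rows by the upstream search pipeline.
* The ML ancestral mode fixes branch lengths and uses an equal-rates
  model; it is a reconstruction device, not a substitution-model fit.
* Candidate-site projection inherits alignment ambiguity near indels;
  positions inside gaps are reported as unmapped rather than guessed.
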