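Package: phoscompendium
Title: Multi-Experiment Phosphoproteomic Compendia, Cross-Species P-Site
    Conservation and Metabolic Phospho-Regulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds stringently filtered phosphorylation-site (p-site)
    compendia from multiple high-throughput phosphoproteomic experiments,
    assigns evidence-based confidence classes, and estimates the fraction of
    low-evidence sites that are genuine by extrapolation from overlap with a
    curated gold standard. Maps p-sites across species through ortholog
    resolution and pairwise global protein alignment, classifies conservation
    (including serine/threonine interchange), and reconstructs ancestral
    phospho-acceptor states over a species tree by parsimony or maximum
    likelihood. Quantifies phospho-regulation coverage of a genome-scale
    metabolic model, performs abundance-matched group comparisons of protein
    features, and prioritizes p-sites by integrated evidence flags. Includes
    a seeded synthetic-data generator that emulates the statistical structure
    of every input, so all estimators can be checked against planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
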