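Package: designvar
Title: Site Variability Comparison of Designed and Natural Protein Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess how closely computationally designed protein
    sequences recapitulate the site-specific variability of natural homologs.
    Computes per-site Shannon entropy, pseudocount-corrected and rank-ordered
    Kullback-Leibler divergence between designed and natural alignment
    profiles, relative solvent accessibility (RSA) from classic DSSP output
    with max-ASA normalization, exposure-class entropy summaries, entropy-RSA
    correlations, split-half natural-vs-natural controls, and hybrid design
    alignments that mix buried and exposed columns from different design
    conditions. Includes a fully parameterized synthetic-alignment generator
    (RSA-dependent Dirichlet natural model, Boltzmann design model with a
    temperature parameter) so the whole pipeline is testable without external
    structure or alignment data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    graphics,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
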