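# designvar

Computational protein design produces, for a given backbone, large sets of
candidate sequences. A natural question is how closely such designed sets
recapitulate the *site-specific variability* of natural homologs of the same
structure: are cores appropriately conserved and hydrophobic, are surfaces
appropriately variable, and does variability track solvent exposure the way
it does in evolution? `designvar` implements the complete alignment-level
comparison pipeline for this question, aimed at structural bioinformaticians
evaluating design protocols (e.g. fixed-backbone versus flexible-backbone
design across a temperature sweep).

## What it computes

For an alignment column *i* with amino-acid frequencies *p<sub>ij</sub>*:

- **Site entropy** (nats): *H<sub>i</sub> = −Σ<sub>j</sub> p<sub>ij</sub> ln p<sub>ij</sub>*,
  the per-site variability measure.
- **Kullback–Leibler divergence** of a designed (focal) profile against the
  natural (reference) profile:
  *D<sub>i</sub><sup>KL</sup> = Σ<sub>j</sub> p<sub>ij</sub> ln(p<sub>ij</sub>/q<sub>ij</sub>)*,
  with 1/20 added to every amino-acid count before normalization so all
  frequencies are strictly positive.
- **Rank-ordered KL divergence**: the same sum after sorting both 20-vectors
  in descending order, comparing frequencies at equal rank — a pure
  distribution-*shape* comparison that ignores amino-acid identity.
- **RSA and exposure classes**: relative solvent accessibility = DSSP ACC
  value divided by the residue's maximum ASA (Tien et al. 2013 scales);
  buried (RSA ≤ 0.05), partially buried (0.05 < RSA ≤ 0.25), exposed
  (RSA > 0.25).
- **Entropy–RSA correlation** per protein and condition, exposure-class
  entropy medians across proteins, exposure-stratified amino-acid
  frequencies pooled over proteins, a split-half natural-vs-natural KL
  control, and **hybrid designs** whose buried/partially-buried columns come
  from one design condition and exposed columns from another.

A synthetic-alignment generator (`synthetic_spec()`,
`make_benchmark_scenario()`) emulates the relevant regularities of real
data — conservation and hydrophobic enrichment in the core, a
temperature-like parameter controlling designed-sequence variability,
cysteine-free designs — with full ground truth, so the whole pipeline is
testable without structure databases or a design run.

## Worked example

```r
library(designvar)

spec <- synthetic_spec(n_sites = 100, seed = 7)     # one synthetic protein
rsa  <- sample_rsa_profile(spec)
nat  <- generate_natural_alignment(spec, rsa)$alignment
energies <- draw_site_energies(spec, rsa)
designs  <- lapply(c(0.1, 0.6, 1.8), function(T)
  generate_design_alignment(spec, rsa, T, energies)$alignment)
names(designs) <- sapply(designs, `[[`, "condition")

cmp <- compare_designs(nat, designs, rsa, control_seed = 7)
summary(cmp)
```

```
Protein 'protein': per-condition summaries (pearson correlation)
 protein_id condition mean_entropy mean_kl mean_rank_kl   cor_r cor_n
    protein   natural       1.1510      NA           NA  0.8158   100
    protein      T0.1       0.2570  5.6263       0.5534 -0.0081   100
    protein      T0.6       1.7403  4.5092       0.8418  0.1665   100
    protein      T1.8       2.7202  3.8997       2.4061  0.2193   100
Split-half natural control KL: 0.0312 nats
```

Reading the table: designs at T = 0.1 are far too conserved
(mean entropy 0.26 vs 1.15 nats for natural) and at T = 1.8 far too variable
(2.72 nats). Standard KL *decreases* monotonically with temperature — a
broadening artifact — while the rank-ordered KL is smallest at a low
temperature and rises again, exposing that high-temperature designs match
natural profiles in overlap but not in shape. Every designed set is far
above the split-half control (0.031 nats), and no design condition
approaches the natural entropy–RSA correlation of 0.82.

Multi-protein runs are driven by a YAML configuration
(`validate_config()`, `run_comparison()`), which writes per-site and
per-protein TSV tables, pooled class frequencies, hybrid correlations and a
failure table with per-protein error isolation.

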