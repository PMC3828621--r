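---
title: "Methods: comparing site variability in designed and natural protein alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing site variability in designed and natural protein alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`designvar` compares alignments of computationally designed sequences with
alignments of natural homologs of the same structure, site by site. This
vignette documents the statistical procedures, the conventions and numerical
choices behind them, and the generative model of the synthetic benchmark,
so that every reported quantity has an unambiguous definition.

## Per-site statistics

**Counting.** Each alignment designates a reference row whose ungapped
sequence corresponds to the native structure; all per-site statistics are
computed only at the reference's non-gap columns (`build_site_map()`).
Columns where the reference is gapped — insertion columns of a domain
alignment relative to the structure — are dropped entirely: there is no RSA
value to attach to them, and keeping them would make per-protein means
depend on alignment depth in an uncontrolled way. Within a column, gap and
unknown characters are excluded from the counts and the frequencies are
renormalized over the observed canonical residues; a column with no
countable residue is excluded with a warning rather than silently zeroed.
Columns are unweighted: no phylogenetic down-weighting of redundant natural
sequences is applied anywhere.

**Entropy.** Site entropy is the Shannon entropy
$H_i = -\sum_j p_{ij}\,\ln p_{ij}$ in nats, with $0\ln 0 = 0$. The natural
logarithm is used throughout, so $H_i \in [0, \ln 20 \approx 2.996]$.
Entropy is computed from *raw* frequencies by default; an
`entropy_pseudocount` option exists but is off, because the pseudocount is a
device for divergence computations, not a smoothing prior we want inside the
variability measure itself.

**KL divergence and the pseudocount.** The divergence of a focal (designed)
profile against a reference (natural) profile is
$D_i = \sum_j p_{ij}\ln(p_{ij}/q_{ij})$. Reference frequencies of zero are
fatal here, so both profiles receive the 1/20 pseudocount: each of the 20
amino-acid counts is incremented by 1/20 before normalizing, making the row
denominator the site total plus one. `kl_divergence()` refuses profiles
containing zeros rather than patching them silently. The divergence is
asymmetric by construction and the code never symmetrizes: natural
alignments always supply $q$.

**Rank-ordered KL.** To compare distribution *shapes* while ignoring
amino-acid identity, both 20-vectors are sorted in descending order and
compared rank against rank. Sorting makes the statistic invariant to any
relabeling of the alphabet applied independently to each profile, and it is
insensitive to tie-breaking order: tied frequencies contribute identical
values at the affected ranks regardless of which permutation the sort
chooses, so no explicit tie rule is needed. Because designed sets never
contain cysteine, its count is zero there; the pseudocount gives it a small
positive frequency and the full 20-letter alphabet is retained in every
entropy and divergence computation — no letter is ever dropped.

**Split-half control.** The baseline for "how different can two alignments
drawn from the same site distributions look" is obtained by randomly
partitioning the natural alignment into halves of sizes
$\lfloor n/2\rfloor$ and $\lceil n/2\rceil$ and computing the mean KL of the
first half against the second, both pseudocounted. The half assignment is
arbitrary (KL is asymmetric); a `reps` argument averages over independent
splits, and the split is deterministic given its seed.

## Solvent accessibility

Absolute accessibilities are read from classic fixed-column DSSP output
(`parse_dssp()`), one chain at a time, with chain-break and missing-density
records (`!`) skipped and counted, and DSSP's lowercase notation for
disulfide-bonded cysteines mapped back to `C`. RSA is the ACC value divided
by the residue's maximum possible ASA; the default constants are the
theoretical maxima of Tien et al. (2013), with their empirical scale
available as an alternative and user-supplied tables accepted. RSA values
above 1 (which occur under theoretical scales) are retained, not clipped —
clipping would deflate the exposed class — and counted in a message.

Exposure classes follow the inclusive-upper-bound convention: buried is
RSA ≤ 0.05, partially buried 0.05 < RSA ≤ 0.25, exposed RSA > 0.25. The
two-class scheme used for pooled amino-acid frequency tables splits at 0.05
only. RSA is computed once, on the native structure; designed alignments
inherit it by structure position, and no structural calculation is ever
performed on designs.

## Joining, correlations, summaries

Per-site tables join mapped positions with RSA records by structure
position; positions present on only one side are excluded and counted, so
the join is lossless modulo logged exclusions. The entropy–RSA association
is summarized per protein by a correlation coefficient. Pearson is the
default and Spearman is available; the package's qualitative conclusions
(natural above designed, and so on) are checked on synthetic data and hold
under both, which is why the choice is exposed as an option rather than
fixed. A correlation over fewer than 3 sites, or with a constant axis, is
an error and is reported as missing — never coerced to 0.

Distribution summaries across proteins (per condition) report min,
quartiles, median, mean and max, with quartiles computed by the default
linear-interpolation convention of `stats::quantile()`. Descriptive
amino-acid frequency tables are raw counts pooled over all sites of all
proteins per exposure class, without pseudocount. A paired-comparison
helper (`paired_condition_test()`) wraps a paired t-test for users who want
significance statements about per-protein metric differences; the package
itself asserts none.

## Hybrid designs

`build_hybrid()` splices two design conditions column-wise: buried and
partially buried positions take the core condition's column, exposed
positions the surface condition's column; reference-gap columns (if any)
follow the core. Row *k* of the hybrid concatenates columns of row *k* of
each source — column-wise statistics are identical under any row pairing,
and this choice keeps the output a well-formed alignment. Hybrids are
diagnostic constructs, not designable sequences; no energetic or
plausibility check is applied. `select_hybrid_recipe()` picks the pair of
conditions at the dataset level, matching across-protein median class
entropies (core conditions on buried + partially buried sites, surface
conditions on exposed sites) against the natural values.

## The synthetic benchmark

The generator provides ground-truthed data with the regularities the
pipeline is meant to detect, while remaining honest about what it does not
model.

**Exposure.** RSA values are drawn from a two-component Beta mixture,
0.5·Beta(0.9, 8) + 0.5·Beta(2.2, 1.8): a buried-enriched spike near zero
plus a broad exposed component, giving roughly 15% buried, 30% partially
buried and 55% exposed sites — proportions in the range seen for globular
proteins.

**Natural model.** Each site's amino-acid distribution is drawn from a
Dirichlet whose base measure interpolates linearly (in RSA) between a
hydrophobic-favoring buried composition and a polar-favoring exposed
composition, and whose concentration is $\alpha(\mathrm{rsa}) = 0.2 +
5.5\cdot\mathrm{rsa}$. Low concentration at buried sites yields sparse,
conserved columns; high concentration at exposed sites yields diffuse,
variable columns. These defaults were fixed once, by forward simulation,
to produce natural mean entropies near 1.1 nats with a clear entropy–RSA
association and class-entropy separation large enough that core- and
surface-matching design temperatures differ — the regime in which hybrid
construction is meaningful. Sequences are drawn i.i.d. per site; the first
row of every generated alignment is the per-site modal sequence of its
generating distributions and serves as the (gapless) reference row, so the
site map is the identity. Its inclusion biases counts toward the mode by at
most one part in n+1.

**Design model.** Each site receives a fixed energy vector
$E_j = -\ln b_j + \varepsilon_j$, where $b$ is the natural base composition
at that site's RSA renormalized over the 19-letter design alphabet
(cysteine has infinite energy, hence exactly zero probability at every
temperature) and $\varepsilon_j \sim N(0, 1)$. Energies are drawn once per
site and shared across the whole temperature sweep, so conditions differ
only through the Boltzmann exponent $p_j \propto e^{-E_j/T}$. Sharing the
base composition with the natural model makes designed and natural sets
agree in hydrophobicity structure while the energy noise decouples their
per-site identities — which is precisely what separates the standard KL
(identity-sensitive) from the rank-ordered KL (shape-only). The default
temperature sweep is 0.03, 0.1, 0.3, 0.6, 0.9, 1.2, 1.8, 2.4 with 500
designed sequences per condition; 500 natural sequences are drawn per
protein.

**Reproducibility.** One integer seed controls everything. Each operation
draws from a fixed sub-stream derived from that seed (and, for multi-protein
scenarios, from the protein index), the caller's RNG state is saved and
restored around every draw, and `make_benchmark_scenario()` written twice
with the same seed is byte-identical.

**What the generator does not emulate.** Sites are independent — amino-acid
covariation, a central feature of real alignments and of flexible-backbone
design outputs, is absent by construction. There is no phylogenetic
structure among the natural sequences, no alignment gaps, no real energy
function, and no relationship between sites beyond the shared RSA
dependence. Passing the synthetic acceptance checks therefore demonstrates
that the pipeline measures what it claims to measure on data with known
structure; it does not certify conclusions about any particular design
protocol on real data.

## Numerical conventions and degenerate inputs

- Alignment columns and structure positions are both 1-based; the site map
  makes the correspondence explicit.
- Frequency rows must sum to 1 within 1e-9; KL and entropy values are
  clamped to 0 when round-off produces magnitudes below 1e-12.
- Empty entropy or divergence vectors, all-gap references, sub-4-sequence
  split-half requests, constant correlation axes, unknown config keys, and
  disordered exposure thresholds are all hard errors, not silent defaults.
- Multi-protein runs isolate failures: one unreadable input marks that
  protein failed and the run continues, with the error recorded in a
  failure table.

## Problem sizes

The packaged benchmark used by the test suite and the acceptance script is
8 synthetic proteins × 150 sites, with 500 natural and 500 designed
sequences per condition across the 8-temperature sweep — large enough that
per-condition curves are stable across seeds (the whole benchmark runs in
seconds) — plus a 20-seed, 200-site recovery study targeting a ground-truth
entropy–RSA correlation of 0.6 (realized by the concentration settings
$\alpha(\mathrm{rsa}) = 0.45 + 2.2\cdot\mathrm{rsa}$). Unit tests use much
smaller fixtures built in code.

## Known limitations

- Classic DSSP text output only; mmCIF-style DSSP files are rejected with a
  clear error rather than parsed.
- No sequence weighting and no covariation statistics; profile-similarity
  scores from other evaluation traditions are out of scope.
- The hybrid module asserts nothing about which condition pair is "right";
  the recipe is either user-specified or chosen by the class-entropy
  matching rule described above.
- Reported p-values from paired tests at small protein counts should be
  treated as descriptive.
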