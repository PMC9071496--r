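---
title: "Methods: the PTM landscape of RNA-binding proteins"
author: "rbptm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the PTM landscape of RNA-binding proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbptm)
```

# The problem

Posttranslational modifications (PTMs) — phosphorylation, ubiquitination,
acetylation, methylation, and dozens of rarer marks — regulate protein
structure, localization, turnover, and interactions. RNA-binding proteins
(RBPs) sit at the center of posttranscriptional regulation, yet the
landscape of PTMs on the RBP-ome is scattered over many curated site
databases, each with its own identifiers, label dialects, and evidence
standards. `rbptm` implements, as a tested reusable pipeline, the
integrative analysis such a catalog enables:

1. **Harmonization** of per-source PTM catalogs onto a canonical proteome.
2. **Landscape statistics**: per-type counts, per-protein modification
   density, RBP enrichment tests, multi-site fractions, site-count CDFs.
3. **Conservation contrast** of PTM positions against per-protein resampled
   backgrounds.
4. **Enzyme pairing**: ME/M/E classification of (RBP, PTM type) pairs over a
   protein–protein interaction (PPI) network.
5. **Cancer-mutation proximity** to PTM sites at the exact residue and
   within a ±k window.
6. **Crosslink interface proximity**: standardized windows around UV
   crosslink ranges and distance–frequency statistics.
7. **eCLIP peak–gene intersection**, strand-aware, replicate-concordant.
8. **Atlas export** as an 11-column flat table.

A seeded synthetic-data generator plants each of the effects these analyses
are designed to detect, so the whole pipeline is testable without any
external download.

# Harmonization rules

Site records are read per source under registered *dialects* (column-name
maps plus the evidence values that mark computational predictions, which
are always dropped — only experimentally determined sites are analyzed).
PTM labels are normalized against a controlled vocabulary with a synonym
table (`inst/extdata/ptm_vocabulary.tsv`); unmappable labels are dropped
with a warning, never silently passed.

Unification deduplicates by the key **(accession, position, PTM type)** —
one residue carrying two modification types is two sites, matching per-type
counting throughout the pipeline. Sources and PMIDs are merged per key and
the individual provenance records retained for export. Sites on accessions
absent from the proteome, sites beyond the protein length, and (when
sequences are available) sites whose stated residue conflicts with the
canonical sequence are dropped with logged counts; the conflict rule is
configurable to `"keep"` because either the catalog or the sequence version
may be at fault, and dropping is the conservative default. Rows are put in
a canonical order before aggregation, so unification is idempotent and
independent of catalog input order.

Positions are 1-based indices into the canonical (SwissProt-style)
sequence; isoform mapping is assumed done upstream.

# Landscape statistics

*Density* is the unified site count divided by the full protein length in
residues, modified or not; group comparison uses Welch's *t*.

*Enrichment* per PTM type is a 2×2 Pearson chi-squared test of the
modified-by-that-type proportion, **RBP versus non-RBP**. The disjoint
contrast is the default because a test of RBPs against *all* proteins
counts every RBP in both margins; the overlapping variant is available via
`analysis_config(overlapping_groups = TRUE)` for comparability with
analyses phrased that way. No continuity correction is applied by default
(the intended regime is thousands of proteins per margin; a Yates flag
exists). Raw p-values are Bonferroni-adjusted with family size *m* = the
number of PTM types carrying at least one modified protein, and called at
`alpha = 0.05`. A table with a zero margin is reported as *degenerate* with
an `NA` statistic rather than raised, so one absent type cannot abort a
cohort run.

# Conservation contrast

Conservation input is per-residue scores in [0, 1] (e.g. phastCons
collapsed from nucleotides to residues upstream; averaging the codon's
three scores is the suggested convention — the synthetic generator emits
residue scores directly). For each protein the mean score at scored PTM
positions is compared with the mean over `background_n = 100` positions
drawn uniformly **without replacement** from the protein's scored residues
after excluding PTM positions; when fewer than 100 eligible positions
remain the draw falls back to with-replacement (logged). Ties count as
*not* more conserved. The cohort summary reports the fraction of proteins
whose PTM sites are more conserved, the fraction whose PTM mean exceeds the
high-conservation threshold (0.9), and a pooled two-sample
Kolmogorov–Smirnov test.

Background seeds are derived per protein from `(seed, accession)` with a
rolling string hash, so cohort results are identical whatever the protein
processing order.

# Enzyme pairing (ME/M/E)

An enzyme *matches* a PTM type when it is annotated for that type in
**either** the writer or eraser role — depositing and removing enzymes both
constrain stoichiometry, and the headline per-enzyme rankings cover both
kinases and phosphatases. A writer-only mode exists
(`analysis_config(writer_only = TRUE)`). Each (RBP, type) cell receives
exactly one label: `ME` (modified and ≥1 matching enzyme neighbor), `M`
(modified only), `E` (enzyme neighbor only), or `none`. Types deposited by
cellular chemistry rather than enzymes (default: oxidation, sulfenic acid)
are excluded from enzyme matching, so their cells are only ever `M`/`none`.

Edges are undirected, self-loops dropped, and duplicates across source
databases collapsed before any counting, making every statistic invariant
under direction flips and cross-database redundancy. *Potentially modifying
interactions* count (modified RBP, matching enzyme) **pairs** — an RBP with
three kinase neighbors contributes three — so the count is always at least
the number of `ME` cells for the type.

# Mutation proximity

Mutation records are residue-level (accession, 1-based position, reference
and alternate amino acid, cancer type, case count); genomic MAF parsing is
upstream. "Within k residues" is **inclusive and symmetric**
(|Δ| ≤ k, default k = 10). Because the natural counting unit is ambiguous
— a mutation may pair with several sites — the pipeline emits all three
tallies: (mutation, site) pairs, deduplicated mutations, and deduplicated
proteins. Per-position tracks sum case counts by residue and conserve the
protein's total retained cases.

# Crosslink interface windows

Crosslink studies report contact ranges at very different resolutions, so
every range is standardized to a `window_size = 21`-residue window: the
center is `floor((start + end)/2)` (the left-of-middle residue for
even-length ranges) and the window is the center ±10, **clipped to
[1, length] without re-centering** — shifting a boundary window would move
its center away from the reported contact. Ranges of 21+ residues are
thereby truncated around their center (the window is a subset of the
range); shorter ranges are expanded.

Sites inside a window are recorded once per containing window with
`distance = |position − center|` ≤ 10. For the distance–frequency
correlation, the per-distance counts are divided by the number of residue
*slots* at that distance across windows (one slot at distance 0, up to two
at each positive distance, fewer where clipping removed a flank) before
computing Spearman's rank correlation over the 11 bins (average ranks for
ties, asymptotic p). Without this normalization the distance-0 bin has
structurally half the opportunity of every other bin, which biases the
rank correlation positive by about +0.25 under uniform placement; with it,
uniform placement is genuinely null and planted decay is recovered at full
strength. Raw-count mode remains available (`windows = NULL`). Identical
frequencies in all bins are reported as rho = 0 under the all-ties
convention and flagged; a single occupied bin is flagged `insufficient`.

For family contrasts each site gets a single **unbounded**
nearest-center distance (minimum over the protein's window centers), and
groups defined by `family_tags` (e.g. `"hnRNP"`) are compared by Welch's
*t*; proteins without windows are excluded.

# eCLIP intersection

Peaks are 0-based half-open (narrowPeak); an (RBP, gene) pair is a hit iff
**each replicate independently** contains at least one peak overlapping the
gene on the **same strand** with overlap length / peak length ≥
`overlap_fraction = 0.5`. The denominator is the peak's own length, and the
replicates need not share the same peak. Interval work is done with
GenomicRanges; the test suite checks it against an all-pairs scan.

# Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `window_size` | 21 | residues | standardized crosslink window width (odd) |
| `proximity_k` | 10 | residues | mutation/PTM proximity radius, inclusive |
| `background_n` | 100 | positions | conservation background per protein |
| `overlap_fraction` | 0.5 | fraction | eCLIP peak-over-gene requirement |
| `high_conservation_threshold` | 0.9 | score | "highly conserved" PTM mean |
| `alpha` | 0.05 | — | significance after Bonferroni |
| `yates` | FALSE | — | 2×2 continuity correction |
| `overlapping_groups` | FALSE | — | RBP vs all proteins instead of vs non-RBP |
| `writer_only` | FALSE | — | restrict enzyme matching to writers |
| `nonenzymatic_types` | oxidation, sulfenic acid | — | excluded from E/ME logic |

# The synthetic-data generator

The generator emulates the statistical structure the analyses assume, not
the biology of any specific dataset. Defaults: ~2,000 proteins with
log-normal lengths (median ≈ 400 residues, floored at 50), 12% RBPs (10% of
them tagged `hnRNP`); per-residue site rates per type with phosphorylation
dominant and a planted ×5 rate multiplier in RBPs; 3 enzymes per type with
planted substrate edges at 0.3 versus 0.02 background; mutation rates of
0.02 per residue within 10 of a PTM site versus 0.002 elsewhere (a 10×
hotspot); ~2 crosslink ranges per RBP with 5,000 interface site records, of
which 80% are placed at signed offsets from window centers with |offset| ~
Geometric(success = 0.7) — so `interface_decay = 1` degenerately puts every
decayed site at the center — and 20% uniformly; conservation scores
Beta(2, 3) with +0.2 added at PTM positions (clipped at 1); and a toy
two-chromosome eCLIP fixture with 60% of peaks planted inside genes on the
gene's strand. These sizes generate a full bundle in about a second and run
the eight-stage pipeline in under ten seconds on one CPU; the calibration
simulations in the test suite use 300–500 proteins per cohort and 100–1,000
replicates.

Determinism: every generator draws from a sub-seed derived by a rolling
string hash of `(master seed, module name)`, so regenerating one module is
stable and bundle checksums are reproducible; per-replicate catalogs use
`seed_key` suffixes. One calibration subtlety the test suite encodes: null
replicates for the enrichment test redraw the *proteome* as well as the
catalog, because conditioning on a single proteome freezes chance length
imbalances between the RBP and non-RBP groups into a systematic effect.

**What the generator does not emulate** — and therefore what passing tests
do *not* show about real data: sequence-level PTM motifs (residues are
drawn from the vocabulary's compatibility sets, and proteins carry no
sequences by default); realistic PPI topology (edges are independent
Bernoulli draws, not scale-free); the strongly bimodal distribution of real
phastCons scores (the Beta background is unimodal, so the "mean score >
0.9" fraction is essentially zero on synthetic data while real RBP cohorts
report ~35–40%); genome coordinates beyond toy chromosomes; and any
family-specific interface effect (interface sites are planted uniformly
across RBPs, so the hnRNP-versus-others contrast is null in the default
bundle and is exercised instead with purpose-built cohorts in the tests).

# Numerical and degenerate-input choices

- Even-length crosslink ranges center on the left-of-middle residue;
  boundary windows are clipped, never shifted.
- Proximity windows are inclusive at |Δ| = k.
- Conservation ties (PTM mean = background mean) are not "more conserved".
- Degenerate 2×2 margins give `NA` statistics with a flag, not errors.
- All-ties distance frequencies give rho = 0 with a flag; a single occupied
  bin is `insufficient`.
- Ranking tie-breaks are deterministic: combination labels lexicographic,
  mutated sites by accession then position.
- The atlas `source` column can be renamed to the published `Ssource`
  spelling via `strict_header = TRUE`; export is one row per
  (site × evidence record) by default, with a one-row-per-site mode, since
  published per-entry counts are ambiguous between the two.

# Known limitations

- Published RBP-ome sizes differ between analysis and database descriptions
  (2,508 vs 2,436 in the motivating study); the pipeline makes no attempt
  to reconcile catalog-version discrepancies, and absolute counts from any
  specific database snapshot are out of scope.
- Protein-to-genome coordinate mapping, UniProt ID mapping services, and
  live database queries are upstream of this package: inputs are assumed
  pre-mapped to canonical accessions.
- Whether distance–frequency analyses should be opportunity-normalized is
  an open question in the literature; this package defaults to normalized
  (for the calibration reasons above) and exposes raw mode.
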