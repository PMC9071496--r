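# rbptm

Posttranslational modifications (PTMs) regulate what proteins do;
RNA-binding proteins (RBPs) regulate what RNAs do. Understanding how the
two intersect — which marks sit on the RBP-ome, which enzymes plausibly
deposit or remove them, which cancer mutations hit modified residues, and
which PTMs sit near the RNA–protein interface — requires stitching together
PTM site catalogs, an RBP census, protein–protein interaction (PPI)
networks, mutation tables, conservation tracks, UV-crosslink ranges, and
eCLIP peaks. `rbptm` implements that integrative analysis as a tested,
reusable R pipeline for computational biologists who have such inputs (or
want to prototype against realistic synthetic ones).

## What it computes

- **Catalog harmonization** — per-source readers with column dialects,
  exclusion of computational predictions, vocabulary normalization of PTM
  labels, and unification onto a canonical proteome keyed by
  (accession, position, PTM type), with provenance retained.
- **Landscape statistics** — per-protein type-count profiles, modification
  density (sites per residue over the full protein length), per-type
  RBP-vs-non-RBP enrichment via Pearson's χ² on the 2×2 table
  (modified/unmodified × RBP/other) with Bonferroni correction over the m
  types tested, multi-site fractions, site-count CDFs, and ranked PTM-type
  combinations.
- **Conservation contrast** — for each protein, mean conservation at PTM
  positions versus n = 100 background positions resampled from the same
  protein (PTM positions excluded); cohort fractions and a pooled
  two-sample Kolmogorov–Smirnov test.
- **Enzyme pairing** — each (RBP, PTM type) cell labeled ME / M / E / none
  by co-occurrence of modification and interaction with an enzyme annotated
  for that type (writer or eraser); interaction counts, per-enzyme
  substrate counts, and enzyme target-set overlaps.
- **Mutation proximity** — cancer mutations intersected with PTM sites at
  the exact residue and within |Δ| ≤ k = 10 residues; pair, mutation, and
  protein tallies; ranked mutated sites; per-position case-count tracks.
- **Interface proximity** — reported crosslink ranges standardized to
  21-residue windows centered on floor((start+end)/2) and clipped to the
  protein; PTM-to-center distances; Spearman rank correlation between
  distance (0..10) and opportunity-normalized PTM frequency; per-family
  nearest-distance contrasts (Welch's t).
- **eCLIP intersection** — (RBP, gene) hits where, in each replicate, a
  peak overlaps the gene on the same strand with ≥ 50% of the peak's
  length.
- **Atlas export** — the 11-column flat table (UniProt ID, gene name,
  position, PMID, source, amino acid, modification type, cell line, sample
  type, body site, disease state), one row per evidence record, with a
  lossless re-import.
- **Synthetic data** — a seeded generator that plants every effect above
  (RBP site-rate enrichment, enzyme–substrate edges, mutation hotspots,
  geometric distance decay around crosslink centers, conservation shift)
  and writes complete input bundles.

See `vignettes/rbptm-methods.Rmd` for the statistical conventions and the
reasoning behind each default.

## Worked example

```r
library(rbptm)

spec   <- simulation_spec(n_proteins = 500L, seed = 42L)
bundle <- file.path(tempdir(), "bundle")
make_bundle(spec, bundle)

config   <- analysis_config(seed = 42L)
manifest <- run_pipeline(bundle, file.path(tempdir(), "reports"), config)
sapply(manifest$stages, function(s) s$status)
#>    harmonize    landscape conservation      enzymes    mutations
#>  "completed"  "completed"  "completed"  "completed"  "completed"
#>    interface        eclip       export
#>  "completed"  "completed"  "completed"

enr <- read.delim(file.path(tempdir(), "reports", "enrichment.tsv"))
enr[, c("ptm_type", "n_rbp_modified", "n_other_modified",
        "statistic", "p_adjusted")]
#>          ptm_type n_rbp_modified n_other_modified statistic p_adjusted
#> 1     acetylation             60              185      67.7   1.12e-15
#> 2     methylation             60              167      78.6   4.53e-18
#> 3       oxidation             55               83     136.1   1.14e-30
#> 4 phosphorylation             61              295      28.1   6.90e-07
#> 5     sumoylation             57              118     104.3   1.04e-23
#> 6  ubiquitination             61              213      57.3   2.24e-13
```

Every PTM type comes out enriched in RBPs (Bonferroni-adjusted p ≪ 0.05)
because the generator plants a 5× per-residue site-rate multiplier in RBPs;
the 2×2 counts show the modified-protein margins the χ² statistic is
computed from. The conservation stage recovers the planted +0.2 score shift
at PTM sites:

```r
read.delim(file.path(tempdir(), "reports", "conservation_summary.tsv"))
#>   n_proteins more_conserved_fraction high_conservation_fraction ks_statistic ks_p_value
#> 1         61                       1                          0        0.339          0
```

— all 61 profiled RBPs have PTM sites more conserved than their sampled
background, and the pooled KS test is overwhelming. And the interface stage
recovers the planted distance decay of PTMs around crosslink-window
centers:

```r
head(read.delim(file.path(tempdir(), "reports", "distance_correlations.tsv")), 3)
#>      ptm_type    rho p_value n_sites flag
#> 1         all -0.752 0.00763    1957   ok
#> 2 acetylation -0.806 0.00271     312   ok
#> 3 methylation -0.752 0.00756     311   ok
```

negative Spearman rho: PTM frequency falls with distance from the
crosslink center.

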