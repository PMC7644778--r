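# spikequant

Absolute, volumetric microbial abundances from shotgun metagenomes calibrated
with internal genomic standards.

Marine microbial ecologists usually see their communities as proportions:
read counts are compositional, so a bloom of one taxon silently "dilutes"
every other. Spiking known quantities of foreign genomic DNA into each sample
before extraction fixes this. `spikequant` implements the full analysis path
from homology-search hit tables to cells per liter of seawater, plus the
community statistics built on top of them, and ships a ground-truthed
simulator so the whole pipeline is testable without any external data.

## The model

For each spiked standard with `S_p` protein-coding genes, `S_a` molecules
added and `S_s` protein-encoding reads recovered:

    S_r = S_s / S_p          genome copies of the standard recovered
    R   = S_r / S_a          recovery ratio (fraction of molecules sequenced)
    G_a = G_s / R            molecules of any gene category with G_s reads

Dividing by the filtered volume `V` (liters) gives genes per liter. Counting
reads of the conserved single-copy recombinase gene *recA* per taxon gives
genome equivalents:

    cells/L = n_recA / (R * V)

Three standards per sample provide the mean `R` used for point estimates, a
95% confidence interval (t, df = 2) and a percent coefficient of variation;
`1/(R*V)` is the sequencing detection limit in cells per liter.

Around that core the package provides:

* **Hit-table arbitration** (`identify_standard_reads`,
  `count_standard_protein_reads`, `arbitrate_annotations`, `count_recA`):
  BLAST/DIAMOND tabular input, standard-read identification
  (e < 0.001, %ID > 95, alignment > 50% of read, bit > 50), bit-40/%ID-95
  standard-protein filtering, the strict viral-override rule, and
  keyword-confirmed *recA* counting.
* **Quantification** (`recovery_ratio`, `genome_equivalents`,
  `quantify_samples`, `detection_limit`): abundance tables with per-standard
  CIs, %CV and detection limits; zeros are reported as zeros with the limit
  attached.
* **Community summaries** (`bin_by_family`, `classify_abundance`,
  `relative_abundance`, `top_n_families`, `rank_recruitment`): family
  binning, the dominant/abundant/minor/rare decade classes, and rank-order
  reference-bin recruitment.
* **Ordination** (`composition_matrix`, `pca_ordination`, `bray_curtis`,
  `permanova`, `dispersion_test`): log10 percent composition with 0.001
  zero replacement, centered+scaled PCA, and first-party Bray–Curtis
  PERMANOVA with a homogeneity-of-dispersion check.
* **Hydrography** (`potential_density`, `mixed_layer_depth`,
  `mixed_layer_average`): mixed-layer depth from CTD profiles by the
  0.35 kg/m³ potential-density criterion (EOS-80), with trapezoidal layer
  averaging.
* **Simulation** (`sim_config`, `generate_reference_collection`,
  `generate_community_scenario`, `simulate_sequencing`,
  `write_fixture_set`): archipelago-like communities with west–east
  gradients and El Niño-style year shifts, spiked standards, multinomial
  read sampling with single-copy *recA* semantics, and annotation noise —
  with the true cells/L recorded for every taxon and sample.

## Worked example

```r
library(spikequant)

cfg <- sim_config(n_families = 10, n_taxa = 20, reads_per_sample = 2e5, seed = 7)
col <- generate_reference_collection(cfg)
sc  <- generate_community_scenario(cfg, col)
sq  <- simulate_sequencing(sc, col)

ab <- quantify_samples(sq$counts[, c("sample_id", "taxon_id", "recA")],
                       sq$recovery, col$standards, sc$samples)
ab[ab$sample_id == "y1_site01", ][1:4,
   c("taxon_id", "recA", "cells_per_L", "ci_low", "ci_high", "detection_limit")]
#>   taxon_id recA cells_per_L   ci_low  ci_high detection_limit
#> 1   tax001    0           0        0        0        63895393
#> 2   tax002    1    63895393 45424273 83639598        63895393
#> 3   tax003    0           0        0        0        63895393
#> 4   tax004    0           0        0        0        63895393

rec <- attr(ab, "recovery")
sprintf("mean R = %.3g, mean %%CV = %.1f%%", mean(rec$R_mean), mean(rec$cv_percent))
#> "mean R = 1.19e-08, mean %CV = 15.5%"
```

One read of *recA* at this depth corresponds to ~6.4 × 10⁷ cells/L — taxa
below that detection limit show up as zeros, which is why they are reported
with the limit attached rather than as missing. The three standards agree to
a mean CV of 15.5%, so normalization noise is small against the
between-sample variation.

```r
fam  <- bin_by_family(abundance_matrix(ab), taxon_family_map(col))
table(classify_abundance(fam[, "y1_site01"]))
#> dominant abundant    minor     rare
#>        3        3        0        4

prop <- t(sweep(fam, 2, colSums(fam), "/"))
permanova(prop, sc$samples$year, n_perm = 999, seed = 1)
#> PERMANOVA: pseudo-F = 0.027, R2 = 0.001, p = 0.986 (999 permutations, seed 1)
```

This scenario has no configured year effect, and the PERMANOVA agrees
(p ≈ 1). Configure `elnino_indicator_families` to inject order-of-magnitude
year shifts and the test detects them; `dispersion_test()` should be checked
alongside to confirm group differences are location, not spread.

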