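---
title: "Quantitative metagenomics with internal genomic standards: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative metagenomics with internal genomic standards: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikequant)
```

## The quantification model

Shotgun metagenome read counts are compositional: twice the reads does not
mean twice the cells. Spiking a known quantity of foreign genomic DNA into
each sample *before* extraction breaks that degeneracy. If a standard genome
with $S_p$ protein-coding genes is added at $S_a$ molecules and $S_s$ of its
protein-encoding reads are recovered in the library, then

$$S_r = \frac{S_s}{S_p}, \qquad R = \frac{S_r}{S_a},$$

where $S_r$ is the number of standard genome copies recovered and $R$ — the
recovery ratio — is the proportion of added molecules that made it through
extraction, library preparation and sequencing. Any gene category observed
with $G_s$ reads then contains $G_a = G_s / R$ molecules in the sample, and
dividing by the filtered seawater volume $V$ gives a volumetric abundance in
genes per liter.

Counting reads of a conserved single-copy gene — the recombinase *recA* —
per taxon turns gene abundances into *genome equivalents*:

$$\text{cells L}^{-1} \approx \frac{n_{recA}}{R \cdot V},$$

because each genome carries exactly one *recA* copy. Three standards are
spiked per sample; the point estimate uses their arithmetic mean $R$, while
the three per-standard estimates yield a 95% confidence interval
($t$-distribution, two degrees of freedom, floored at zero) and a percent
coefficient of variation ($\mathrm{sd}/\mathrm{mean}\times 100$). We adopt
the pooled mean $R$ for point estimates because the per-standard spread is a
library-level nuisance, not taxon information; the per-standard estimates are
retained for the uncertainty summaries.

`molecules_added()` converts a spiked mass to molecules with the average
dsDNA molar mass of 650 g mol⁻¹ bp⁻¹ and the Avogadro constant; both are
arguments, since the conversion convention is not universal.

**Detection limit.** We define it as the abundance at which one *recA* read
is expected, $1/(R \cdot V)$. An alternative Poisson definition — the
abundance at which $P(\geq 1\ \text{read}) = p$ — is available via
`detection_limit(method = "poisson")`. The expected-one convention is simple,
scale-transparent, and makes zero counts interpretable: zero-count taxa are
reported as 0 cells L⁻¹ with the sample's detection limit attached, never as
missing.

## Hit-table arbitration

The pipeline consumes BLAST/DIAMOND tabular output (12 standard columns plus
query length and a subject-set label). All cutoffs live in one place,
`annotation_thresholds()`, and are applied with the strictness their usual
statement implies:

* a read is an **internal-standard read** iff its best nucleotide hit against
  the standard genomes has e-value < 0.001, identity > 95%, alignment length
  > 50% of the read length, and bit score > 50 (all strict);
* **standard protein** hits are removed when bit < 40 *or* identity < 95
  (kept on equality) after an e-value < 0.001 prefilter; the survivors are
  $S_s$;
* **community protein** hits below bit 50 are removed before top-hit
  selection; a bacterial annotation is replaced by a viral one only when the
  viral bit score is *strictly* higher (ties keep the bacterial label);
* a read counts as ***recA*** when its top hit against the RecA reference set
  exceeds bit 50 and its community annotation confirms a RecA product.

Boundary values therefore fall exactly where the written rule puts them:
identity 95.0 fails the standard-read test but passes the standard-protein
filter. Top-hit ties are broken by lexicographically smallest subject
identifier, then input order — the searches themselves do not guarantee an
order, and determinism is required for testing. "Duplicate hit" removal is
implemented as per-read top-hit selection within each subject set.

RecA reference membership is decided by title keywords ("recombinase RecA",
"protein RecA", "recombinase A", "RecA protein") matched case-sensitively by
default, since annotation pipelines emit these exact strings; a
case-insensitive switch exists. When the RecA search and the community search
disagree on the taxon, the RecA subject wins and the conflict is tallied —
the community search only *confirms* the product, it does not vote on
taxonomy.

For translated (protein) searches no alignment-length fraction is applied by
default; where a length fraction is needed the nucleotide convention
(aligned nucleotides over read length) is used. The spiked-standard filters
are applied sequentially exactly as listed, so a borderline read must pass
the nucleotide screen before the protein screen ever sees it.

## Community summaries

Genome equivalents are binned at the family level by exact summation
(`bin_by_family()`; unmapped taxa go to an explicit `unclassified` family)
and classified as dominant (> 10⁸ cells L⁻¹), abundant (> 10⁷), minor
(> 10⁶) or rare. Thresholds are strict, so a value of exactly 10⁶ is rare —
the boundaries are measure-zero in practice and the literal reading keeps
the rule auditable. Classes are assigned per sample; a cross-sample mean can
be classified separately if a single label per family is wanted.
`rank_recruitment()` ranks reference bins per sample with competition
ranking (ties share the best rank), which is deterministic and standard.

## Ordination

`composition_matrix()` computes percent composition on the *full* family
table, restricts to the top-*n* families (default 100, ranked by overall
abundance), replaces zeros by 0.001 *percent* (so the floor after log10 is
−3), and log10-transforms. The zero replacement is interpreted in percent
units because it is applied to percentages; this is half the smallest
plausible nonzero percentage at the read depths the pipeline targets and the
ordination is insensitive to its exact value within an order of magnitude.

`pca_ordination()` is a first-party SVD on the centered, unit-variance
matrix. Zero-variance columns cannot be scaled and are dropped with a
warning. Component signs are fixed by making each loading vector's
largest-magnitude entry positive; the sign of a singular vector is otherwise
arbitrary and deterministic output matters more than any particular
orientation.

`permanova()` square-root transforms non-negative community data, computes
Bray–Curtis dissimilarity ($d = \sum|x_i - y_i| / \sum(x_i + y_i)$), and
partitions squared distances into total and within-group sums,

$$F = \frac{(SS_T - SS_W)/(g-1)}{SS_W/(n-g)},$$

with $SS_T = \frac{1}{n}\sum_{i<j} d_{ij}^2$ and
$SS_W = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d_{ij}^2$. The p-value is
$(1 + \#\{F_{perm} \ge F_{obs}\})/(1 + n_{perm})$ under random relabeling
with a mandatory seed. The default input is family *proportions* (not
volumetric abundances): the square-root/Bray–Curtis recipe is a
composition-level analysis, and proportions keep library-depth differences
out of the distance. Volumetric input is possible by passing the abundances
directly; the log-transformed PCA matrix can also be supplied through the
`distance` argument if a user wants the two analyses on identical input.
Bray–Curtis is semimetric, so no triangle-inequality property is asserted
anywhere.

`dispersion_test()` guards PERMANOVA against heterogeneity artifacts. The
distance matrix is embedded by principal coordinates (Gower double
centering); axes with negative eigenvalues are retained separately and their
squared contributions are *subtracted* from squared deviations — the
standard imaginary-part correction for semimetric distances. Each sample's
deviation is its distance to its group *centroid* (not spatial median:
simpler and deterministic), and group differences in mean deviation are
tested with a one-way F. The null distribution permutes the *group labels*
and recomputes centroids and deviations for every permutation. Permuting
precomputed deviations (as some reference implementations do) ignores the
fact that deviations are residuals from group-fitted centers, and we found
it measurably anti-conservative at small group sizes, while label
permutation holds the nominal level in the package's own calibration tests.

## The simulator

The synthetic-data module makes every downstream stage testable against a
known truth. It emulates:

* a reference collection of `n_taxa` taxa in `n_families` families, genome
  lengths log-uniform on 1.3–9 Mbp, one protein gene per kilobase, exactly
  one *recA* per genome, plus three non-community standard genomes (2.1, 3.2
  and 6.1 Mbp) spiked at 4 ng each, converted to molecules by
  `molecules_added()`;
* a two-year survey of five regions ordered west → east; per-taxon
  log-normal baselines rescaled to a target community total (default
  1.5 × 10⁹ cells L⁻¹, typical of productive surface seawater; admissible
  range 10⁸–10¹⁰); a multiplicative west–east gradient spanning
  `10^gradient_log10_span` for designated families, log-linear in site rank
  and centered on 1 so that the gradient shifts composition without
  inflating community totals; year-1 multipliers for designated indicator
  families (an El Niño-type shift — in the tests three families drop 10×
  while three rise 10×, mirroring warm-water taxa being replaced by
  upwelling-associated taxa);
* per-sample log-normal noise of 0.3 log10 units per taxon — the survey
  design gives no within-site replicate variance model, so this is a free,
  configurable parameter set to a moderate default;
* sequencing as a single multinomial draw of `reads_per_sample` reads over
  (taxon, standard) categories, a taxon's weight being its gene molecules
  (cells L⁻¹ × V × gene count) and a standard's being $S_a \times S_p$;
  *recA* reads are binomial within a taxon's reads with probability
  1/(gene count), enforcing single-copy semantics exactly;
* annotation noise: a `misannotation_rate` fraction of community reads
  (default 1%) receives a bit score below 50 and is lost to the filters, and
  a `dual_hit_rate` fraction (default 1%) receives an independent viral hit,
  half of which out-score the bacterial hit and are relabeled. Both defaults
  are small because the pipeline's boundary is *annotated* reads; reads that
  would fail annotation outright are upstream of it. The estimator therefore
  inherits a downward bias equal to the annotation-loss fraction (≈1.5% at
  the defaults) — visible, intended, and well inside the ±3% recovery
  budget the tests enforce.

Reads are simulated at the annotation level — hit-table rows, not
nucleotide sequences. `format = "hits"` materializes per-read BLAST-style
tables (with read-length tables and reconstructable protein titles) for
exercising the filtering stage; `format = "counts"` collapses the identical
model to per-category counts for large designs. What the simulator does
*not* emulate: sequencing error models, assembly, chimeras, database
incompleteness, or taxonomic mis-binning between related taxa. Passing
tests therefore demonstrate that the *computational* pipeline recovers known
inputs under its stated sampling model — not that any particular real
annotation database is adequate.

## Hydrography

Mixed-layer depth is the shallowest depth where the potential density
anomaly exceeds the surface value by 0.35 kg m⁻³. Potential density uses the
UNESCO (EOS-80) one-atmosphere polynomial with potential temperature from
the standard adiabatic-lapse Runge–Kutta scheme; the implementation
reproduces the published check values of both to their printed precision,
and for the shallow casts this pipeline targets the pressure correction is
minute. "Surface" means the shallowest valid record — casts rarely sample
0 m. The crossing depth is linearly interpolated between bracketing records
by default (`mode = "bin"` returns the first record past the threshold, for
comparison with bin-resolution conventions), and when the threshold is never
exceeded the deepest depth is returned with an `extends_beyond_profile`
flag. Mixed-layer temperature and salinity are depth-weighted trapezoidal
means over the layer — exact for linear profiles and robust to irregular
sampling grids, unlike a plain record mean.

## Problem sizes and numerical conventions in the tests

The package's test suite validates end-to-end parameter recovery on 24
samples × 50 families at 10⁶ reads per sample; the detection-limit Poisson
property on 500 samples with a taxon pinned at one fifth of the detection
limit; %CV depth scaling over 10⁴–10⁷ reads; PERMANOVA against exhaustive
enumeration at n = 6, type-I error over 1,000 null simulations (199
permutations each), and ≥90% power on the simulated year shift over 20
seeds; the dispersion test's calibration over 1,000 equal-dispersion nulls;
and PCA/PCoA against independent eigendecompositions at 10⁻⁸. These sizes
were chosen so each property is sharply testable at interactive timescales.
All simulation entry points take explicit seeds and reruns are
byte-identical.

## Known limitations

* One *recA* per genome is assumed throughout; no copy-number correction for
  other marker choices is provided.
* The viral override arbitrates only between one bacterial and one viral
  retained hit per read; richer multi-database arbitration is out of scope.
* PERMANOVA is one-way; stratified or multi-factor designs are not
  implemented.
* The dispersion test uses centroids, which can differ from implementations
  that default to spatial medians.
* The simulator's annotation noise is taxon-independent; real
  misannotation is phylogenetically structured.
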