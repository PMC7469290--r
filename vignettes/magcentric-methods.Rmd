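---
title: "Genome-centric rumen metagenome analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-centric rumen metagenome analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magcentric)
```

`magcentric` implements a genome-centric analysis of rumen shotgun
metagenomes built around metagenome-assembled genomes (MAGs): quality
filtering and two-stage average-nucleotide-identity (ANI)
dereplication, sketch-based uniqueness analysis, bias-corrected MAG
abundance estimation, community-structure statistics with a bootstrap
power analysis, negative-binomial differential abundance under a
crossover feeding design, and the attribution of shifts in community
functional potential to differentially abundant taxa. Everything
downstream of binning is covered; read trimming, assembly, binning,
read mapping and the annotation databases themselves are upstream
inputs consumed as tables.

This vignette explains the models, their assumptions, the tunable
parameters and the numerical choices. It states no empirical result
that the package's tests and acceptance script do not themselves
compute.

## The study design the package assumes

The motivating setting is a crossover feeding trial: six Boran steers
fed at 40%, 60%, 80% and 100% of maintenance energy requirement (MER)
over four periods, one rumen sample per animal per period
(`crossover_design()`, 24 samples). Two exclusions are applied by
`filter_samples()` before any diet comparison: period-1 samples
(stored without cryoprotectant, a storage batch confounder) and 100%
MER samples (a compositionally different ration). This leaves 14
samples in a 4:5:5 split across 40:60:80% MER; animal and period enter
every downstream model as batch covariates.

## Genome comparison and dereplication

Genomes are compared through canonical k-mers (k = 21, the
lexicographic minimum of a k-mer and its reverse complement). A
MinHash sketch (`sketch_genome()`) keeps the `s` smallest values of a
seeded 64-bit hash over the distinct canonical k-mers (default
`s = 100000`, hash seed 42; both configurable, and sketches are only
comparable at equal settings). The Jaccard similarity `j` of two
k-mer sets is estimated by the merged bottom-`s` rule and converted to
a Mash distance `d = min(1, -(1/k) ln(2j/(1+j)))`; percent identity is
`(1 - d) * 100` and ANI is `1 - d`.

`dereplicate()` follows the two-stage workflow standard for MAG
catalogues:

1. **Primary clusters** at 90% ANI: average-linkage hierarchical
   clustering of Mash distances, cut at `d = 0.10`. The primary stage
   uses sketch size 1000 - the Mash default of the dereplication tools
   this mirrors - because at a 10% ANI threshold the estimate is far
   more precise than the decision it feeds.
2. **Secondary clusters** at 99% ANI within each primary cluster. The
   original workflow uses whole-genome alignment here; at desk scale
   this package substitutes the Mash transform of the **exact** full
   k-mer Jaccard (no subsampling). For substitution-only synthetic
   genomes the k-mer estimate is tight at 99% ANI, which is what the
   tests exercise; for real genomes with indels and repeats an
   alignment-based ANI would differ, and this substitution is the
   package's main deliberate deviation from the original tooling.

One winner per secondary cluster is retained, the genome with the
highest score `S = completeness - 5 contamination +
contamination * (strain heterogeneity / 100) + 0.5 log10(N50)` (ties
broken by lexicographic genome id). The score is the published default
of the dereplication tool the workflow cites; the weight on genome
size is zero. The preceding quality gate (`filter_quality()`) keeps
genomes with completeness >= 80% and contamination <= 10%, both
boundaries inclusive. Neither the linkage criterion nor the score
weights are stated in the study this design mirrors; average linkage
and the tool's published defaults are adopted and recorded here rather
than inferred from results.

`min_distance_to_set()` supports the uniqueness analysis: for each
query genome the nearest reference by Mash distance (self-comparisons
excluded when ids overlap), with counts of queries reaching
percent-identity thresholds such as 90%.

## Abundance estimation

`correct_bias()` removes contig-level GC and length bias within each
sample: counts become count-per-kb rates, contigs are stratified into
ten equal-frequency GC bins (ties broken by contig id), and the
per-bin median rates - anchored at the bin median GC and centred on
the log scale - are interpolated into a smooth per-sample GC-bias
curve; each rate is divided by the curve at its contig's GC, rescaled
by length, and the sample total is restored, so correction never
changes library size. The normalisation package named by the
motivating study offers several variants without stating which was
used. An earlier design of this step used within-sample full-quantile
normalisation across the GC strata; it was replaced because quantile
mapping couples features through their ranks - when a substantial
minority of contigs genuinely shifts between diets, the per-sample
reference distribution shifts with them and high-abundance null
contigs inherit diet-correlated corrections, producing convincing but
spurious differential abundance downstream. The median-curve
correction keeps the testable contract (GC decorrelation at planted
monotone bias, exact no-op when strata share a distribution, totals
preserved, invariance to length at fixed coverage density) while
being robust to differentially abundant tails, since bin medians
ignore them.

`aggregate_to_mag()` sums each MAG's contig counts.  `hellinger()`
takes the square root of relative abundance, so each sample has unit
sum of squares and Euclidean distances become ecologically meaningful.
`remove_batch()` then removes animal and period effects feature-wise
via `limma::removeBatchEffect`, keeping intercept and diet components,
in the stated order (transform, then batch-correct). Full aliasing
between a batch variable and the kept variable - in either direction -
is an error, since the components are then inseparable.
`phylum_relative_abundance()` computes per-sample phylum percentages
first and then averages within diets, reading "average abundance per
diet treatment" as a mean of per-sample relative abundances (the
alternative, pooling counts before converting to percentages, weights
samples by depth).

## Community structure

`permanova()` uses Anderson's partitioning on squared distances:
`SS_total = sum_{i<j} d_ij^2 / N`, within-group sums scaled by group
size, and `pseudo-F = (SS_between/(a-1)) / (SS_within/(N-a))` with
`R2 = SS_between/SS_total`. P-values come from free permutation of
sample labels (9999 by default) with the add-one convention counting
strict exceedances, `p = (1 + #[F_perm > F_obs])/(n_perm + 1)`. Strict
counting matters: a permutation occasionally reproduces the observed
partition and hence its exact F, and counting that tie would make the
attainable minimum p irreproducible. A `strata` argument restricts
permutations within blocks (e.g. animals); free permutation is the
default because animal and period are removed before testing.
`pairwise_permanova()` applies the same test to each group pair and
adjusts across pairs with Benjamini-Hochberg. `pcoa()` is classical
metric scaling (double-centred Gram matrix eigendecomposition via
`cmdscale`), with axis variance fractions over the positive
eigenvalues and a warning when material negative eigenvalues indicate
a non-Euclidean input.

### Bootstrap power analysis

`permanova_power()` estimates the power of candidate designs (3:3:3,
4:4:4, 4:5:5, 5:5:5 samples per diet) by resampling the transformed,
batch-corrected matrix, recomputing Euclidean distances, and running a
PERMANOVA per resampled matrix; power at a level is the fraction of
matrices with `p <= alpha`, and its distribution comes from
bootstrapping the per-matrix indicators (the median is reported).

A plain within-group bootstrap is anti-conservative three ways:
duplicated samples have zero mutual distance and always fall inside a
group, inflating F; the chance group-mean differences of a finite null
data set are re-detected as if real; and chance within-group
dispersion differences persist across resamples. Resampled columns are
therefore built as `overall mean + c * group-mean deviation + pooled
residual draw + smoothing noise`: residuals are pooled across groups,
the shrinkage `c = max(0, 1 - E[noise]/SS_between)` estimates how much
observed separation exceeds its sampling noise (near 0 for
exchangeable data, near 1 for separated groups), and Gaussian noise
with `bandwidth` times the pooled residual standard deviation keeps
duplicate draws distinct. The default bandwidth of 1 doubles the
within-group variance, so power estimates are deliberately slightly
conservative. Under a null generator the median power then sits at the
significance level, and power grows with design size on separated
data - both properties the acceptance suite checks at 200 matrices and
999 permutations per matrix (the full-scale analysis the defaults
describe uses 1000 matrices and 10000 permutations).

## Differential abundance

`nb_lrt()` tests each feature (MAG or KO) with negative-binomial GLMs
(log link), offset by log median-of-ratios size factors
(`size_factors()`, normalised to geometric mean 1), comparing the full
design `~ period + animal + diet` against the reduced
`~ period + animal` by likelihood ratio, `chi^2` with df = 2 for three
diets. Fold changes per contrast (40 vs 80, 60 vs 80) come from the
full-model diet coefficients with 80% MER as reference. Fitting uses
iteratively reweighted least squares (`glm.fit` with
`MASS::negative.binomial`, dispersion held fixed, maximum 100
iterations, deviance tolerance 1e-8); aliased design columns are
dropped deterministically (first occurrence kept); non-converging
features are flagged, get `NA` p-values and are excluded from the BH
adjustment. This is a transparent, fully specified pipeline rather
than the shrinkage machinery of the package the motivating study used;
it is sufficient for binary differential-abundance calls at the scales
tested here, and that substitution is deliberate.

Dispersion (`estimate_dispersion()`) starts from per-feature moment
estimates `alpha = max(floor, (var - mean)/mean^2)` on normalised,
design-residualised counts (floor 1e-8). With only four residual
degrees of freedom in the crossover design these are noisy, and a
fixed-dispersion LRT with noisy dispersions is anti-conservative. The
default therefore moderates toward a common dispersion calibrated so
the aggregate Pearson statistic of design-fitted NB models matches its
degrees of freedom (weights: residual df vs `prior_df = 50`), while
features whose raw estimate exceeds twice the common value keep their
own estimate so genuinely dispersed features are never tested too
liberally. `method = "feature"` exposes the raw moment estimator.
With this default the null type-I error of the LRT sits inside the
0.03-0.07 band at the 14-sample design, which the acceptance suite
verifies on 2000 simulated null features.

## Functional potential and attribution

Annotation hits are filtered with the study's published gates:
KEGG-ortholog (KO) hits at identity >= 50% and E-value < 1e-5; CAZyme
hits at coverage >= 35% and E-value < 1e-18 (identity and coverage
inclusive, E-value strict). `build_annotation_matrix()` counts one hit
per (protein, target), keeping the lowest-E hit per pair, so a
multi-domain protein can contribute one site per distinct family.
`cazy_module_percentages()` and `phylum_cazy_proportions()` summarise
the six CAZy modules (GH, GT, PL, CE, AA, CBM, read off the family
prefix) dataset-wide and per phylum; `cazy_family_heatmap_input()`
prepares the standard log(count+1) heatmap with columns ordered by
average-linkage clustering on one minus the Spearman correlation of
per-taxon mean profiles and rows in taxonomy order (constant columns,
whose correlation is undefined, go last and are flagged).

`ko_per_sample()` forms the community functional potential as the
matrix product of per-MAG KO copy numbers and per-sample MAG
abundance, rounded to integers because the downstream count model
requires them (the motivating study passed scaled counts to a count
model without stating its rounding). `aggregate_pathways()` sums KOs
into pathway modules; a KO in several modules counts in each, and
unmapped KOs fall into an explicit `unassigned` bucket.

`taxon_contribution()` restricts the functional potential to the
differentially abundant MAGs, aggregates by taxonomic group, pathway
and diet, and reports `lfc = log2((count_low + c)/(count_high + c))`
with pseudocount `c = 1` (contribution counts can be zero and the
original tables do not state their zero-handling). Two defaults
deserve note. First, columns are library-size normalised
(median-of-ratios over all MAGs) and diets aggregated as per-sample
means: raw within-diet sums would carry a `log2(4/5) = -0.32`
offset purely from the unequal retained group sizes, plus depth noise.
`normalize = FALSE` reproduces literal sums for hand-checkable
examples. Second, `total` rows carry the total-over-groups fold change
- the shift attributable to the DA MAGs as a whole.

`classify_scenarios()` contrasts, per pathway and contrast, the
overall shift (pooled counts of the pathway's significantly DA KOs,
FDR < 0.05) with the attributable shift, at a threshold of 0.5 on
|log2 fold change| (the source analysis classifies qualitatively; a
numeric gate is needed for a testable contract, and 0.5 is
configurable):

* **agreement** - both shifts meet the threshold with the same sign;
* **disconnect** - both meet it with opposite signs, or a meaningful
  attributable shift runs against an overall change of opposite sign
  even when the latter is small (this covers the canonical example of
  a -0.13 overall against a +1.34 attributable shift);
* **attribution-only** - no significant KO in the pathway (or no
  meaningful same-sign overall change) despite a meaningful
  attributable shift;
* **none** - otherwise.

## The synthetic community generator

`simulate_study()` generates a complete input bundle with recorded
ground truth so every stage is testable without downloads. Its
defaults are the study conditions, chosen once:

* **Metadata**: the bundled 24-sample crossover design.
* **Genomes** (`simulate_genomes()`): substitution-only mutation from
  ancestors (no indels, keeping ANI analytically controlled).
  Primary-cluster ancestors are mutated from a common root at rate
  0.12 (pairwise divergence about 22%, safely above the 10% cut);
  secondary-cluster ancestors within a primary cluster diverge at rate
  0.03 (pairwise about 6%, between the cuts); genomes within a
  secondary cluster at `d_secondary/2 = 0.0025` each (pairwise about
  0.5%, under the 1% cut). Quality metrics straddle the 80/10 gate
  (completeness uniform on 70-100, contamination on 0-15). The
  catalogue preset (`simulate_genomes_preset()`) reproduces the
  published cluster-size distribution - 1200 genomes in 850 secondary
  clusters - at 4 kb per genome, a length at which the binomial noise
  of substitution counts keeps within-cluster divergence far from the
  1% boundary, so dereplication recovers the planted partition
  exactly.
* **Counts** (`simulate_counts()`): negative-binomial with
  `variance = mu + alpha mu^2` (matching the downstream model),
  log-linear mean with per-MAG baselines (log-normal, meanlog
  `log(150)` per contig kb, sdlog 0.8), planted per-MAG log2 fold
  changes versus the 80% diet, additive animal (sd 0.3) and period
  (sd 0.15) log-scale batch effects, log library depth (sd 0.3),
  contig length offsets and a monotone GC bias
  `exp(2 (gc - 0.5))`. Dispersion defaults to 0.1, a moderate
  overdispersion typical of metagenomic counts; 5 contigs per MAG,
  lengths 2-20 kb, GC 0.30-0.70. Nine DA MAGs (6 up, 3 down) at
  |log2 fold change| = 2 are planted by default.
* **Annotations** (`simulate_annotations()`): KO copy numbers are
  derived from abundance-weighted target masses per pathway block
  (`default_scenario_spec()`), so the expected KO-per-sample totals
  hit the planted design regardless of the random baselines. The
  blocks plant the three interplay scenarios plus a null: two
  agreement pathways, one disconnect pathway (a significant negative
  KO block beside a positively shifted but heavily diluted one), one
  attribution-only pathway (DA carriage swamped by background), and an
  exactly balanced housekeeping block (down-mass equal to four times
  up-mass offsets a +/-2 fold change). Background carriage is
  concentrated in two non-DA carrier MAGs - pathway specialists - so
  the planted attribution signal is insensitive to which non-DA MAGs a
  downstream analysis might occasionally misclassify. Ground-truth
  scenario labels are derived analytically from the realised copy
  numbers and baselines using the same classification rule the
  pipeline applies, fed with expected rather than estimated
  quantities. The CAZy matrix uses deterministic phylum-specific
  module mixtures so planted proportions are recovered exactly.

What the generator does **not** emulate: indels, repeats and mobile
elements (so sketch ANI is exact by construction), read-level noise
and mapping ambiguity, compositionality constraints, taxon
correlations, and dispersion heterogeneity across features. Passing
tests therefore demonstrate correctness of the implemented
statistics under the stated model, not robustness to every property of
real rumen data.

## Problem sizes and stochastic margins

The test and acceptance workloads are sized for a single CPU: the
catalogue preset dereplicates 1200 x 4 kb genomes; sketch accuracy is
checked on 100 kb genome pairs against an exact string-enumeration
oracle; PERMANOVA calibration uses 500 null replicates at the
14-sample design; the differential-abundance null uses 2000 features
and the recovery run 300 MAGs with 30 planted; power analysis uses 200
resampled matrices at 999 permutations. The full-scale defaults
(sketch 100000, 9999 permutations, 1000 matrices at 10000
permutations) remain the documented settings for real analyses.

Two checks are intrinsically stochastic at about the 5% level: a
truly-null KO can clear the BH gate and perturb a pathway's overall
fold change, and calibration fractions sit in finite bands. The
planted designs keep safety margins (exact balanced nulls, carrier
concentration, effect sizes well above thresholds) so that scenario
recovery and calibration hold across seeds, but an occasional boundary
seed is possible; the quantities are recomputed from scratch at every
run rather than asserted.

## Known limitations

* Secondary-stage ANI is k-mer-based, not alignment-based; on real
  genomes with structural variation the two differ near the 99% cut.
* The NB pipeline has no fold-change shrinkage, outlier replacement or
  independent filtering; all features enter the BH adjustment.
* The scenario gate (0.5 log2 fold change) is a package choice where
  the source analysis classified qualitatively.
* Bootstrap power is slightly conservative by construction (smoothing
  widens within-group variance), which is the safer direction for
  design planning.
* `ko_per_sample()` treats annotation copy numbers as exact; annotation
  noise propagates multiplicatively and is not modelled.
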