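# magcentric

Genome-centric analysis of rumen metagenomes built around
metagenome-assembled genomes (MAGs).

Shotgun metagenomics of the rumen yields hundreds of draft genomes per
study, and the interesting biology lives in what happens *between*
them: which genomes are redundant assemblies of the same organism,
how novel a catalogue is relative to existing rumen genome
collections, how community structure and functional potential respond
to diet, and whether a community-wide functional shift is driven by a
few differentially abundant taxa or by the whole microbiome moving at
once. `magcentric` implements that workflow for the common setting of
a crossover feeding trial (animals fed several diets over successive
periods, here 40/60/80/100% of maintenance energy requirement, MER),
from binning output to pathway-level attribution. It is aimed at
microbiome researchers who have contig counts, genome quality metrics
and annotation tables in hand and want a tested, scriptable analysis
rather than a chain of one-off tools.

## What it computes

* **Dereplication** — quality gate (completeness >= 80%,
  contamination <= 10%), MinHash sketches over canonical 21-mers, Mash
  distances `d = -(1/21) ln(2j/(1+j))`, primary clusters at 90% ANI
  (average linkage), secondary clusters at 99% ANI from exact k-mer
  Jaccard, and one winner per cluster by the score
  `S = completeness - 5 contamination +
  contamination (strain heterogeneity / 100) + 0.5 log10(N50)`.
* **Novelty** — minimum Mash distance of each genome to a reference
  set, with percent-identity threshold counts.
* **Abundance** — contig counts corrected for GC and length bias
  (per-sample GC-median curve, totals preserved), aggregated to MAGs,
  Hellinger transformed (square root of relative abundance), and
  batch-corrected for animal and period.
* **Community structure** — Euclidean distances, principal coordinate
  analysis, PERMANOVA (pseudo-F, R2, permutation p with 9999
  permutations), pairwise tests with Benjamini-Hochberg correction,
  and a noise-adjusted bootstrap power analysis over candidate designs
  (3:3:3 ... 5:5:5 samples per diet).
* **Differential abundance** — negative-binomial likelihood-ratio
  tests of `~ period + animal + diet` against `~ period + animal`
  with median-of-ratios size factors and moderated moment dispersions,
  giving per-feature log2 fold changes for 40 vs 80 and 60 vs 80% MER.
* **Functional attribution** — KO and CAZyme hit filtering, per-MAG
  profiles, the KO-per-sample functional potential
  (`copy number x abundance`), pathway aggregation, taxon-group
  contribution fold changes restricted to the differentially abundant
  MAGs, and classification of each pathway into **agreement**,
  **disconnect**, **attribution-only** or **none** by contrasting the
  overall functional shift with the DA-attributable shift.
* **Synthetic community** — a generator (`simulate_study()`,
  `simulate_genomes()`) producing genomes with planted ANI structure,
  NB counts with GC/length bias and batch effects, and annotation
  matrices with planted interplay scenarios, all with recorded ground
  truth, so the whole pipeline is testable end to end.

## Worked example

A complete synthetic study with nine planted differentially abundant
MAGs (six up, three down at |log2 fold change| = 2 in the restricted
diets) and planted pathway scenarios:

```r
library(magcentric)

st <- simulate_study(seed = 1)                  # 60 MAGs, 24 samples
md <- filter_samples(st$metadata)               # drop period 1, 100% MER
corrected <- correct_bias(st$counts, st$contigs)
abundance <- aggregate_to_mag(corrected, st$contigs)[, md$sample_id]

# community structure on transformed, batch-corrected abundances
h   <- remove_batch(hellinger(abundance), md)
fit <- permanova(euclidean_distances(h), md$diet, n_perm = 9999, seed = 1)
fit
#> PERMANOVA: pseudo-F = 73.013 (df 2, 11), R2 = 0.930, p = 0.0001 (9999 perms)
```

Diet explains 93% of the between-sample variance here and the
permutation p-value sits at its attainable minimum — the planted diet
effect dominates this synthetic community.

```r
da  <- nb_lrt(abundance, md)     # NB LRT: ~period+animal+diet vs ~period+animal
sig <- da_features(da)
sig$summary
#> # A tibble: 2 × 5
#>   contrast n_total  n_up n_down n_zero
#>   <chr>      <int> <int>  <int>  <int>
#> 1 40vs80         9     6      3      0
#> 2 60vs80         9     6      3      0
```

All nine planted MAGs are recovered, with the correct 6:3 split of
fold-change signs and no false positives. Scaling per-MAG KO copy
numbers by abundance and contrasting the overall functional shift with
the part attributable to the DA MAGs classifies each pathway:

```r
ks  <- ko_per_sample(st$ko_matrix, abundance)
kda <- nb_lrt(ks, md)
ct  <- taxon_contribution(st$ko_matrix, abundance, st$taxonomy, md,
                          st$pathway_map,
                          da_mags = sig$features$feature_id)
sc  <- classify_scenarios(kda, ks, ct, st$pathway_map, md)
subset(as.data.frame(sc), contrast == "40vs80")
#>                   pathway n_sig_kos overall_lfc attributable_lfc         scenario
#> 1   amino_acid_metabolism         8       1.095           1.7081        agreement
#> 2       energy_metabolism         6       0.768           1.6165        agreement
#> 3 carbohydrate_metabolism         3      -1.432           1.0378       disconnect
#> 4   nucleotide_metabolism         0          NA           1.5280 attribution-only
#> 5            housekeeping         0          NA           0.0441             none
```

Reading the rows: amino-acid and energy metabolism shift up overall
*and* within the DA MAGs (agreement); carbohydrate metabolism shifts
down overall while the DA MAGs' carbohydrate content shifts up
(disconnect); nucleotide metabolism shows no significant KO overall
yet a strong DA-attributable shift (attribution-only); the
housekeeping block moves nowhere. These match the generator's planted
ground truth (`st$truth$scenarios`).

The methods vignette (`vignettes/magcentric-methods.Rmd`) documents
the models, parameter defaults and numerical choices in detail.

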