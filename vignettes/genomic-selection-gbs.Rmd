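---
title: "Genomic selection for half-sib parent breeding values from GBS data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic selection for half-sib parent breeding values from GBS data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsgbs)
```

## The problem

Breeding perennial outbreeding forage crops such as alfalfa for biomass
yield is slow: narrow-sense heritability of yield is low (published
estimates around 0.15–0.30), selection cycles based on half-sib progeny
testing take about five years, and the crop's severe inbreeding depression
rules out line breeding. Genomic selection — training a whole-genome
regression of parent breeding values on dense markers, then selecting new
parents on marker data alone — can shorten the cycle to roughly one year
(genotyping plus polycrossing). Whether it is worthwhile hinges on the
accuracy `r_A` with which marker models predict parent breeding values, as
inferred from the yield of dense-planted half-sib progenies.

`gsgbs` implements that full analysis chain at desk scale:

1. **Tag-pair SNP calling** (`demultiplex_trim()`, `discover_tag_pairs()`,
   `call_genotypes()`, `call_snps()`): reference-free genotyping from
   barcoded single-end GBS reads.
2. **Missing-data QC** (`filter_missing()`, `impute()`, `filter_maf()`,
   `build_common()`, `qc_pipeline()`).
3. **Phenotype adjustment** (`estimate_variance_components()`,
   `heritability_progeny_mean()`, `blup_adjust()`).
4. **Prediction models** (`gs_fit()` with rrBLUP, Bayes A/B, Bayesian
   Lasso, linear/Gaussian SVR, random forest regression).
5. **Evaluation** (`cross_validate()`, `cross_population_predict()`,
   `run_benchmark_grid()`, `gain_ratio()`).
6. **Association** (`kinship_matrix()`, `mixed_model_gwas()`,
   `manhattan_export()`).
7. **Synthetic data** (`simulate_population()` and friends), so every
   stage is testable without sequencing data.

## Reference-free SNP calling

GBS reads begin with a sample barcode followed by the restriction-site
remnant (ApeKI leaves `CWGC`, `W` matching A or T). Reads carrying a known
barcode and the remnant are trimmed to a 64-bp *tag*; identical tags are
aggregated into per-sample counts. Tags with at least 10 reads across all
individuals are compared pairwise, and a pair differing at exactly one
base defines a candidate biallelic SNP. Tags that would enter more than
one pair form ambiguous networks — the signature of paralogous or
repetitive sequence — and are discarded, keeping only reciprocal unique
pairs.

Genotypes are called from the per-individual read counts of the two tags
of a pair. Alfalfa is autotetraploid; its three heterozygous dosage
classes (`Aaaa`, `AAaa`, `AAAa`) are deliberately collapsed into the
single pseudo-diploid heterozygote code 1, so every marker is coded
\{0, 1, 2, missing\}. The read-depth rule is configurable because the
published pipelines leave it implicit: with fewer than `min_depth = 3`
total reads the call is missing; with at least `het_min_minor_reads = 2`
reads of each allele it is heterozygous; otherwise it is homozygous for
the majority allele. These defaults are conservative surrogates chosen
before any benchmarking; they can be changed per call.

Two calling strategies are supported by `call_snps()`: `separate`
(discovery and calling per cohort) and `joint` (discovery on the pooled
reads, genotype matrix split back per cohort). Joint calling is the only
way to get consistent SNP naming across cohorts without a reference
genome; marker names are a deterministic hash of the sorted tag pair, so
they are stable across runs and data sets. Allele orientation is likewise
reference-free: the lexicographically smaller tag is the reference allele.
Variant positions are 0-based within the tag internally and 1-based in the
VCF written by `write_genotype_vcf()`.

## Missing-data QC

The pipeline order is fixed and mirrors standard GBS practice: filter
markers whose missing rate exceeds a threshold (grid
`r paste(missing_threshold_grid(), collapse = ", ")`), impute what
remains, then drop markers with minor allele frequency below 2.5%.
Retention is inclusive at the boundary in both filters (missing rate
`<=` threshold, MAF `>=` cut-off).

Three imputers are first-class:

* **MNI** — per-marker mean of observed values;
* **SVDI** — regression of each marker on the `k = 10` leading left
  singular vectors of the mean-completed matrix (if the matrix rank is
  lower, the rank is used);
* **RFI** — iterative random-forest regression per marker on all other
  markers (`ntree = 100`, `maxiter = 10`), stopping early when fewer than
  0.5% of imputed cells change between iterations.

All imputed values are discretized to the closer value in \{0, 1, 2\};
ties at 0.5 and 1.5 round toward the heterozygote, which absorbs three of
the five tetraploid dosage classes and is therefore the maximum-prior
call. A fourth imputer slot, `LHCI_SURROGATE`, exists only so the full
2 x 4 x 6 benchmarking grid shape is reproducible: haplotype-order-based
reference imputers need a physical marker order, which unordered tag-pair
markers do not have, so the slot applies mean imputation after a random
permutation of marker order and is labelled a surrogate in all output.

For two jointly-called cohorts, `qc_pipeline(..., joint = TRUE)` filters
and imputes the stacked matrix — giving the imputer the pooled information
of both cohorts — and splits the result back. The COMMON marker set for
cross-population work is the by-name intersection of the two post-QC
matrices.

## Progeny-trial BLUP

Parent phenotypes are shrunken half-sib progeny means from a randomized
complete block trial. A two-way (progeny + block) ANOVA provides the
expected-mean-square estimators `s2_e = MS_error` and
`s2_hs = (MS_progeny - MS_error) / r`; negative `s2_hs` estimates are
truncated to zero with a warning, the standard practice that keeps the
progeny-mean heritability

$$h_B^2 = \frac{S_{hs}^2}{S_{hs}^2 + S_e^2 / r}$$

inside [0, 1]. Adjusted values are
`grand mean + h_B2 * (progeny mean - grand mean)`; shrinkage preserves the
grand mean and the ranking exactly and scales the variance by `h_B2^2`.
Incomplete-block (lattice) recovery is deliberately not implemented:
replications are treated as complete blocks, the common procedure the
analysis chain assumes for both of its populations.

## Prediction models

All models share the contract `gs_fit(G, y, model)` /
`predict(fit, G_new)` on complete \{0,1,2\} matrices.

**rrBLUP.** The additive model `y = mu + G u + e` with
`u ~ N(0, I sigma2_u)` is solved in its dual form
`u_hat = G'(GG' + lambda I)^{-1}(y - mu)`, where
`lambda = sigma2_e / sigma2_u`. `lambda` is estimated by restricted
maximum likelihood profiled over the variance ratio after one spectral
decomposition of `GG'` (`reml_variance_ratio()`), so each likelihood
evaluation is O(n) after an O(n^3) setup. `mu` is the phenotype mean;
marker columns are centered for conditioning (in exact arithmetic the fit
is identical) and predictions re-add `mu`. The primal identity
`(G'G + lambda I)^{-1} G'(y - mu)` is the test oracle.

**Bayesian alphabet.** Gibbs samplers with the study chain settings
(5000 iterations, 500 burn-in, thinning 5): Bayes A places a scaled-t
prior on each effect via per-marker variances; Bayes B adds a point mass
at zero with prior weight `pi0 = 0.95`; the Bayesian Lasso uses the
exponential scale-mixture representation of the double-exponential prior
with a Gamma hyper-prior on the regularization parameter. Hyper-prior
values are not printed by the software conventions this follows, so the
package uses the conventional additive-variance heuristic (prior modes
split `var(y)` 50:50 between markers and residual; marker-variance df
4.2); all are arguments. Reported effects are posterior means of the
thinned post-burn-in samples.

**SVR.** Epsilon-insensitive support vector regression (`C = 1`,
`epsilon = 0.1`) with linear or Gaussian kernel, via the libsvm engine in
`e1071`. The Gaussian bandwidth uses the median pairwise-distance
heuristic (unstated upstream, standard choice); the solver tolerance is
1e-3.

**RFR.** Random forest regression with `ntree = 500`,
`mtry = ceiling(p/3)`, `min_node = 5` via `randomForest`.

## Accuracy evaluation

`cross_validate()` repeats a random 90/10 genotype split 500 times,
fitting on the training split and scoring the Pearson correlation between
predicted and observed phenotypes on the validation split; reported
accuracy is the mean over repetitions (the per-repetition values and SD
are kept, though only the mean has an external counterpart).
Per-repetition seeds derive from the master seed by a counter scheme, so
grids parallelize and reproduce exactly. Repetitions with constant
predictions score r = 0 rather than being dropped, keeping the report
shape deterministic.

Two numerical points deserve note:

* **Null calibration.** Permuting the phenotype once and averaging over
  splits does *not* give zero expected accuracy: the fixed permutation's
  chance association with the genotypes (order `1/sqrt(n)`) is common to
  all splits. `cross_validate(permute_y = TRUE)` therefore re-permutes
  before every repetition, which gives an exactly centred null.
* **Accuracy ceilings.** With `m` exchangeable markers the expected CV
  accuracy is roughly `sqrt(h2) * sqrt(n h2 / (n h2 + Me))` with
  `Me ~ m`; at `n = 300`, `m = 1000`, `h2 = 0.5` that is about 0.26. Real
  GBS panels are heavily redundant (many tags per segment), which is what
  the generator's LD-block option models; the package's benchmark
  scenario for signal recovery uses blocks of 10 markers with 5%
  within-block noise and 50 QTL, for which the same formula puts rrBLUP
  accuracy near 0.6.

`cross_population_predict()` trains on all genotypes of one population
and predicts the other on the COMMON marker set, z-normalizing phenotypes
within population first (the two populations are phenotyped on different
scales and durations). `run_benchmark_grid()` enumerates calling strategy
x imputer x threshold x model x population — the full study grid is
2 x 4 x 6 = 48 configurations per population per model — and
`gain_ratio()` computes the selection-gain comparison
`(r_A / cycle_gs) / (h_N / cycle_conv)` with `h_N = sqrt(h_N2)` rounded
to two decimals by default; at `r_A = 0.32`, `h_N2 = 0.21` and 1- vs
5-year cycles the ratio is 3.48, i.e. over three-fold.

## Kinship and association

`kinship_matrix()` is the centered cross-product (VanRaden-type)
relatedness `ZZ' / (2 sum p_j (1 - p_j))` on the pseudo-diploid codes —
symmetric and positive semi-definite by construction, used both as a
structure diagnostic and as the random-effect covariance.
`mixed_model_gwas()` uses the population-parameters-previously-determined
scheme: variance components are estimated once under the no-marker null,
the data are whitened by `(K + delta I)^{-1/2}`, and each marker is then
an ordinary two-column regression with a t-test on `n - 2` degrees of
freedom. The overall variance scale cancels in the statistic, and with
`K = I` the procedure reduces exactly to per-marker simple linear
regression — a property the tests check. Markers without a genome
alignment are displayed on the fictitious chromosome `N` with sequential
pseudo-positions (`manhattan_export()`); no multiple-testing threshold is
imposed, though a Bonferroni column is emitted as a convenience.

## The synthetic-data generator

`simulate_population()` draws founder allele frequencies (default uniform
on (0.1, 0.9), the range typical of MAF-filtered GBS panels), then
genotypes: in the default tetraploid-collapsed mode, dosages are
Binomial(4, p) per individual (autotetraploid Hardy-Weinberg) and classes
1–3 collapse to code 1, mirroring the calling convention while retaining
realistic heterozygote read fractions for the read simulator. A trait is
built from `n_qtl` marker effects; noise is scaled so
`var(BV)/var(y)` targets the requested `h2` (at `h2 = 0` the phenotype is
pure noise — no finite noise added to a non-degenerate breeding value can
drive the ratio to zero). `simulate_two_populations()` shares one panel
and QTL set between cohorts, with a Balding–Nichols frequency
perturbation (Fst-like `freq_divergence`) and a configurable fraction of
shared QTL effects. `simulate_progeny_trial()` emits plot values
`grand mean + block + family effect + error` with the family effect
scaled to `s2_hs`; a quarter of that variance is a Mendelian/finite-family
sampling term by default, so progeny-based accuracy against parent
breeding values is meaningful rather than tautological. Block variance is
`s2_e / 4` by default (zero plot error then implies identical replicate
values exactly). `mask_missing()` draws per-marker missing rates from a
Beta(1, 2) law by default — marker-specific rates are what make threshold
filtering non-degenerate. `simulate_tag_reads()` writes FASTQ reads
(barcode + 64-bp tag beginning with the cut-site remnant, fixed base
qualities) with per-cell negative-binomial depth (size 5) and binomial
allocation of reads to the two tags by true dosage fraction.

What the generator does **not** emulate: realistic LD decay along
chromosomes (blocks are exchangeable unless the block option is used),
selection history, quality-score realism, or full 100-bp reads. Passing
tests therefore demonstrate the correctness and calibration of the
machinery, not field-data accuracy levels; the published accuracy values
derive from real sequencing data and are used here only as directional
properties.

## Problem sizes and determinism

Every stochastic routine takes an explicit seed, and sub-seeds are derived
by name/counter hashing (`derive_seed()`), so identical seeds reproduce
all outputs bit-exactly and adding a stage never perturbs another. The
package's own benchmark scenarios use: 500 repetitions for the null
calibration (n = 300, m = 1000); 100 repetitions for rrBLUP and 20 for
RFR signal recovery (forest fits dominate the cost and their repetition
error is small relative to the effect being checked); 80 x 100 matrices at
30% missingness for the imputation comparison; 30 individuals x 60 markers
at mean depth 60 for the calling round trip; and 2000 markers or progenies
for the association-calibration and variance-recovery checks. These sizes
are the package's choices for a desk-scale demonstration and are stated
here so they can be scaled up.

## Known limitations

* Genotype calls are pseudo-diploid by design; true tetraploid dosage
  calling is out of scope.
* The BLUP adjustment assumes complete blocks; lattice recovery and
  spatial or repeated-measures modelling are not implemented.
* The Gibbs samplers are plain R loops: adequate at desk scale
  (seconds to tens of seconds per fit), not tuned for 100k-marker panels.
* `run_benchmark_grid()` caches QC per grid cell but fits models serially.
* Association output reports no genome alignment of tags; chromosome
  assignments must come from a user-supplied map, otherwise all markers
  sit on chromosome `N`.
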