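# gsgbs — genomic selection for parent breeding values from GBS data

`gsgbs` is an R implementation of a complete genomic-selection analysis
for outbreeding autotetraploid forage crops (the motivating case is
alfalfa biomass yield), where parent breeding values are inferred from the
yield of dense-planted half-sib progenies and markers come from
genotyping-by-sequencing (GBS) without a reference genome.

It covers, as composable functions:

* **Reference-free SNP calling** — barcoded reads are trimmed to 64-bp
  tags, tags with ≥ 10 reads are matched into pairs differing at exactly
  1 bp, and genotypes are called pseudo-diploid: the three autotetraploid
  heterozygote classes (Aaaa, AAaa, AAAa) collapse to one code, so markers
  live in {0, 1, 2, missing}. Separate and joint calling across cohorts
  are supported; joint calling guarantees shared SNP names.
* **Missing-data QC** — threshold filtering (grid 0.10–0.70), imputation
  by marker means (MNI), SVD regression (SVDI) or iterative random
  forests (RFI), then a 2.5% minor-allele-frequency filter; plus the
  COMMON cross-population marker intersection.
* **Progeny-trial BLUP** — ANOVA variance components, progeny-mean
  heritability `h_B² = S²_hs / (S²_hs + S²_e / r)`, and shrinkage of
  progeny means by `h_B²`.
* **Seven prediction models** under one `gs_fit()`/`predict()` contract:
  ridge-regression BLUP solved by the closed form
  `û = G′(GG′ + λI)⁻¹(y − μ)` with λ from spectral REML; Bayes A, Bayes B
  and the Bayesian Lasso by Gibbs sampling (5000 iterations, 500 burn-in,
  thinning 5); ε-insensitive support vector regression (C = 1, ε = 0.1,
  linear or Gaussian kernel); and random forest regression (500 trees,
  mtry = p/3, node size 5).
* **Evaluation** — repeated 90/10 cross-validation (500 repetitions,
  Pearson accuracy), cross-population prediction with within-population
  z-normalization, the full calling × imputer × threshold × model
  benchmark grid (2 × 4 × 6 = 48 configurations per population), and the
  genomic-vs-conventional gain comparison `(r_A/1) vs (h_N/5)`.
* **Association** — VanRaden kinship and EMMAX-style mixed-model GWAS
  with Manhattan-ready export (unaligned markers on the fictitious
  chromosome "N").
* **Synthetic data** — populations with tetraploid-collapsed dosages,
  polygenic traits at a target heritability, optional LD blocks,
  half-sib progeny trials, per-marker missingness masks, and FASTQ-level
  GBS read simulation, so the whole pipeline runs and is tested without
  any external data.

## Worked example

Simulate one reference population at the scale of a typical half-sib
panel, phenotype it through a replicated progeny trial, QC the markers,
and estimate genomic prediction accuracy:

```r
library(gsgbs)

spec <- population_spec(n_individuals = 124, n_markers = 2000, n_qtl = 100,
                        h2 = 0.21, ld_block_size = 10, ld_within_noise = 0.05,
                        seed = 20)
pop <- simulate_population(spec)

trial <- simulate_progeny_trial(pop$model$breeding_values, r = 2,
                                s2_hs = 1, s2_e = 2, seed = 21)
y <- blup_phenotypes(trial)
attr(y, "h_B2")
#> [1] 0.491

G_missing <- mask_missing(pop$genotypes, missing_rate_beta(), seed = 22)
G <- qc_pipeline(G_missing, threshold = 0.5, imputer = "MNI")
attr(G, "qc_report")
#>            stage n_markers
#> 1          input      2000
#> 2 missing_filter      1491
#> 3        imputed      1491
#> 4     maf_filter      1491

acc <- cross_validate(G, y[rownames(G)], model = "rrBLUP",
                      n_reps = 100, seed = 23)
acc
#> Cross-validation accuracy: mean r = 0.258 (sd 0.283, 100 reps, rrBLUP)

gain_ratio(acc$mean_r, 0.21)
#> Gain per unit time, genomic vs conventional: (0.26/1) / (0.46/5) = 2.803
```

Read line by line: the progeny trial separates family from plot variance
well enough to shrink progeny means by `h_B² ≈ 0.49`; half-marker
missingness at the 0.50 threshold leaves 1491 of 2000 markers; ridge BLUP
predicts the BLUP-adjusted phenotypes of held-out parents at r ≈ 0.26 — in
line with what a 0.21-heritability trait supports at this sample size —
and even that modest accuracy yields a ~2.8-fold advantage in predicted
gain per year over a 5-year phenotypic cycle.

A YAML-configured end-to-end run (two populations, QC, cross-validation,
cross-population prediction, GWAS, gain comparison, with a reproducible
manifest) is available through `validate_config()` + `run_pipeline()`.

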