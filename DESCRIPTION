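Package: gsgbs
Title: Genomic Selection for Parent Breeding Values from
    Genotyping-by-Sequencing Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: A desk-scale pipeline for genomic selection in outbreeding
    autotetraploid forage crops phenotyped through half-sib progeny
    trials.  Covers reference-free tag-pair SNP discovery and
    pseudo-diploid genotype calling from barcoded genotyping-by-sequencing
    (GBS) reads, missing-data threshold filtering with mean, SVD-regression
    and iterative random-forest imputation, BLUP shrinkage of progeny-trial
    phenotypes, seven whole-genome prediction models (ridge-regression
    BLUP with spectral REML, Bayes A, Bayes B, Bayesian Lasso, linear and
    Gaussian support vector regression, random forest regression),
    repeated random-split cross-validation and cross-population accuracy
    evaluation on common marker sets, kinship-based mixed-model
    association, and the genomic-versus-conventional selection gain
    comparison.  A synthetic-data module generates populations, progeny
    trials, missing-data masks and GBS read sets with the statistical
    structure the analysis assumes, so the whole pipeline is testable
    without external sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    kernlab,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
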