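#' Repeated random-split cross-validation accuracy
#'
#' Per repetition, genotypes are split at random into a training fraction
#' (default 90%) and a validation fraction (10%); the model is fitted on
#' the training split and accuracy is the Pearson correlation between
#' predicted and observed phenotypes on the validation split.  The
#' procedure is repeated `n_reps` times (default 500) and accuracies are
#' averaged.  Repetitions with constant predictions or constant validation
#' phenotypes score r = 0 (with one summary warning) rather than being
#' dropped, so the report shape is deterministic.  Per-repetition seeds are
#' derived from the master seed by a counter scheme ([derive_seed()]).
#'
#' @param G complete genotype matrix.
#' @param y phenotype vector.
#' @param model model tag, see [gs_fit()].
#' @param params model hyperparameters.
#' @param train_frac training fraction (default 0.9).
#' @param n_reps number of repetitions (default 500).
#' @param seed master seed.
#' @param permute_y null-calibration mode: freshly permute the phenotype
#'   vector before each repetition's split, so the expected accuracy is
#'   exactly zero.  A single fixed permutation would not do: its chance
#'   association with the genotypes (of order `1/sqrt(n)`) is shared by all
#'   splits and does not average out over repetitions.
#' @param config optional named list describing the grid cell this run
#'   belongs to (stored in the report).
#' @return an `accuracy_report`: list with `config`, `per_rep_r`, `mean_r`,
#'   `sd_r`, `n_reps`.
#' @export
cross_validate <- function(G, y, model = "rrBLUP", params = list(),
                           train_frac = 0.9, n_reps = 500L, seed = 1L,
                           permute_y = FALSE, config = list()) {
  n <- nrow(G)
  n_val <- round((1 - train_frac) * n)
  if (n_val < 3L) stop("validation set must contain at least 3 individuals")
  rs <- numeric(n_reps)
  n_degenerate <- 0L
  y_obs <- y
  for (i in seq_len(n_reps)) {
    rep_seed <- derive_seed(seed, paste0("cv_rep_", i))
    set.seed(rep_seed)
    if (permute_y) y <- sample(y_obs)
    val <- sample.int(n, n_val)
    fit <- gs_fit(G[-val, , drop = FALSE], y[-val], model = model,
                  params = params, seed = rep_seed)
    pred <- predict(fit, G[val, , drop = FALSE])
    if (stats::sd(pred) == 0 || stats::sd(y[val]) == 0) {
      n_degenerate <- n_degenerate + 1L
      rs[i] <- 0
    } else {
      rs[i] <- stats::cor(pred, y[val])
    }
  }
  if (n_degenerate > 0L) {
    warning(n_degenerate, " repetition(s) had constant predictions; scored r = 0")
  }
  structure(list(config = c(config, list(model = model,
                                         train_frac = train_frac)),
                 per_rep_r = rs, mean_r = mean(rs), sd_r = stats::sd(rs),
                 n_reps = n_reps),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("Cross-validation accuracy: mean r = %.3f (sd %.3f, %d reps, %s)\n",
              x$mean_r, x$sd_r, x$n_reps, x$config$model))
  invisible(x)
}

#' Cross-population prediction accuracy
#'
#' Trains a model on all genotypes of one population and predicts the
#' phenotypes of the other, both matrices restricted to the COMMON marker
#' set with identical column order ([build_common()]).  Phenotypes are
#' z-normalized within each population before the analysis, as the two
#' populations are phenotyped on different scales.
#'
#' @param G_train,y_train training population data.
#' @param G_test,y_test target population data.
#' @param model,params,seed see [gs_fit()].
#' @return Pearson correlation between predictions and normalized observed
#'   phenotypes of the target population.
#' @export
cross_population_predict <- function(G_train, y_train, G_test, y_test,
                                     model = "rrBLUP", params = list(),
                                     seed = 1L) {
  if (!identical(colnames(G_train), colnames(G_test))) {
    stop("marker-name mismatch: restrict both populations to the COMMON set")
  }
  zt <- (y_train - mean(y_train)) / stats::sd(y_train)
  zv <- (y_test - mean(y_test)) / stats::sd(y_test)
  fit <- gs_fit(G_train, zt, model = model, params = params, seed = seed)
  pred <- predict(fit, G_test)
  stats::cor(pred, zv)
}

#' Enumerate and run the calling x imputation x threshold x model grid
#'
#' One accuracy report per combination of SNP calling strategy, imputation
#' algorithm, missing-data threshold, model and population.  The study
#' grid - 2 strategies x 4 imputers x 6 thresholds - yields 48
#' configurations per population per model.  With `dry_run = TRUE` only
#' the configuration table is returned (no fitting).
#'
#' For the `joint` strategy, filtering and imputation run on the stacked
#' two-cohort matrix and are split back per population; for `separate`,
#' each population's own calling output is processed alone.
#'
#' @param cohorts named list: one element per population, each a list with
#'   components named after the strategies (genotype matrices with missing
#'   data) plus `phenotype`.
#' @param strategies,imputers,thresholds,models grid axes; defaults are the
#'   full study grid with `rrBLUP`.
#' @param n_reps cross-validation repetitions per cell.
#' @param train_frac training fraction.
#' @param maf_min MAF cut-off applied after imputation.
#' @param seed master seed.
#' @param imputer_params,model_params parameter lists keyed by imputer /
#'   model tag.
#' @param dry_run return the enumerated configuration table only.
#' @return a tidy data frame, one row per configuration, with marker count
#'   and mean/sd accuracy columns (`NA` in a dry run).
#' @export
run_benchmark_grid <- function(cohorts,
                               strategies = c("separate", "joint"),
                               imputers = c("MNI", "SVDI", "RFI",
                                            "LHCI_SURROGATE"),
                               thresholds = missing_threshold_grid(),
                               models = "rrBLUP",
                               n_reps = 10L, train_frac = 0.9,
                               maf_min = 0.025, seed = 1L,
                               imputer_params = list(),
                               model_params = list(),
                               dry_run = FALSE) {
  pops <- names(cohorts)
  stopifnot(!is.null(pops))
  grid <- expand.grid(population = pops, strategy = strategies,
                      imputer = imputers, threshold = thresholds,
                      model = models, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid$n_markers <- NA_integer_
  grid$mean_r <- NA_real_
  grid$sd_r <- NA_real_
  grid$n_reps <- if (dry_run) NA_integer_ else as.integer(n_reps)
  if (dry_run) return(grid)

  for (pop in pops) {
    for (s in strategies) {
      if (is.null(cohorts[[pop]][[s]])) {
        stop("missing pre-computed calling output for population '", pop,
             "', strategy '", s, "'")
      }
    }
  }

  # cache QC'd matrices per (strategy, imputer, threshold)
  qc_cache <- new.env(parent = emptyenv())
  get_qc <- function(strategy, imp, thr) {
    key <- paste(strategy, imp, thr, sep = "|")
    if (!is.null(qc_cache[[key]])) return(qc_cache[[key]])
    qseed <- derive_seed(seed, paste0("qc_", key))
    res <- if (strategy == "joint") {
      mats <- lapply(cohorts, `[[`, "joint")
      qc_pipeline(mats, threshold = thr, imputer = imp, maf_min = maf_min,
                  joint = TRUE, params = imputer_params[[imp]] %||% list(),
                  seed = qseed)
    } else {
      lapply(stats::setNames(pops, pops), function(pop) {
        qc_pipeline(cohorts[[pop]][[strategy]], threshold = thr,
                    imputer = imp, maf_min = maf_min,
                    params = imputer_params[[imp]] %||% list(), seed = qseed)
      })
    }
    qc_cache[[key]] <- res
    res
  }

  for (i in seq_len(nrow(grid))) {
    row <- grid[i, ]
    mats <- get_qc(row$strategy, row$imputer, row$threshold)
    Gq <- mats[[row$population]]
    y <- cohorts[[row$population]]$phenotype
    rep_seed <- derive_seed(seed, paste(row$population, row$strategy,
                                        row$imputer, row$threshold,
                                        row$model, sep = "|"))
    rep_ <- cross_validate(Gq, y, model = row$model,
                           params = model_params[[row$model]] %||% list(),
                           train_frac = train_frac, n_reps = n_reps,
                           seed = rep_seed)
    grid$n_markers[i] <- ncol(Gq)
    grid$mean_r[i] <- rep_$mean_r
    grid$sd_r[i] <- rep_$sd_r
  }
  grid
}

#' Genomic vs. conventional selection gain comparison
#'
#' Predicted yield gain per unit time of genomic selection relative to
#' conventional half-sib progeny-test selection at equal selection
#' intensity reduces to comparing `r_A / cycle_gs` with
#' `h_N / cycle_conv`, where `r_A` is the genomic prediction accuracy of
#' breeding values and `h_N` the square root of narrow-sense heritability
#' (rounded to `hn_digits` decimals, default 2).  With the study values
#' `r_A = 0.32`, `h_N^2 = 0.21` (`h_N = 0.46`) and 1- vs. 5-year cycles
#' the ratio is about 3.48 - over three-fold.
#'
#' @param r_A genomic prediction accuracy of breeding values, in (0, 1].
#' @param h_N2 narrow-sense heritability, in (0, 1].
#' @param cycle_gs,cycle_conv cycle lengths in years (defaults 1 and 5).
#' @param hn_digits decimals `h_N` is rounded to (default 2; `NULL` for no
#'   rounding).
#' @return an object of class `gain_comparison` with fields `r_A`, `h_N`,
#'   `cycle_gs`, `cycle_conv`, `ratio`.
#' @export
gain_ratio <- function(r_A, h_N2, cycle_gs = 1, cycle_conv = 5,
                       hn_digits = 2) {
  if (r_A <= 0 || r_A > 1) stop("r_A must lie in (0, 1]")
  if (h_N2 <= 0 || h_N2 > 1) stop("h_N2 must lie in (0, 1]")
  if (cycle_gs <= 0 || cycle_conv <= 0) stop("cycle lengths must be positive")
  h_N <- sqrt(h_N2)
  if (!is.null(hn_digits)) h_N <- round(h_N, hn_digits)
  structure(list(r_A = r_A, h_N = h_N, cycle_gs = cycle_gs,
                 cycle_conv = cycle_conv,
                 ratio = (r_A / cycle_gs) / (h_N / cycle_conv)),
            class = "gain_comparison")
}

#' @export
print.gain_comparison <- function(x, ...) {
  cat(sprintf(
    "Gain per unit time, genomic vs conventional: (%.2f/%g) / (%.2f/%g) = %.3f\n",
    x$r_A, x$cycle_gs, x$h_N, x$cycle_conv, x$ratio))
  invisible(x)
}
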