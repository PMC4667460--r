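test_that("cross-validation recovers a perfect single-marker signal", {
  G <- toy_geno(60, 20, seed = 1)
  y <- as.numeric(G[, 7])   # noiseless marker trait
  rep_ <- cross_validate(G, y, "rrBLUP", n_reps = 20, seed = 2)
  expect_gt(rep_$mean_r, 0.99)
  expect_equal(rep_$mean_r, mean(rep_$per_rep_r))
  expect_true(all(abs(rep_$per_rep_r) <= 1))
  # study defaults: 90/10 splits repeated 500 times
  expect_equal(eval(formals(cross_validate)$train_frac), 0.9)
  expect_equal(formals(cross_validate)$n_reps, 500L)
})

test_that("cross-validation reports are reproducible and sized correctly", {
  G <- toy_geno(50, 30, seed = 3)
  y <- rnorm(50)
  a <- cross_validate(G, y, n_reps = 10, seed = 7)
  b <- cross_validate(G, y, n_reps = 10, seed = 7)
  expect_identical(a$per_rep_r, b$per_rep_r)
  expect_equal(a$n_reps, 10)
  expect_error(cross_validate(G[1:10, ], y[1:10], n_reps = 2,
                              train_frac = 0.95), "at least 3")
})

test_that("per-repetition permutation gives a centred null", {
  G <- toy_geno(100, 200, seed = 4)
  y <- rnorm(100)
  rep0 <- cross_validate(G, y, "rrBLUP", n_reps = 100, seed = 5,
                         permute_y = TRUE)
  expect_lt(abs(rep0$mean_r), 0.08)
})

test_that("accuracy increases with simulated heritability", {
  accs <- sapply(c(0.1, 0.6), function(h2) {
    pop <- simulate_population(population_spec(
      150, 300, 30, h2 = h2, ld_block_size = 5, ld_within_noise = 0.05,
      seed = 17))
    cross_validate(pop$genotypes, pop$phenotype, n_reps = 40,
                   seed = 6)$mean_r
  })
  expect_gt(accs[2], accs[1])
})

test_that("cross-population prediction is scale-free and name-checked", {
  pop <- simulate_population(population_spec(80, 150, 20, h2 = 0.6, seed = 9))
  G <- pop$genotypes; y <- pop$phenotype
  acc_same <- cross_population_predict(G, y, G, y)
  # identical populations: equals the in-sample fit accuracy
  fit <- gs_fit(G, (y - mean(y)) / sd(y), "rrBLUP")
  expect_equal(acc_same, cor(predict(fit, G), (y - mean(y)) / sd(y)))
  # Pearson invariance under affine rescaling of the target phenotypes
  expect_equal(cross_population_predict(G, y, G, 3 * y + 10), acc_same)
  Gb <- G; colnames(Gb) <- paste0("x", colnames(G))
  expect_error(cross_population_predict(G, y, as_genotype_matrix(Gb), y),
               "mismatch")
})

test_that("shared-architecture populations cross-predict close to intra", {
  two <- simulate_two_populations(
    population_spec(300, 800, 40, h2 = 0.5, ld_block_size = 8,
                    ld_within_noise = 0.05, seed = 1),
    population_spec(300, 800, 40, h2 = 0.5, ld_block_size = 8,
                    ld_within_noise = 0.05, seed = 2),
    shared_qtl_fraction = 1, freq_divergence = 0.03, seed = 9)
  common <- build_common(two$a$genotypes, two$b$genotypes)
  acc_cross <- cross_population_predict(common$a, two$a$phenotype,
                                        common$b, two$b$phenotype)
  acc_intra <- cross_validate(two$b$genotypes, two$b$phenotype,
                              n_reps = 40, seed = 3)$mean_r
  expect_gt(acc_cross, 0)
  expect_gt(acc_cross, 0.5 * acc_intra)
  expect_lt(abs(acc_cross - acc_intra), 0.15)
})

test_that("the benchmark grid enumerates the full factorial", {
  two <- simulate_two_populations(
    population_spec(50, 150, 15, h2 = 0.4, seed = 1),
    population_spec(55, 150, 15, h2 = 0.4, seed = 2),
    shared_qtl_fraction = 1, freq_divergence = 0.05, seed = 4)
  law <- missing_rate_beta()
  cohorts <- list(
    PV = list(separate = mask_missing(two$a$genotypes, law, seed = 1),
              joint = mask_missing(two$a$genotypes, law, seed = 2),
              phenotype = two$a$phenotype),
    Me = list(separate = mask_missing(two$b$genotypes, law, seed = 3),
              joint = mask_missing(two$b$genotypes, law, seed = 4),
              phenotype = two$b$phenotype))

  # minimal 1x1x1 grid: one report per population
  one <- run_benchmark_grid(cohorts, strategies = "separate",
                            imputers = "MNI", thresholds = 0.5,
                            n_reps = 3, seed = 5)
  expect_equal(nrow(one), 2)
  expect_true(all(is.finite(one$mean_r)))

  # 2 x 2 x 3 toy grid: cartesian-product count, all cells populated
  grid <- run_benchmark_grid(cohorts, strategies = c("separate", "joint"),
                             imputers = c("MNI", "SVDI"),
                             thresholds = c(0.3, 0.5, 0.7),
                             n_reps = 3, seed = 5)
  expect_equal(nrow(grid), 2 * 2 * 3 * 2)
  expect_true(all(is.finite(grid$mean_r)))
  expect_true(all(grid$n_markers > 0))

  # a missing strategy is reported by name
  broken <- cohorts; broken$PV$joint <- NULL
  expect_error(run_benchmark_grid(broken, n_reps = 2, dry_run = FALSE),
               "PV.*joint")
})

test_that("gain comparison arithmetic and guards", {
  expect_equal(gain_ratio(0.5, 1, 1, 5)$ratio, 2.5)
  expect_equal(gain_ratio(0.4, 0.16, 3, 3)$ratio, 1)  # r_A = h_N, same cycle
  expect_error(gain_ratio(0, 0.2), "r_A")
  expect_error(gain_ratio(0.3, 0), "h_N2")
  expect_error(gain_ratio(0.3, 0.2, cycle_gs = -1), "positive")
})
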