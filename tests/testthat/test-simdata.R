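test_that("heritability limits behave: noiseless, pure-noise and intermediate", {
  # h2 = 1: phenotype equals breeding values exactly
  pop1 <- simulate_population(population_spec(100, 200, 20, h2 = 1, seed = 3))
  expect_equal(unname(pop1$phenotype), unname(pop1$model$breeding_values))

  # h2 = 0: no genetic signal in the trait
  pop0 <- simulate_population(population_spec(1000, 100, 20, h2 = 0, seed = 4))
  expect_lt(abs(cor(pop0$phenotype, pop0$model$breeding_values)), 0.1)

  # h2 = 0.5: realized variance ratio (direct variance bookkeeping)
  pop5 <- simulate_population(population_spec(500, 200, 30, h2 = 0.5, seed = 5))
  ratio <- var(pop5$model$breeding_values) / var(pop5$phenotype)
  expect_gte(ratio, 0.40)
  expect_lte(ratio, 0.60)
})

test_that("realized heritability converges to the target at n = 2000", {
  pop <- simulate_population(population_spec(2000, 300, 50, h2 = 0.3, seed = 11))
  r2 <- cor(pop$phenotype, pop$model$breeding_values)^2
  expect_lt(abs(r2 - 0.3), 0.05)
})

test_that("population specs validate and reproduce bit-exactly", {
  expect_error(population_spec(50, 100, 200), "n_qtl")
  expect_error(population_spec(50, 100, 10, h2 = 1.2), "h2")
  spec <- population_spec(40, 60, 10, h2 = 0.4, seed = 77)
  a <- simulate_population(spec)
  b <- simulate_population(spec)
  expect_identical(unclass(a$genotypes), unclass(b$genotypes))
  expect_identical(a$phenotype, b$phenotype)
  expect_identical(a$model$qtl_effects, b$model$qtl_effects)
})

test_that("tetraploid dosages collapse to the pseudo-diploid coding", {
  pop <- simulate_population(population_spec(60, 80, 10, seed = 6))
  G <- pop$genotypes
  D <- attr(G, "dosage")
  expect_true(all(G %in% 0:2))
  expect_true(all(D %in% 0:4))
  expect_true(all(G[D == 0] == 0))
  expect_true(all(G[D == 4] == 2))
  expect_true(all(G[D %in% 1:3] == 1))
  # breeding values are sums of effects times the collapsed codes
  bv <- as.numeric(G[, pop$model$qtl_indices] %*% pop$model$qtl_effects)
  expect_equal(unname(pop$model$breeding_values), bv)
})

test_that("progeny trials have the declared variance structure", {
  bv <- rnorm(300)
  expect_error(simulate_progeny_trial(bv, r = 0), "replication")
  expect_error(simulate_progeny_trial(bv, s2_hs = -1), "variance")

  # zero plot error: the r replicate values of each progeny are identical
  tr0 <- simulate_progeny_trial(bv, r = 3, s2_hs = 1, s2_e = 0, seed = 2)
  spread <- tapply(tr0$plot_value, tr0$progeny_id, function(v) diff(range(v)))
  expect_true(all(spread == 0))

  # zero family variance: var of progeny means ~ s2_e / r (closed form)
  tr1 <- simulate_progeny_trial(rnorm(2000), r = 2, s2_hs = 0, s2_e = 2,
                                seed = 3)
  m1 <- tapply(tr1$plot_value, tr1$progeny_id, mean)
  expect_lt(abs(var(m1) - 2 / 2) / (2 / 2), 0.15)
})

test_that("mask_missing respects its rate law and never edits observed cells", {
  G <- toy_geno(100, 100, seed = 8)
  G00 <- mask_missing(G, 0, seed = 1)
  expect_identical(as.vector(unclass(G00)), as.vector(unclass(G)))
  expect_identical(dimnames(G00), dimnames(G))
  expect_true(all(is.na(mask_missing(G, 1, seed = 1))))
  expect_error(mask_missing(G, 1.4, seed = 1), "rates")

  Gm <- mask_missing(G, 0.3, seed = 9)
  frac <- mean(is.na(Gm))
  ci <- 2.576 * sqrt(0.3 * 0.7 / length(G))
  expect_lt(abs(frac - 0.3), ci)
  obs <- !is.na(Gm)
  expect_identical(unclass(Gm)[obs], unclass(G)[obs])

  # marker-specific beta rates leave the threshold grid non-degenerate
  Gb <- mask_missing(G, missing_rate_beta(), seed = 10)
  expect_gt(sd(marker_missing_rate(Gb)), 0.05)
})

test_that("two-population draws share panel and architecture as requested", {
  sa <- population_spec(50, 200, 20, h2 = 0.5, seed = 1)
  sb <- population_spec(60, 200, 20, h2 = 0.5, seed = 2)
  expect_error(simulate_two_populations(sa, sb, shared_qtl_fraction = 2),
               "shared_qtl_fraction")
  two <- simulate_two_populations(sa, sb, 1, 0, seed = 4)
  expect_identical(colnames(two$a$genotypes), colnames(two$b$genotypes))
  expect_identical(two$a$model$qtl_effects, two$b$model$qtl_effects)
  expect_identical(two$a$model$qtl_indices, two$b$model$qtl_indices)
  half <- simulate_two_populations(sa, sb, 0.5, 0.1, seed = 4)
  expect_equal(mean(half$a$model$qtl_effects == half$b$model$qtl_effects), 0.5)
})

test_that("simulated reads follow the dosage-mixture binomial allocation", {
  pop <- simulate_population(population_spec(12, 20, 4, seed = 21))
  # empty library at depth zero
  rd0 <- simulate_tag_reads(pop$genotypes, depth_law = 0, seed = 1)
  expect_equal(rd0$n_reads, 0)

  # force every individual heterozygous at a single-marker panel with
  # known dosage 1 (alt fraction 1/4): binomial oracle on the read split
  G <- as_genotype_matrix(matrix(1L, 50, 1))
  attr(G, "dosage") <- matrix(1L, 50, 1)
  rd <- simulate_tag_reads(G, depth_law = function(k) rep(100L, k), seed = 5)
  tab <- demultiplex_trim(rd$fastq, rd$key_file)
  alt_reads <- sum(tab$counts[, rd$panel$tag_alt])
  total <- sum(tab$counts)
  ci <- 2.576 * sqrt(0.25 * 0.75 / total)
  expect_lt(abs(alt_reads / total - 0.25), ci)

  # homozygous reference, no errors: only reference-tag reads
  Gh <- as_genotype_matrix(matrix(0L, 10, 2))
  rdh <- simulate_tag_reads(Gh, depth_law = 10, error_rate = 0, seed = 6)
  tabh <- demultiplex_trim(rdh$fastq, rdh$key_file)
  expect_true(all(tabh$tags %in% rdh$panel$tag_ref))

  # invalid panels are rejected
  Gbad <- toy_geno(5, 2, seed = 1)
  attr(Gbad, "markers") <- data.frame(
    name = c("a", "b"), chrom = "N", pos = 1:2,
    tag_ref = c(strrep("A", 64), strrep("C", 63)),
    tag_alt = c(strrep("A", 64), strrep("C", 63)), tag_pos0 = c(1L, 1L))
  expect_error(simulate_tag_reads(Gbad, depth_law = 5, seed = 1),
               "invalid panel")
})
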