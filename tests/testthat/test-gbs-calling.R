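test_that("demultiplexing trims to 64 bp tags and drops foreign reads", {
  tag1 <- fixed_tag(1)
  key <- data.frame(flowcell = "F", lane = 1,
                    barcode = c("ACGTAC", "TTGGCC"),
                    sample_id = c("s1", "s2"), stringsAsFactors = FALSE)
  fq <- write_toy_fastq(c(
    paste0("ACGTAC", tag1), paste0("ACGTAC", tag1), paste0("ACGTAC", tag1),
    paste0("TTGGCC", tag1),
    paste0("GGGGGG", tag1),                   # unknown barcode
    paste0("ACGTAC", "TTTT", substr(tag1, 5, 64)),  # no cut-site remnant
    paste0("ACGTAC", mutate_at(tag1, 30, "N"))      # ambiguous base
  ))
  tab <- demultiplex_trim(fq, key)
  expect_s3_class(tab, "tag_count_table")
  expect_true(all(nchar(tab$tags) == 64))
  expect_equal(unname(tab$counts["s1", tag1]), 3)
  expect_equal(unname(tab$counts["s2", tag1]), 1)
  expect_equal(sum(tab$counts), 4)

  key_dup <- key; key_dup$barcode <- c("ACGTAC", "ACGTAC")
  expect_error(demultiplex_trim(fq, key_dup), "duplicate")
  expect_warning(tab0 <- demultiplex_trim(write_toy_fastq(character(0)), key),
                 "empty")
  expect_equal(length(tab0$tags), 0)
})

test_that("tag pairing honours the read threshold and 1-bp rule", {
  t1 <- fixed_tag(2)
  t2 <- mutate_at(t1, 40, setdiff(c("A", "C", "G", "T"),
                                  substr(t1, 40, 40))[1])
  t3 <- fixed_tag(3)                      # far from t1/t2
  t4 <- mutate_at(t1, 40, setdiff(c("A", "C", "G", "T"),
                                  substr(t1, 40, 40))[2])  # ambiguous with t1/t2
  counts <- matrix(c(12, 9, 30, 0), nrow = 1,
                   dimnames = list("s1", c(t1, t2, t3, t4)))
  # t2 has only 9 reads: below threshold, no pair emitted
  expect_equal(nrow(discover_tag_pairs(tag_count_table(counts), 10)), 0)
  # lowering the threshold pairs t1-t2; raising it never adds SNPs
  p5 <- discover_tag_pairs(tag_count_table(counts), 5)
  expect_equal(nrow(p5), 1)
  expect_setequal(c(p5$tag_ref, p5$tag_alt), sort(c(t1, t2)))
  expect_equal(p5$tag_pos0, 39L)

  # brute-force Hamming oracle: emitted pairs are exactly the unique
  # distance-1 pairs among retained tags
  set.seed(9)
  tags <- unique(replicate(12, fixed_tag(sample.int(1e6, 1))))
  tags <- c(tags, mutate_at(tags[1], 20, "A"), mutate_at(tags[2], 64, "A"))
  tags <- unique(tags)
  cnt <- matrix(20L, nrow = 1, ncol = length(tags),
                dimnames = list("s1", tags))
  got <- discover_tag_pairs(tag_count_table(cnt), 10)
  hd <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  want <- t(combn(tags, 2))
  want <- want[apply(want, 1, function(r) hd(r[1], r[2]) == 1), , drop = FALSE]
  occ <- table(as.vector(want))
  want <- want[occ[want[, 1]] == 1 & occ[want[, 2]] == 1, , drop = FALSE]
  expect_equal(nrow(got), nrow(want))
  expect_setequal(paste(got$tag_ref, got$tag_alt),
                  paste(pmin(want[, 1], want[, 2]),
                        pmax(want[, 1], want[, 2])))

  # ambiguous three-tag network (t1~t2, t1~t4, t2~t4 at one site): dropped
  cnt3 <- matrix(20L, nrow = 1, ncol = 3, dimnames = list("s1", c(t1, t2, t4)))
  expect_equal(nrow(discover_tag_pairs(tag_count_table(cnt3), 10)), 0)
})

test_that("genotype calls follow the depth and minor-read rules", {
  expect_true(is.na(call_genotypes(0, 0)))
  expect_equal(call_genotypes(12, 0, min_depth = 3), 0L)
  expect_equal(call_genotypes(0, 12, min_depth = 3), 2L)
  expect_equal(call_genotypes(10, 10), 1L)
  expect_equal(call_genotypes(c(5, 1, 2), c(1, 5, 2), min_depth = 3,
                              het_min_minor_reads = 2),
               c(0L, 2L, 1L))
  expect_error(call_genotypes(-1, 3), "non-negative")
})

test_that("joint calling shares SNP names and rescues cross-cohort markers", {
  t1 <- fixed_tag(4)
  t2 <- mutate_at(t1, 50, setdiff(c("A", "C", "G", "T"),
                                  substr(t1, 50, 50))[1])
  # cohort A segregates (both tags present); cohort B is monomorphic for t1
  cA <- matrix(c(6, 6, 6, 6), 2, 2, dimnames = list(c("a1", "a2"), c(t1, t2)))
  cB <- matrix(c(8, 8), 2, 1, dimnames = list(c("b1", "b2"), t1))
  tabA <- tag_count_table(cA); tabB <- tag_count_table(cB)

  sep <- call_snps(list(A = tabA, B = tabB), mode = "separate")
  expect_equal(ncol(sep$A), 1)
  expect_equal(ncol(sep$B), 0)          # never discovered within B alone

  joint <- call_snps(list(A = tabA, B = tabB), mode = "joint")
  expect_identical(colnames(joint$A), colnames(joint$B))
  expect_equal(ncol(joint$B), 1)
  expect_true(all(joint$B == 0))        # monomorphic column in B
  expect_true(all(joint$A == 1))

  # single cohort: the two modes coincide
  one_sep <- call_snps(list(A = tabA), mode = "separate")
  one_joint <- call_snps(list(A = tabA), mode = "joint")
  expect_identical(unclass(one_sep$A), unclass(one_joint$A))

  # sample-id collision across cohorts is refused in joint mode
  cB2 <- cB; rownames(cB2) <- c("a1", "b2")
  expect_error(call_snps(list(A = tabA, B = tag_count_table(cB2)),
                         mode = "joint"), "collision")
})

test_that("read simulation and calling round-trip at moderate depth", {
  pop <- simulate_population(population_spec(
    15, 30, 6, h2 = 0.5, allele_freq_law = function(m) runif(m, 0.25, 0.75),
    seed = 14))
  rd <- simulate_tag_reads(pop$genotypes, depth_law = 40, seed = 3)
  calls <- call_snps(list(c1 = list(fastq = rd$fastq, key = rd$key_file)),
                     mode = "separate")
  G <- calls$c1
  expect_true(all(G %in% c(0:2, NA)))
  mk <- marker_info(G)
  key_called <- paste(mk$tag_ref, mk$tag_alt)
  key_true <- paste(pmin(rd$panel$tag_ref, rd$panel$tag_alt),
                    pmax(rd$panel$tag_ref, rd$panel$tag_alt))
  idx <- match(key_called, key_true)
  expect_true(all(!is.na(idx)))
  conc <- 0; tot <- 0
  for (j in seq_along(idx)) {
    truth <- pop$genotypes[, idx[j]]
    called <- G[rownames(pop$genotypes), j]
    if (rd$panel$tag_ref[idx[j]] != mk$tag_ref[j]) called <- 2L - called
    ok <- !is.na(called)
    conc <- conc + sum(called[ok] == truth[ok]); tot <- tot + sum(ok)
  }
  expect_gt(conc / tot, 0.97)
})
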