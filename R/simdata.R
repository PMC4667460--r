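#' Specify a synthetic reference population
#'
#' Defines the study conditions for one genotyped-and-phenotyped reference
#' population: an unstructured sample of parent genotypes carrying
#' exchangeable biallelic markers, a polygenic additive trait, and (in
#' tetraploid-collapsed mode) autotetraploid allele dosages collapsed to the
#' pseudo-diploid coding used throughout.
#'
#' @param n_individuals number of parent genotypes.
#' @param n_markers number of biallelic markers.
#' @param n_qtl number of markers carrying additive effects (must not
#'   exceed `n_markers`).
#' @param h2 narrow-sense heritability of the parent phenotype in `[0, 1]`.
#' @param allele_freq_law function(m) returning founder allele frequencies
#'   in (0, 1); default uniform on (0.1, 0.9), the frequency range typical
#'   of MAF-filtered GBS panels.
#' @param ploidy_mode `"tetraploid-collapsed"` (default): allele dosages are
#'   drawn from Binomial(4, p) per individual (autotetraploid HWE) and the
#'   heterozygous dosages 1-3 collapse to code 1; or `"diploid"`.
#' @param ld_block_size markers per linkage block; 1 (default) makes markers
#'   exchangeable, larger values give block-correlated genotypes for
#'   imputation benchmarking.
#' @param ld_within_noise probability that a marker entry within a block is
#'   resampled from its marginal rather than copied from the block haplotype
#'   column.
#' @param seed integer seed; identical seeds reproduce all outputs
#'   bit-exactly.
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(n_individuals, n_markers, n_qtl,
                            h2 = 0.2,
                            allele_freq_law = function(m) stats::runif(m, 0.1, 0.9),
                            ploidy_mode = c("tetraploid-collapsed", "diploid"),
                            ld_block_size = 1L,
                            ld_within_noise = 0.1,
                            seed = 1L) {
  ploidy_mode <- match.arg(ploidy_mode)
  if (n_qtl > n_markers) stop("invalid spec: n_qtl exceeds n_markers")
  if (h2 < 0 || h2 > 1) stop("invalid spec: h2 must lie in [0, 1]")
  if (n_individuals < 2) stop("invalid spec: need at least 2 individuals")
  if (!is.function(allele_freq_law)) stop("allele_freq_law must be a function")
  structure(list(n_individuals = as.integer(n_individuals),
                 n_markers = as.integer(n_markers),
                 n_qtl = as.integer(n_qtl),
                 h2 = h2,
                 allele_freq_law = allele_freq_law,
                 ploidy_mode = ploidy_mode,
                 ld_block_size = as.integer(ld_block_size),
                 ld_within_noise = ld_within_noise,
                 seed = as.integer(seed)),
            class = "population_spec")
}

# Draw a dosage (tetraploid) or code (diploid) matrix for given frequencies,
# with optional block-LD structure.
draw_genotype_codes <- function(spec, freqs) {
  n <- spec$n_individuals
  m <- spec$n_markers
  size <- if (spec$ploidy_mode == "tetraploid-collapsed") 4L else 2L
  if (spec$ld_block_size <= 1L) {
    raw <- matrix(stats::rbinom(n * m, size, rep(freqs, each = n)), n, m)
  } else {
    block <- (seq_len(m) - 1L) %/% spec$ld_block_size
    raw <- matrix(0L, n, m)
    for (b in unique(block)) {
      cols <- which(block == b)
      p <- freqs[cols[1L]]
      freqs[cols] <- p        # a block shares its base frequency
      base <- stats::rbinom(n, size, p)
      for (j in cols) {
        flip <- stats::runif(n) < spec$ld_within_noise
        col <- base
        col[flip] <- stats::rbinom(sum(flip), size, p)
        raw[, j] <- col
      }
    }
  }
  list(raw = raw, freqs = freqs)
}

collapse_dosage <- function(dosage) {
  code <- dosage
  code[dosage >= 1L & dosage <= 3L] <- 1L
  code[dosage == 4L] <- 2L
  code
}

# Core generator shared by simulate_population() and
# simulate_two_populations(): frequencies, QTL indices and effects are
# supplied by the caller; the RNG stream is already positioned.
sim_pop_core <- function(spec, freqs, qtl_indices, qtl_effects) {
  drawn <- draw_genotype_codes(spec, freqs)
  if (spec$ploidy_mode == "tetraploid-collapsed") {
    dosage <- drawn$raw
    G <- collapse_dosage(dosage)
  } else {
    dosage <- NULL
    G <- drawn$raw
  }
  dimnames(G) <- list(sprintf("I%04d", seq_len(nrow(G))),
                      sprintf("M%05d", seq_len(ncol(G))))
  G <- as_genotype_matrix(G)
  if (!is.null(dosage)) attr(G, "dosage") <- dosage

  bv <- as.numeric(G[, qtl_indices, drop = FALSE] %*% qtl_effects)
  names(bv) <- rownames(G)
  v_bv <- stats::var(bv)
  if (spec$h2 > 0 && v_bv > 0) {
    residual_sd <- sqrt(v_bv * (1 - spec$h2) / spec$h2)
    phenotype <- bv + stats::rnorm(length(bv), 0, residual_sd)
  } else {
    # h2 = 0 (or degenerate BV): the trait carries no genetic signal
    residual_sd <- if (v_bv > 0) sqrt(v_bv) else 1
    phenotype <- mean(bv) + stats::rnorm(length(bv), 0, residual_sd)
  }
  names(phenotype) <- rownames(G)
  list(genotypes = G,
       phenotype = phenotype,
       model = list(qtl_indices = qtl_indices,
                    qtl_effects = qtl_effects,
                    breeding_values = bv,
                    residual_sd = residual_sd),
       allele_freqs = drawn$freqs,
       spec = spec)
}

#' Simulate one reference population
#'
#' Draws founder allele frequencies, genotypes (tetraploid dosages collapsed
#' to pseudo-diploid codes by default), a true polygenic model and a
#' phenotype whose noise is scaled so that `var(BV)/var(y)` targets the
#' requested narrow-sense heritability.  At `h2 = 0` the phenotype is pure
#' noise; at `h2 = 1` it equals the breeding values.
#'
#' @param spec a [population_spec()].
#' @return a list with elements `genotypes` (genotype matrix; tetraploid
#'   mode also carries the uncollapsed dosages in attribute `"dosage"`),
#'   `phenotype`, `model` (QTL indices and effects, breeding values,
#'   residual sd), `allele_freqs` and `spec`.
#' @export
simulate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed)
  freqs <- spec$allele_freq_law(spec$n_markers)
  if (any(freqs <= 0 | freqs >= 1)) stop("allele frequencies must lie in (0, 1)")
  qtl_indices <- sort(sample.int(spec$n_markers, spec$n_qtl))
  qtl_effects <- stats::rnorm(spec$n_qtl)
  sim_pop_core(spec, freqs, qtl_indices, qtl_effects)
}

#' Simulate a replicated half-sib progeny trial
#'
#' Emulates a randomized complete block progeny test: each parent's
#' half-sib family is grown in `r` complete blocks and each plot value is
#' grand mean + block effect + progeny effect + plot error.  The progeny
#' (family) effect tracks the parent breeding value, scaled so its variance
#' equals `s2_hs`, with a Mendelian/finite-family sampling component
#' controlled by `mendelian_frac`.
#'
#' @param breeding_values named numeric vector of parent breeding values.
#' @param r number of replications (complete blocks), at least 1.
#' @param s2_hs half-sib progeny variance component.
#' @param s2_e plot error variance component.
#' @param seed integer seed.
#' @param mendelian_frac fraction of `s2_hs` due to finite-family sampling
#'   rather than parent transmission (default 0.25).
#' @param s2_block block effect variance (default `s2_e / 4`).
#' @param grand_mean trial grand mean.
#' @return a `TrialTable` data frame with columns `progeny_id`,
#'   `replication_id`, `plot_value`, carrying the simulated family effects
#'   in attribute `"progeny_effects"`.
#' @export
simulate_progeny_trial <- function(breeding_values, r = 2L, s2_hs = 1,
                                   s2_e = 1, seed = 1L,
                                   mendelian_frac = 0.25,
                                   s2_block = s2_e / 4,
                                   grand_mean = 0) {
  if (r < 1) stop("invalid design: need at least one replication")
  if (s2_hs < 0 || s2_e < 0 || s2_block < 0) stop("variances must be >= 0")
  set.seed(seed)
  n <- length(breeding_values)
  ids <- names(breeding_values) %||% sprintf("P%04d", seq_len(n))
  z <- breeding_values - mean(breeding_values)
  sdz <- stats::sd(z)
  z <- if (sdz > 0) z / sdz else rep(0, n)
  fam <- sqrt((1 - mendelian_frac) * s2_hs) * z +
    stats::rnorm(n, 0, sqrt(mendelian_frac * s2_hs))
  blocks <- stats::rnorm(r, 0, sqrt(s2_block))
  tab <- expand.grid(progeny_id = ids, replication_id = seq_len(r),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab$plot_value <- grand_mean + blocks[tab$replication_id] +
    fam[match(tab$progeny_id, ids)] +
    stats::rnorm(nrow(tab), 0, sqrt(s2_e))
  attr(tab, "progeny_effects") <- stats::setNames(fam, ids)
  tab
}

#' Beta-distributed per-marker missing rates
#'
#' Default missingness law for [mask_missing()]: marker-specific rates make
#' threshold filtering non-degenerate, and the Beta family reproduces the
#' wide spread of per-marker call rates typical of GBS.
#'
#' @param shape1,shape2 Beta parameters (default mean 1/3).
#' @return a function(m) returning m rates.
#' @export
missing_rate_beta <- function(shape1 = 1, shape2 = 2) {
  function(m) stats::rbeta(m, shape1, shape2)
}

#' Mask genotype entries as missing
#'
#' Entries are set missing independently with per-marker rates drawn from
#' `marker_rate_law`; observed entries are never altered.  The uncollapsed
#' dosage attribute (simulation truth) is dropped from the masked output.
#'
#' @param G complete genotype matrix.
#' @param marker_rate_law function(m) of per-marker missing rates, or a
#'   numeric scalar/vector of rates in `[0, 1]`.
#' @param seed integer seed.
#' @return genotype matrix with `NA`s; realized per-marker rates in
#'   attribute `"missing_rates"`.
#' @export
mask_missing <- function(G, marker_rate_law = missing_rate_beta(), seed = 1L) {
  if (anyNA(G)) stop("mask_missing expects a complete genotype matrix")
  set.seed(seed)
  m <- ncol(G)
  rates <- resolve_law(marker_rate_law, m, "missing-rate")
  if (any(rates < 0 | rates > 1)) stop("missing rates must lie in [0, 1]")
  mask <- matrix(stats::runif(nrow(G) * m), nrow(G), m) <
    matrix(rates, nrow(G), m, byrow = TRUE)
  out <- G
  out[mask] <- NA_integer_
  attr(out, "markers") <- marker_info(G)
  attr(out, "dosage") <- NULL
  attr(out, "missing_rates") <- rates
  out
}

#' Simulate two genetically-contrasting reference populations
#'
#' The two populations share one marker panel and one set of QTL positions.
#' A fraction `shared_qtl_fraction` of the QTL effects is identical across
#' populations (the rest are drawn independently), and population B's allele
#' frequencies are perturbed from the base frequencies by a
#' Balding-Nichols draw with differentiation `freq_divergence` (an
#' Fst-like parameter; 0 means identical frequency laws).
#'
#' @param spec_a,spec_b [population_spec()]s sharing `n_markers` and
#'   `n_qtl`.
#' @param shared_qtl_fraction fraction in `[0, 1]` of QTL effects identical
#'   across populations.
#' @param freq_divergence Fst-like allele-frequency differentiation in
#'   `[0, 1)`.
#' @param seed integer master seed (population seeds are derived from it).
#' @return list with elements `a` and `b`, each as returned by
#'   [simulate_population()].
#' @export
simulate_two_populations <- function(spec_a, spec_b,
                                     shared_qtl_fraction = 1,
                                     freq_divergence = 0,
                                     seed = 1L) {
  stopifnot(inherits(spec_a, "population_spec"),
            inherits(spec_b, "population_spec"))
  if (spec_a$n_markers != spec_b$n_markers ||
      spec_a$n_qtl != spec_b$n_qtl) {
    stop("the two populations must share marker panel and QTL count")
  }
  if (shared_qtl_fraction < 0 || shared_qtl_fraction > 1) {
    stop("shared_qtl_fraction must lie in [0, 1]")
  }
  if (freq_divergence < 0 || freq_divergence >= 1) {
    stop("freq_divergence must lie in [0, 1)")
  }
  set.seed(seed)
  m <- spec_a$n_markers
  p <- spec_a$allele_freq_law(m)
  p <- pmin(pmax(p, 1e-3), 1 - 1e-3)
  if (freq_divergence > 0) {
    f <- freq_divergence
    pb <- stats::rbeta(m, p * (1 - f) / f, (1 - p) * (1 - f) / f)
    pb <- pmin(pmax(pb, 1e-3), 1 - 1e-3)
  } else {
    pb <- p
  }
  qtl_indices <- sort(sample.int(m, spec_a$n_qtl))
  eff_a <- stats::rnorm(spec_a$n_qtl)
  n_shared <- round(shared_qtl_fraction * spec_a$n_qtl)
  shared <- seq_len(n_shared)
  eff_b <- eff_a
  if (n_shared < spec_a$n_qtl) {
    eff_b[-shared] <- stats::rnorm(spec_a$n_qtl - n_shared)
  }
  set.seed(derive_seed(seed, "pop_a"))
  a <- sim_pop_core(spec_a, p, qtl_indices, eff_a)
  set.seed(derive_seed(seed, "pop_b"))
  b <- sim_pop_core(spec_b, pb, qtl_indices, eff_b)
  list(a = a, b = b)
}

# ---- GBS read simulation ---------------------------------------------------

# Realize an IUPAC-coded cut-site remnant (e.g. "CWGC" -> "CAGC"/"CTGC").
iupac_expand <- c(A = "A", C = "C", G = "G", T = "T",
                  W = "AT", S = "CG", M = "AC", K = "GT", R = "AG", Y = "CT",
                  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

realize_remnant <- function(remnant) {
  letters <- strsplit(remnant, "")[[1]]
  paste(vapply(letters, function(l) {
    opts <- strsplit(iupac_expand[[l]], "")[[1]]
    opts[sample.int(length(opts), 1L)]
  }, character(1)), collapse = "")
}

#' Generate a 64-bp tag-pair panel for a marker set
#'
#' Each marker gets a random 64-base reference tag beginning with a realized
#' cut-site remnant, plus an alternate tag differing at exactly one position
#' downstream of the remnant (the SNP).
#'
#' @param n_markers number of markers.
#' @param cutsite_remnant IUPAC remnant the tags start with (default ApeKI
#'   `"CWGC"`).
#' @param marker_names optional marker names.
#' @return data frame with columns `name`, `chrom`, `pos`, `tag_ref`,
#'   `tag_alt`, `tag_pos0` (0-based SNP offset within the tag).
#' @export
make_tag_panel <- function(n_markers, cutsite_remnant = "CWGC",
                           marker_names = NULL) {
  bases <- c("A", "C", "G", "T")
  rem_len <- nchar(cutsite_remnant)
  tags <- character(n_markers)
  alts <- character(n_markers)
  pos0 <- integer(n_markers)
  for (j in seq_len(n_markers)) {
    remnant <- realize_remnant(cutsite_remnant)
    body <- paste(sample(bases, 64L - rem_len, replace = TRUE), collapse = "")
    ref <- paste0(remnant, body)
    k <- sample((rem_len + 1L):64L, 1L)
    cur <- substr(ref, k, k)
    alt_base <- sample(setdiff(bases, cur), 1L)
    alt <- ref
    substr(alt, k, k) <- alt_base
    tags[j] <- ref; alts[j] <- alt; pos0[j] <- k - 1L
  }
  data.frame(name = marker_names %||% sprintf("M%05d", seq_len(n_markers)),
             chrom = "N", pos = seq_len(n_markers),
             tag_ref = tags, tag_alt = alts, tag_pos0 = pos0,
             stringsAsFactors = FALSE)
}

#' Simulate barcoded GBS reads for a genotype matrix
#'
#' Per individual and marker, a read count is drawn from `depth_law`
#' (default negative binomial, the overdispersed depth distribution typical
#' of GBS) and reads are allocated to the marker's two tags binomially
#' according to the allele fraction of the true dosage (collapsed
#' heterozygote classes 1-3 contribute fractions 1/4, 2/4, 3/4 when the
#' matrix carries its `"dosage"` attribute, else codes 0/1/2 map to
#' 0, 1/2, 1).  Reads are the sample barcode followed by the 64-bp tag
#' (which itself starts with the cut-site remnant), written as FASTQ with
#' fixed qualities.
#'
#' @param G genotype matrix; its `"markers"` attribute must carry (or will
#'   be given, via [make_tag_panel()]) a valid tag-pair panel.
#' @param depth_law mean depth scalar (negative binomial with size 5), a
#'   vector, or a function(k) of per-cell read counts.
#' @param barcode_map named character vector `sample -> barcode`; generated
#'   (unique 6-mers) when `NULL`.
#' @param error_rate per-read probability of one random substitution within
#'   the tag.
#' @param seed integer seed.
#' @param fastq,key_file output paths (`.gz` fastq supported).
#' @param cutsite_remnant IUPAC remnant used when a panel must be generated.
#' @return list with `fastq`, `key_file`, `key` (data frame), `panel`, and
#'   `n_reads`.
#' @export
simulate_tag_reads <- function(G,
                               depth_law = 8,
                               barcode_map = NULL,
                               error_rate = 0,
                               seed = 1L,
                               fastq = tempfile(fileext = ".fastq"),
                               key_file = tempfile(fileext = ".key.tsv"),
                               cutsite_remnant = "CWGC") {
  set.seed(seed)
  mk <- marker_info(G)
  if (!all(c("tag_ref", "tag_alt", "tag_pos0") %in% names(mk))) {
    mk <- cbind(mk[setdiff(names(mk), c("tag_ref", "tag_alt", "tag_pos0"))],
                make_tag_panel(ncol(G), cutsite_remnant,
                               marker_names = mk$name)[
                  c("tag_ref", "tag_alt", "tag_pos0")])
    attr(G, "markers") <- mk
  }
  if (any(nchar(mk$tag_ref) != 64L) || any(nchar(mk$tag_alt) != 64L)) {
    stop("invalid panel: tags must be 64 bases long")
  }
  hd <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, mk$tag_ref, mk$tag_alt)
  if (any(hd != 1L)) stop("invalid panel: tag pairs must differ at exactly 1 bp")

  n <- nrow(G); m <- ncol(G)
  samples <- rownames(G)
  if (is.null(barcode_map)) {
    barcode_map <- generate_barcodes(samples)
  }
  if (anyDuplicated(barcode_map)) stop("barcodes must be unique")

  dosage <- attr(G, "dosage")
  frac <- if (!is.null(dosage)) dosage / 4 else unclass(G) / 2
  frac[is.na(frac)] <- 0   # missing genotype: no reads

  if (is.function(depth_law)) {
    depth <- depth_law(n * m)
  } else if (is.numeric(depth_law) && length(depth_law) == 1L) {
    depth <- stats::rnbinom(n * m, mu = depth_law, size = 5)
  } else {
    depth <- rep_len(depth_law, n * m)
  }
  depth <- as.integer(depth)
  depth[as.vector(is.na(G))] <- 0L
  alt_n <- stats::rbinom(n * m, depth, as.vector(frac))
  ref_n <- depth - alt_n

  ind_idx <- rep(seq_len(n), times = m)
  mkr_idx <- rep(seq_len(m), each = n)
  bc <- unname(barcode_map[samples])
  seqs <- c(
    rep(paste0(bc[ind_idx], mk$tag_ref[mkr_idx]), ref_n),
    rep(paste0(bc[ind_idx], mk$tag_alt[mkr_idx]), alt_n)
  )
  if (length(seqs) > 0L) seqs <- sample(seqs)  # interleave reads
  if (error_rate > 0 && length(seqs) > 0L) {
    hit <- which(stats::runif(length(seqs)) < error_rate)
    for (i in hit) {
      bclen <- nchar(seqs[i]) - 64L
      k <- bclen + sample.int(64L, 1L)
      cur <- substr(seqs[i], k, k)
      substr(seqs[i], k, k) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
    }
  }
  con <- if (grepl("\\.gz$", fastq)) gzfile(fastq, "w") else file(fastq, "w")
  if (length(seqs) > 0L) {
    recs <- paste0("@read", seq_along(seqs), "\n", seqs, "\n+\n",
                   strrep("I", nchar(seqs)))
    writeLines(recs, con)
  }
  close(con)

  key <- data.frame(flowcell = "SIMFC", lane = 1L,
                    barcode = unname(barcode_map[samples]),
                    sample_id = samples, stringsAsFactors = FALSE)
  utils::write.table(key, key_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(fastq = fastq, key_file = key_file, key = key, panel = mk,
       n_reads = length(seqs))
}

# Unique 6-bp barcodes for a sample list (equal length: no prefix ambiguity).
generate_barcodes <- function(samples) {
  bases <- c("A", "C", "G", "T")
  seen <- character(0)
  out <- character(length(samples))
  for (i in seq_along(samples)) {
    repeat {
      bc <- paste(sample(bases, 6L, replace = TRUE), collapse = "")
      if (!bc %in% seen) break
    }
    seen <- c(seen, bc)
    out[i] <- bc
  }
  stats::setNames(out, samples)
}
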