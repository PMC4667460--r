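# Shared fixture builders (all fixtures are generated in code).

toy_geno <- function(n, m, seed = 1, p_range = c(0.2, 0.8)) {
  set.seed(seed)
  p <- stats::runif(m, p_range[1], p_range[2])
  as_genotype_matrix(matrix(stats::rbinom(n * m, 2, rep(p, each = n)), n, m))
}

# A tiny FASTQ on disk from explicit (barcode, tag) read records.
write_toy_fastq <- function(seqs, path = tempfile(fileext = ".fastq")) {
  con <- file(path, "w")
  if (length(seqs) > 0) {
    writeLines(paste0("@r", seq_along(seqs), "\n", seqs, "\n+\n",
                      strrep("I", nchar(seqs))), con)
  }
  close(con)
  path
}

# Deterministic 64-bp tag starting with the ApeKI remnant realization CAGC.
fixed_tag <- function(seed = 1) {
  set.seed(seed)
  paste0("CAGC", paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                       collapse = ""))
}

mutate_at <- function(tag, pos, base) {
  substr(tag, pos, pos) <- base
  tag
}
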