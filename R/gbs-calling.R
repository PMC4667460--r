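#' Tag count tables
#'
#' The raw substrate of reference-free SNP calling: per-individual read
#' counts for 64-base sequence tags (identical trimmed reads grouped into
#' one tag).
#'
#' @param counts non-negative integer matrix, samples x tags, with sample
#'   ids as row names and tag sequences as column names.
#' @return an object of class `tag_count_table`.
#' @export
tag_count_table <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) > 0L && any(nchar(colnames(counts)) != 64L)) {
    stop("all tags must be 64 bases long")
  }
  if (length(counts) > 0L && (any(counts < 0) || any(counts != round(counts)))) {
    stop("tag counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  structure(list(counts = counts,
                 sample_ids = rownames(counts),
                 tags = colnames(counts)),
            class = "tag_count_table")
}

#' @export
print.tag_count_table <- function(x, ...) {
  cat("Tag count table:", length(x$sample_ids), "samples,",
      length(x$tags), "tags,", sum(x$counts), "reads\n")
  invisible(x)
}

iupac_regex <- function(pattern) {
  multi <- iupac_expand[nchar(iupac_expand) > 1]
  for (l in names(multi)) {
    pattern <- gsub(l, paste0("[", multi[[l]], "]"), pattern, fixed = TRUE)
  }
  pattern
}

#' Demultiplex and trim barcoded GBS reads into a tag count table
#'
#' Reads lacking a known barcode or the expected cut-site remnant right
#' after it are discarded; retained reads are trimmed to 64 bases after
#' barcode removal (the tag, which starts with the remnant); reads with an
#' ambiguous base in the tag are dropped; identical tags are aggregated per
#' sample.
#'
#' @param fastq path(s) to FASTQ file(s), optionally gzipped.
#' @param key_table data frame with columns `barcode` and `sample_id` (and
#'   optionally flowcell/lane), or the path of such a TSV.
#' @param cutsite_remnant IUPAC pattern that must follow the barcode
#'   (default `"CWGC"`, the ApeKI remnant).
#' @return a [tag_count_table()] with one row per key-table sample.
#' @export
demultiplex_trim <- function(fastq, key_table, cutsite_remnant = "CWGC") {
  if (is.character(key_table)) {
    key_table <- utils::read.table(key_table, sep = "\t", header = TRUE,
                                   stringsAsFactors = FALSE)
  }
  if (anyDuplicated(key_table$barcode)) {
    stop("key-table error: duplicate barcodes")
  }
  samples <- key_table$sample_id
  seqs <- unlist(lapply(fastq, function(f) {
    as.character(Biostrings::readDNAStringSet(f, format = "fastq"))
  }), use.names = FALSE)
  if (length(seqs) == 0L) {
    warning("empty FASTQ input: returning an empty tag count table")
    counts <- matrix(0L, nrow = length(samples), ncol = 0L,
                     dimnames = list(samples, NULL))
    return(tag_count_table(counts))
  }
  # longest barcodes first so a shorter barcode never shadows a longer one
  ord <- order(-nchar(key_table$barcode))
  assigned <- rep(NA_integer_, length(seqs))
  for (i in ord) {
    hit <- is.na(assigned) & startsWith(seqs, key_table$barcode[i])
    assigned[hit] <- i
  }
  keep <- !is.na(assigned)
  tagpart <- substr(seqs[keep], nchar(key_table$barcode[assigned[keep]]) + 1L,
                    nchar(key_table$barcode[assigned[keep]]) + 64L)
  sample_of <- samples[assigned[keep]]
  ok <- nchar(tagpart) == 64L &
    grepl(paste0("^", iupac_regex(cutsite_remnant)), tagpart) &
    !grepl("[^ACGT]", tagpart)
  tagpart <- tagpart[ok]
  sample_of <- sample_of[ok]
  if (length(tagpart) == 0L) {
    counts <- matrix(0L, nrow = length(samples), ncol = 0L,
                     dimnames = list(samples, NULL))
    return(tag_count_table(counts))
  }
  tags <- sort(unique(tagpart))
  counts <- table(factor(sample_of, levels = samples),
                  factor(tagpart, levels = tags))
  counts <- matrix(as.integer(counts), nrow = length(samples),
                   dimnames = list(samples, tags))
  tag_count_table(counts)
}

#' Stable reference-free SNP name from a tag pair
#'
#' Deterministic hash of the lexicographically sorted tag pair plus the
#' variant offset, so joint calling yields identical names across cohorts
#' without a reference genome.
#'
#' @param tag_a,tag_b the two 64-bp tags (order-insensitive).
#' @param pos0 0-based variant offset within the tag.
#' @return a character SNP name.
#' @export
snp_name <- function(tag_a, tag_b, pos0) {
  mapply(function(a, b, p) {
    s <- sort(c(a, b))
    h <- fnv1a32(paste(s[1], s[2], sep = "|"))
    sprintf("TP%04X%04X_%02d", as.integer(h %/% 65536), as.integer(h %% 65536),
            p + 1L)
  }, tag_a, tag_b, pos0, USE.NAMES = FALSE)
}

#' Discover 1-bp tag pairs (candidate biallelic SNPs)
#'
#' Tags with at least `min_total_reads` reads across all individuals enter
#' pairwise matching; emitted pairs differ at exactly one base.  Tags
#' involved in more than one candidate pair (ambiguous networks, the
#' signature of paralogs) are discarded, keeping only reciprocal unique
#' pairs.  The reference allele of a pair is the lexicographically smaller
#' tag (allele orientation is arbitrary without a reference genome).
#'
#' @param table a [tag_count_table()].
#' @param min_total_reads minimum total read count for a tag to be
#'   considered (default 10).
#' @return data frame with columns `name`, `tag_ref`, `tag_alt`,
#'   `tag_pos0`.
#' @export
discover_tag_pairs <- function(table, min_total_reads = 10L) {
  stopifnot(inherits(table, "tag_count_table"))
  totals <- colSums(table$counts)
  tags <- table$tags[totals >= min_total_reads]
  if (length(tags) < 2L) {
    return(data.frame(name = character(0), tag_ref = character(0),
                      tag_alt = character(0), tag_pos0 = integer(0),
                      stringsAsFactors = FALSE))
  }
  pair_a <- character(0); pair_b <- character(0); pair_p <- integer(0)
  for (k in 1:64) {
    key <- paste0(substr(tags, 1L, k - 1L), "*", substr(tags, k + 1L, 64L))
    grp <- split(seq_along(tags), key)
    grp <- grp[lengths(grp) >= 2L]
    for (g in grp) {
      cmb <- utils::combn(g, 2L)
      pair_a <- c(pair_a, tags[cmb[1L, ]])
      pair_b <- c(pair_b, tags[cmb[2L, ]])
      pair_p <- c(pair_p, rep(k - 1L, ncol(cmb)))
    }
  }
  if (length(pair_a) == 0L) {
    return(data.frame(name = character(0), tag_ref = character(0),
                      tag_alt = character(0), tag_pos0 = integer(0),
                      stringsAsFactors = FALSE))
  }
  # network filter: a tag may participate in exactly one pair
  occur <- base::table(c(pair_a, pair_b))
  keep <- occur[pair_a] == 1L & occur[pair_b] == 1L
  pair_a <- pair_a[keep]; pair_b <- pair_b[keep]; pair_p <- pair_p[keep]
  if (length(pair_a) == 0L) {
    return(data.frame(name = character(0), tag_ref = character(0),
                      tag_alt = character(0), tag_pos0 = integer(0),
                      stringsAsFactors = FALSE))
  }
  ref <- pmin(pair_a, pair_b)
  alt <- pmax(pair_a, pair_b)
  out <- data.frame(name = snp_name(ref, alt, pair_p),
                    tag_ref = ref, tag_alt = alt, tag_pos0 = pair_p,
                    stringsAsFactors = FALSE)
  out[order(out$name), , drop = FALSE]
}

#' Call pseudo-diploid genotypes from paired tag read counts
#'
#' Total depth below `min_depth` gives a missing call; both alleles
#' observed with at least `het_min_minor_reads` reads each gives the single
#' collapsed heterozygote code 1 (covering all autotetraploid heterozygous
#' dosage classes); otherwise the call is homozygous for the majority
#' allele.
#'
#' @param reads_ref,reads_alt non-negative integer vectors of per-individual
#'   read counts for the reference and alternate tag.
#' @param min_depth minimum total reads for a call (default 3).
#' @param het_min_minor_reads minimum reads of the minor allele to call a
#'   heterozygote (default 2).
#' @return integer vector of codes in \{0, 1, 2, NA\}.
#' @export
call_genotypes <- function(reads_ref, reads_alt, min_depth = 3L,
                           het_min_minor_reads = 2L) {
  if (any(reads_ref < 0) || any(reads_alt < 0)) {
    stop("read counts must be non-negative")
  }
  tot <- reads_ref + reads_alt
  out <- ifelse(pmin(reads_ref, reads_alt) >= het_min_minor_reads, 1L,
                ifelse(reads_ref >= reads_alt, 0L, 2L))
  out[tot < min_depth] <- NA_integer_
  as.integer(out)
}

# Union-align several tag count tables over samples (rbind) and tags.
combine_tag_tables <- function(tables) {
  all_samples <- unlist(lapply(tables, `[[`, "sample_ids"), use.names = FALSE)
  if (anyDuplicated(all_samples)) {
    stop("cohort sample-id collision in joint mode")
  }
  all_tags <- sort(unique(unlist(lapply(tables, `[[`, "tags"),
                                 use.names = FALSE)))
  counts <- matrix(0L, nrow = length(all_samples), ncol = length(all_tags),
                   dimnames = list(all_samples, all_tags))
  for (tab in tables) {
    if (length(tab$tags) > 0L) {
      counts[tab$sample_ids, tab$tags] <- tab$counts
    }
  }
  tag_count_table(counts)
}

genotypes_from_pairs <- function(table, pairs, min_depth, het_min_minor_reads) {
  n <- length(table$sample_ids)
  if (nrow(pairs) == 0L) {
    G <- matrix(NA_integer_, nrow = n, ncol = 0L,
                dimnames = list(table$sample_ids, NULL))
    return(as_genotype_matrix(G, markers = data.frame(
      name = character(0), chrom = character(0), pos = integer(0),
      tag_ref = character(0), tag_alt = character(0),
      tag_pos0 = integer(0), stringsAsFactors = FALSE)))
  }
  G <- matrix(NA_integer_, nrow = n, ncol = nrow(pairs),
              dimnames = list(table$sample_ids, pairs$name))
  for (j in seq_len(nrow(pairs))) {
    G[, j] <- call_genotypes(table$counts[, pairs$tag_ref[j]],
                             table$counts[, pairs$tag_alt[j]],
                             min_depth, het_min_minor_reads)
  }
  as_genotype_matrix(G, markers = data.frame(
    name = pairs$name, chrom = "N", pos = seq_len(nrow(pairs)),
    tag_ref = pairs$tag_ref, tag_alt = pairs$tag_alt,
    tag_pos0 = pairs$tag_pos0, stringsAsFactors = FALSE))
}

#' Reference-free SNP calling across one or more cohorts
#'
#' In `separate` mode, tag-pair discovery and genotype calling run per
#' cohort independently.  In `joint` mode, discovery runs once on the
#' pooled reads of all cohorts and the resulting genotype matrix is split
#' back by cohort, which guarantees identical SNP names across cohorts (the
#' only way to get consistent naming without a reference genome); markers
#' may then be monomorphic within a single cohort.
#'
#' @param read_sets named list of cohorts; each element is either a
#'   [tag_count_table()] or a list with components `fastq` and `key` to be
#'   passed through [demultiplex_trim()].
#' @param mode `"separate"` or `"joint"`.
#' @param min_total_reads tag retention threshold for discovery
#'   (default 10).
#' @param min_depth,het_min_minor_reads genotype-calling thresholds, see
#'   [call_genotypes()].
#' @param cutsite_remnant passed to [demultiplex_trim()].
#' @return named list of genotype matrices, one per cohort.
#' @export
call_snps <- function(read_sets, mode = c("separate", "joint"),
                      min_total_reads = 10L, min_depth = 3L,
                      het_min_minor_reads = 2L, cutsite_remnant = "CWGC") {
  mode <- match.arg(mode)
  tables <- lapply(read_sets, function(rs) {
    if (inherits(rs, "tag_count_table")) rs
    else demultiplex_trim(rs$fastq, rs$key, cutsite_remnant)
  })
  if (mode == "separate") {
    out <- lapply(tables, function(tab) {
      pairs <- discover_tag_pairs(tab, min_total_reads)
      genotypes_from_pairs(tab, pairs, min_depth, het_min_minor_reads)
    })
    return(out)
  }
  pooled <- combine_tag_tables(tables)
  pairs <- discover_tag_pairs(pooled, min_total_reads)
  G_all <- genotypes_from_pairs(pooled, pairs, min_depth, het_min_minor_reads)
  out <- lapply(tables, function(tab) {
    g <- G_all[tab$sample_ids, , drop = FALSE]
    attr(g, "markers") <- marker_info(G_all)
    g
  })
  names(out) <- names(tables)
  out
}
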