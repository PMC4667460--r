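#' Genotype matrices
#'
#' Throughout the package a genotype matrix is an integer matrix with
#' individuals in rows and biallelic markers in columns, coded
#' `0` (homozygous reference), `1` (heterozygous; in autotetraploids this
#' single class collapses the three dosage classes Aaaa, AAaa and AAAa),
#' `2` (homozygous alternate) and `NA` (missing).  Marker metadata (name,
#' chromosome, position, flanking tag pair) travels in the `"markers"`
#' attribute as a data frame with one row per column.
#'
#' @param codes integer matrix in \{0,1,2,NA\}.
#' @param markers optional marker metadata data frame (one row per column);
#'   a minimal frame is built from column names when omitted.
#' @return the validated matrix with a `"markers"` attribute.
#' @export
as_genotype_matrix <- function(codes, markers = NULL) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  bad <- !(codes %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("genotype codes must be in {0, 1, 2, NA}")
  if (is.null(colnames(codes))) {
    colnames(codes) <- sprintf("M%04d", seq_len(ncol(codes)))
  }
  if (is.null(rownames(codes))) {
    rownames(codes) <- sprintf("I%04d", seq_len(nrow(codes)))
  }
  if (is.null(markers)) {
    markers <- attr(codes, "markers") %||%
      data.frame(name = colnames(codes), chrom = "N",
                 pos = seq_len(ncol(codes)), stringsAsFactors = FALSE)
  }
  if (nrow(markers) != ncol(codes)) {
    stop("marker metadata must have one row per marker column")
  }
  attr(codes, "markers") <- markers
  codes
}

#' Marker metadata of a genotype matrix
#' @param G genotype matrix.
#' @return data frame with one row per marker.
#' @export
marker_info <- function(G) {
  attr(G, "markers") %||%
    data.frame(name = colnames(G), chrom = "N",
               pos = seq_len(ncol(G)), stringsAsFactors = FALSE)
}

# Subset markers keeping metadata in step.
subset_markers <- function(G, keep) {
  mk <- marker_info(G)
  out <- G[, keep, drop = FALSE]
  attr(out, "markers") <- mk[keep, , drop = FALSE]
  out
}

#' Per-marker missing rate
#' @param G genotype matrix.
#' @return numeric vector, one rate per marker.
#' @export
marker_missing_rate <- function(G) colMeans(is.na(G))

#' Per-marker minor allele frequency
#'
#' Allele frequency is `p = mean(code) / 2` on the pseudo-diploid coding;
#' MAF is `min(p, 1 - p)`.
#'
#' @param G complete genotype matrix.
#' @return numeric vector of MAFs.
#' @export
marker_maf <- function(G) {
  p <- colMeans(G, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Write / read a genotype matrix as TSV
#'
#' Plain tab-separated matrix with an `id` column for individuals; missing
#' genotypes are `NA`.
#'
#' @param G genotype matrix.
#' @param path output file.
#' @return `path`, invisibly (writer); a genotype matrix (reader).
#' @export
write_genotype_tsv <- function(G, path) {
  df <- data.frame(id = rownames(G), as.data.frame(G), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @export
read_genotype_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  as_genotype_matrix(m)
}

#' Write a genotype matrix as a minimal pseudo-diploid VCF
#'
#' Codes map to GT fields `0/0`, `0/1`, `1/1` and `./.`.  When the marker
#' metadata carries a tag pair, the SNP alleles at the variant position are
#' used as REF/ALT and the tags are echoed in INFO; variant positions are
#' 1-based in the file.
#'
#' @param G genotype matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(G, path) {
  mk <- marker_info(G)
  gt_map <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  has_tags <- all(c("tag_ref", "tag_alt", "tag_pos0") %in% names(mk))
  if (has_tags) {
    ref <- substr(mk$tag_ref, mk$tag_pos0 + 1L, mk$tag_pos0 + 1L)
    alt <- substr(mk$tag_alt, mk$tag_pos0 + 1L, mk$tag_pos0 + 1L)
    pos <- mk$tag_pos0 + 1L
    info <- paste0("RT=", mk$tag_ref, ";AT=", mk$tag_alt)
  } else {
    ref <- rep("A", nrow(mk)); alt <- rep("C", nrow(mk))
    pos <- if ("pos" %in% names(mk)) mk$pos else seq_len(nrow(mk))
    info <- rep(".", nrow(mk))
  }
  chrom <- if ("chrom" %in% names(mk)) mk$chrom else rep("N", nrow(mk))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=RT,Number=1,Type=String,Description=\"Reference tag\">",
    "##INFO=<ID=AT,Number=1,Type=String,Description=\"Alternate tag\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(G)), collapse = "\t")
  ), con)
  for (j in seq_len(ncol(G))) {
    gts <- ifelse(is.na(G[, j]), "./.", gt_map[as.character(G[, j])])
    writeLines(paste(c(chrom[j], pos[j], mk$name[j], ref[j], alt[j], ".",
                       "PASS", info[j], "GT", gts), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a pseudo-diploid VCF into a genotype matrix
#'
#' Uses \pkg{vcfR} for parsing; GT fields `0/0`, `0/1` (or `1/0`), `1/1`
#' and `./.` map back to codes 0, 1, 2 and `NA`.
#'
#' @param path VCF file.
#' @return genotype matrix (individuals x markers).
#' @export
read_genotype_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_genotype_vcf requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                 dimnames = dimnames(gt))
  code[gt %in% c("0/0", "0|0")] <- 0L
  code[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  code[gt %in% c("1/1", "1|1")] <- 2L
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  m <- t(code)
  colnames(m) <- fix$ID
  as_genotype_matrix(m, markers = data.frame(
    name = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
    stringsAsFactors = FALSE))
}

#' Write / read a phenotype table as TSV
#' @param y named numeric vector of phenotypes.
#' @param path file path.
#' @return `path` invisibly (writer); named numeric vector (reader).
#' @export
write_phenotype_tsv <- function(y, path) {
  utils::write.table(
    data.frame(id = names(y) %||% seq_along(y), phenotype = as.numeric(y)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotype_tsv
#' @export
read_phenotype_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stats::setNames(df$phenotype, df$id)
}
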