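#' Marker-based kinship matrix
#'
#' Centered cross-product (VanRaden-type) relatedness on the pseudo-diploid
#' coding: `K = ZZ' / (2 * sum(p_j (1 - p_j)))` with `Z` the column-centered
#' genotype matrix and `p_j` the allele frequencies.  Symmetric and positive
#' semi-definite by construction; used for structure diagnostics and as the
#' random-effect covariance in mixed-model association.
#'
#' @param G_complete complete \{0,1,2\} genotype matrix with at least two
#'   polymorphic markers.
#' @return an individuals x individuals kinship matrix with attribute
#'   `"method" = "vanraden"`.
#' @export
kinship_matrix <- function(G_complete) {
  if (anyNA(G_complete)) stop("kinship requires a complete matrix")
  p <- colMeans(G_complete) / 2
  v <- colMeans(unclass(G_complete)^2) - (2 * p)^2
  poly <- p > 0 & p < 1 & v > 0
  if (sum(poly) < 2L) stop("need at least 2 polymorphic markers")
  X <- unclass(G_complete)[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(X, 2L, 2 * p, "-")
  K <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  dimnames(K) <- list(rownames(G_complete), rownames(G_complete))
  attr(K, "method") <- "vanraden"
  K
}

#' Kinship-corrected single-marker mixed-model association
#'
#' Population-parameters-previously-determined scheme: the variance
#' components of `y = mu + g + e`, `g ~ N(0, sigma2_g K)`, are estimated
#' once under the no-marker null ([reml_variance_ratio()]); every marker is
#' then tested as a fixed effect by generalized least squares under the
#' fixed covariance structure `K + delta I` (data are whitened by its
#' inverse square root once, after which each marker test is an ordinary
#' regression with a t-test on `n - 2` degrees of freedom).  With
#' `K = identity` this reduces exactly to per-marker simple linear
#' regression.
#'
#' @param G complete genotype matrix.
#' @param y phenotype vector (non-constant).
#' @param K kinship matrix from [kinship_matrix()] or user-supplied;
#'   computed from `G` when `NULL`.
#' @return data frame of class `association_result`: `marker`, `chrom`,
#'   `pos`, `effect`, `stat`, `p`, plus a Bonferroni-adjusted column
#'   (`p_bonferroni`, an extension beyond the Manhattan display).
#' @export
mixed_model_gwas <- function(G, y, K = NULL) {
  check_model_input(G, y)
  if (stats::sd(y) == 0) stop("singular phenotype: no variance to test")
  if (is.null(K)) K <- kinship_matrix(G)
  n <- nrow(G)
  vc <- reml_variance_ratio(y, K)
  # whitening by (K + delta I)^(-1/2); overall scale cancels in the t-test
  eg <- eigen(K + vc$delta * diag(n), symmetric = TRUE)
  ev <- pmax(eg$values, 1e-10)
  # unit-normalized: any common scale of V cancels in the t statistic
  W <- eg$vectors %*% (t(eg$vectors) * sqrt(mean(ev) / ev))
  yt <- as.numeric(W %*% y)
  ones_t <- as.numeric(W %*% rep(1, n))
  Gt <- W %*% unclass(G)

  mk <- marker_info(G)
  eff <- se <- numeric(ncol(G))
  for (j in seq_len(ncol(G))) {
    Xj <- cbind(ones_t, Gt[, j])
    XtX <- crossprod(Xj)
    if (rcond(XtX) < 1e-12) { eff[j] <- 0; se[j] <- NA_real_; next }
    XtXi <- solve(XtX)
    b <- XtXi %*% crossprod(Xj, yt)
    res <- yt - Xj %*% b
    s2 <- sum(res^2) / (n - 2L)
    eff[j] <- b[2L]
    se[j] <- sqrt(s2 * XtXi[2L, 2L])
  }
  stat <- eff / se
  p <- 2 * stats::pt(-abs(stat), df = n - 2L)
  p[is.na(p)] <- 1
  out <- data.frame(marker = mk$name,
                    chrom = if ("chrom" %in% names(mk)) mk$chrom else "N",
                    pos = if ("pos" %in% names(mk)) mk$pos
                          else seq_len(ncol(G)),
                    effect = eff, stat = stat, p = p,
                    stringsAsFactors = FALSE)
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  class(out) <- c("association_result", "data.frame")
  attr(out, "variance_components") <- vc
  out
}

#' Manhattan-ready association table
#'
#' Adds `-log10(p)`, assigns markers without a chromosome record to the
#' fictitious chromosome `"N"` with sequential pseudo-positions after the
#' last real chromosome, and orders rows by (chromosome, position).
#'
#' @param results an association result data frame (see
#'   [mixed_model_gwas()]).
#' @param chromosome_map optional data frame `marker`, `chrom`, `pos`
#'   giving genome alignments; markers absent from it go to chromosome
#'   `"N"`.
#' @return data frame with columns `marker`, `chrom`, `pos`, `plot_pos`,
#'   `effect`, `stat`, `p`, `neg_log10_p`, one row per input marker.
#' @export
manhattan_export <- function(results, chromosome_map = NULL) {
  if (nrow(results) == 0L) stop("empty association results")
  out <- as.data.frame(results)
  if (!is.null(chromosome_map)) {
    idx <- match(out$marker, chromosome_map$marker)
    out$chrom <- ifelse(is.na(idx), "N", chromosome_map$chrom[idx])
    out$pos <- ifelse(is.na(idx), NA_integer_, chromosome_map$pos[idx])
  }
  out$chrom[is.na(out$chrom)] <- "N"
  real <- out$chrom != "N"
  # deterministic ordering: real chromosomes by (chrom, pos), then N
  ord <- order(out$chrom == "N", out$chrom, out$pos, out$marker)
  out <- out[ord, , drop = FALSE]
  n_unplaced <- sum(out$chrom == "N")
  if (n_unplaced > 0L) {
    out$pos[out$chrom == "N"] <- seq_len(n_unplaced)
  }
  chrom_levels <- c(sort(unique(out$chrom[out$chrom != "N"])),
                    if (n_unplaced > 0L) "N")
  offset <- 0
  out$plot_pos <- NA_real_
  for (ch in chrom_levels) {
    sel <- out$chrom == ch
    out$plot_pos[sel] <- offset + out$pos[sel]
    offset <- offset + max(out$pos[sel])
  }
  out$neg_log10_p <- -log10(out$p)
  rownames(out) <- NULL
  out[, c("marker", "chrom", "pos", "plot_pos", "effect", "stat", "p",
          "neg_log10_p",
          intersect("p_bonferroni", names(out)))]
}
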