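#' Filter markers by missing-data threshold
#'
#' A marker is retained iff its missing rate over genotypes is less than or
#' equal to the threshold (strictly-greater rates are excluded); individuals
#' are untouched.  The study grid of thresholds is
#' 0.10, 0.20, 0.30, 0.40, 0.50 and 0.70.
#'
#' @param G genotype matrix with missing values.
#' @param threshold allowed missing rate, in (0, 1).
#' @return the filtered genotype matrix.
#' @export
filter_missing <- function(G, threshold) {
  if (threshold <= 0 || threshold >= 1) {
    stop("missing-data threshold must lie in (0, 1)")
  }
  subset_markers(G, marker_missing_rate(G) <= threshold)
}

#' The study's missing-data threshold grid
#' @return numeric vector `c(0.10, 0.20, 0.30, 0.40, 0.50, 0.70)`.
#' @export
missing_threshold_grid <- function() c(0.10, 0.20, 0.30, 0.40, 0.50, 0.70)

#' Impute missing genotypes
#'
#' Three imputation algorithms for unordered biallelic markers, all ending
#' with discretization of imputed cells to the closer value in \{0, 1, 2\}
#' (observed entries are never altered):
#'
#' * `MNI` - mean imputation: each missing point gets the mean of the
#'   non-missing values of its marker.
#' * `SVDI` - SVD-regression imputation: the `k` leading left singular
#'   vectors of the (mean-completed) matrix serve as predictors in a
#'   per-marker linear regression fitted on observed entries.
#' * `RFI` - iterative random-forest imputation: marker-wise random-forest
#'   regressions on all other markers, repeated until fewer than `tol` of
#'   the imputed cells change between iterations or `maxiter` is reached
#'   (defaults `ntree = 100`, `maxiter = 10`).
#' * `LHCI_SURROGATE` - order-shuffled mean imputation: a stand-in slot for
#'   haplotype-order-based reference imputers, applying MNI after a random
#'   permutation of marker order; labelled a surrogate because marker order
#'   carries no information for unordered markers.
#'
#' @param G genotype matrix with missing values; every marker must retain
#'   at least one observed value.
#' @param method one of `"MNI"`, `"SVDI"`, `"RFI"`, `"LHCI_SURROGATE"`.
#' @param params method-specific settings: `k` (SVDI, default 10),
#'   `ntree`/`maxiter`/`tol` (RFI, defaults 100/10/0.005).
#' @param seed integer seed (RFI and the surrogate are stochastic).
#' @return a complete genotype matrix.
#' @export
impute <- function(G, method = c("MNI", "SVDI", "RFI", "LHCI_SURROGATE"),
                   params = list(), seed = 1L) {
  method <- match.arg(method)
  if (any(colSums(!is.na(G)) == 0L)) {
    stop("all-missing marker: filter before imputing")
  }
  if (!anyNA(G)) return(G)
  out <- switch(method,
    MNI = impute_mni(G),
    SVDI = impute_svdi(G, k = params$k %||% 10L),
    RFI = impute_rfi(G, ntree = params$ntree %||% 100L,
                     maxiter = params$maxiter %||% 10L,
                     tol = params$tol %||% 0.005, seed = seed),
    LHCI_SURROGATE = {
      set.seed(seed)
      ord <- sample.int(ncol(G))
      subset_markers(impute_mni(subset_markers(G, ord)), order(ord))
    })
  out
}

impute_mni <- function(G) {
  mk <- marker_info(G)
  means <- colMeans(G, na.rm = TRUE)
  out <- unclass(G)
  idx <- which(is.na(out), arr.ind = TRUE)
  out[idx] <- discretize_geno(means[idx[, 2L]])
  storage.mode(out) <- "integer"
  as_genotype_matrix(out, markers = mk)
}

# Continuous mean completion (used as SVDI starting point).
mean_complete <- function(G) {
  means <- colMeans(G, na.rm = TRUE)
  X <- unclass(G) * 1.0
  idx <- which(is.na(X), arr.ind = TRUE)
  X[idx] <- means[idx[, 2L]]
  X
}

impute_svdi <- function(G, k = 10L) {
  mk <- marker_info(G)
  X <- mean_complete(G)
  k <- min(k, nrow(X) - 1L, ncol(X))
  sv <- svd(scale(X, center = TRUE, scale = FALSE), nu = k, nv = 0L)
  U <- cbind(1, sv$u)                    # intercept + k eigen-predictors
  out <- unclass(G)
  for (j in which(colSums(is.na(G)) > 0L)) {
    obs <- !is.na(G[, j])
    fit <- stats::lm.fit(U[obs, , drop = FALSE], as.numeric(G[obs, j]))
    beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    pred <- U[!obs, , drop = FALSE] %*% beta
    out[!obs, j] <- discretize_geno(as.numeric(pred))
  }
  storage.mode(out) <- "integer"
  as_genotype_matrix(out, markers = mk)
}

impute_rfi <- function(G, ntree = 100L, maxiter = 10L, tol = 0.005,
                       seed = 1L) {
  set.seed(seed)
  mk <- marker_info(G)
  X <- mean_complete(G)
  miss <- is.na(unclass(G))
  todo <- which(colSums(miss) > 0L)
  todo <- todo[order(colSums(miss)[todo])]   # least missing first
  prev <- discretize_geno(X)
  for (it in seq_len(maxiter)) {
    for (j in todo) {
      obs <- !miss[, j]
      # genotype responses have few unique values; regression is intended
      rf <- withCallingHandlers(
        randomForest::randomForest(
          x = X[obs, -j, drop = FALSE], y = X[obs, j], ntree = ntree),
        warning = function(w) {
          if (grepl("five or fewer unique values", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        })
      X[!obs, j] <- stats::predict(rf, X[!obs, -j, drop = FALSE])
    }
    cur <- discretize_geno(X)
    changed <- sum(cur[miss] != prev[miss]) / max(1L, sum(miss))
    prev <- cur
    if (changed < tol) break
  }
  out <- unclass(G)
  out[miss] <- discretize_geno(X[miss])
  storage.mode(out) <- "integer"
  as_genotype_matrix(out, markers = mk)
}

#' Filter markers by minor allele frequency
#'
#' Runs after imputation, as in the study pipeline.  A marker is retained
#' iff `MAF >= maf_min`, with MAF computed on the pseudo-diploid coding as
#' `min(p, 1 - p)`, `p = mean(code)/2`.
#'
#' @param G complete genotype matrix.
#' @param maf_min MAF cut-off (default 0.025, i.e. minor allele frequency
#'   below 2.5% is excluded).
#' @return the filtered genotype matrix.
#' @export
filter_maf <- function(G, maf_min = 0.025) {
  if (anyNA(G)) stop("filter_maf expects a complete matrix (impute first)")
  if (maf_min < 0 || maf_min > 0.5) stop("maf_min must lie in [0, 0.5]")
  subset_markers(G, marker_maf(G) >= maf_min)
}

#' Build the COMMON cross-population marker set
#'
#' Restricts two jointly-called genotype matrices to the SNPs consistently
#' present (by name) in both, with identical column order, the basis of
#' cross-population prediction.
#'
#' @param G_a,G_b genotype matrices carrying joint-calling SNP names.
#' @return list with elements `a` and `b` on the shared markers.
#' @export
build_common <- function(G_a, G_b) {
  shared <- intersect(colnames(G_a), colnames(G_b))
  if (length(shared) == 0L) {
    stop("empty COMMON set: no shared markers between the two matrices")
  }
  list(a = subset_markers(G_a, match(shared, colnames(G_a))),
       b = subset_markers(G_b, match(shared, colnames(G_b))))
}

#' Missing-data QC pipeline: filter, impute, MAF-filter
#'
#' Applies the study's stated sequence `filter_missing` -> `impute` ->
#' `filter_maf`.  With `joint = TRUE` and a named list of cohort matrices
#' (sharing a jointly-called marker panel), filtering and imputation run on
#' the stacked matrix - giving the imputer the pooled information of both
#' cohorts - and the result is split back per cohort.
#'
#' @param G genotype matrix, or (with `joint = TRUE`) a named list of them.
#' @param threshold missing-data threshold.
#' @param imputer imputation method, see [impute()].
#' @param maf_min MAF cut-off (default 0.025).
#' @param joint impute cohorts jointly on the stacked matrix?
#' @param params imputer parameters.
#' @param seed integer seed.
#' @return a complete, filtered genotype matrix (or named list of them);
#'   attribute `"qc_report"` records marker counts per stage.
#' @export
qc_pipeline <- function(G, threshold = 0.3,
                        imputer = c("MNI", "SVDI", "RFI", "LHCI_SURROGATE"),
                        maf_min = 0.025, joint = FALSE, params = list(),
                        seed = 1L) {
  imputer <- match.arg(imputer)
  if (joint) {
    stopifnot(is.list(G), !is.null(names(G)))
    shared <- Reduce(intersect, lapply(G, colnames))
    if (length(shared) == 0L) stop("joint QC requires shared marker names")
    stacked <- do.call(rbind,
                       lapply(G, function(g) unclass(g)[, shared, drop = FALSE]))
    stacked <- as_genotype_matrix(
      stacked,
      markers = marker_info(G[[1L]])[match(shared, colnames(G[[1L]])), ])
    done <- qc_pipeline(stacked, threshold, imputer, maf_min, FALSE,
                        params, seed)
    sizes <- vapply(G, nrow, integer(1))
    ends <- cumsum(sizes)
    starts <- ends - sizes + 1L
    out <- lapply(seq_along(G), function(i) {
      g <- done[starts[i]:ends[i], , drop = FALSE]
      attr(g, "markers") <- marker_info(done)
      attr(g, "qc_report") <- attr(done, "qc_report")
      g
    })
    names(out) <- names(G)
    return(out)
  }
  n_in <- ncol(G)
  G1 <- filter_missing(G, threshold)
  G2 <- impute(G1, imputer, params = params, seed = seed)
  G3 <- filter_maf(G2, maf_min)
  attr(G3, "qc_report") <- data.frame(
    stage = c("input", "missing_filter", "imputed", "maf_filter"),
    n_markers = c(n_in, ncol(G1), ncol(G2), ncol(G3)))
  G3
}
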