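#' Variance components of a replicated progeny trial
#'
#' Two-way (progeny + block) ANOVA expected-mean-squares estimators for a
#' randomized complete block half-sib progeny test:
#' `s2_e = MS_error` and `s2_hs = (MS_progeny - MS_error) / r`, the latter
#' truncated at zero (with a warning) as is standard practice, which keeps
#' the derived heritability in `[0, 1]`.
#'
#' @param trial data frame with columns `progeny_id`, `replication_id`,
#'   `plot_value` (a `TrialTable`); each progeny may appear at most once
#'   per replication and at least two replications and two progenies are
#'   required.
#' @return list of class `variance_components` with `s2_hs`, `s2_e` and
#'   `r`.
#' @export
estimate_variance_components <- function(trial) {
  stopifnot(all(c("progeny_id", "replication_id", "plot_value") %in%
                  names(trial)))
  if (anyDuplicated(trial[c("progeny_id", "replication_id")])) {
    stop("each progeny may appear at most once per replication")
  }
  r <- length(unique(trial$replication_id))
  n_prog <- length(unique(trial$progeny_id))
  if (r < 2L) stop("variance components are not separable with a single replication")
  if (n_prog < 2L) stop("need at least two progenies")
  fit <- stats::aov(plot_value ~ factor(replication_id) + factor(progeny_id),
                    data = trial)
  ms <- stats::anova(fit)[["Mean Sq"]]
  names(ms) <- rownames(stats::anova(fit))
  ms_prog <- ms[["factor(progeny_id)"]]
  ms_err <- ms[["Residuals"]]
  if (!is.finite(ms_err)) ms_err <- 0
  # snap numerically-zero mean squares (perfectly replicated data) to 0
  tol <- 1e-10 * (stats::var(trial$plot_value) + 1e-12)
  if (ms_err < tol) ms_err <- 0
  if (ms_prog < tol) ms_prog <- 0
  s2_hs <- (ms_prog - ms_err) / r
  if (s2_hs < 0) {
    warning("negative half-sib variance estimate truncated to 0")
    s2_hs <- 0
  }
  structure(list(s2_hs = s2_hs, s2_e = ms_err, r = r),
            class = "variance_components")
}

#' Broad-sense heritability on a progeny-mean basis
#'
#' `h_B^2 = s2_hs / (s2_hs + s2_e / r)`: the shrinkage factor applied to
#' half-sib progeny means.  Defined as 0 (with a warning) in the fully
#' degenerate case `s2_hs = s2_e = 0`.
#'
#' @param vc a `variance_components` object or a list with `s2_hs`, `s2_e`,
#'   `r`.
#' @return heritability in `[0, 1]`.
#' @export
heritability_progeny_mean <- function(vc) {
  stopifnot(vc$s2_hs >= 0, vc$s2_e >= 0, vc$r >= 1)
  denom <- vc$s2_hs + vc$s2_e / vc$r
  if (denom == 0) {
    warning("degenerate trial (all variance components zero): h_B2 set to 0")
    return(0)
  }
  vc$s2_hs / denom
}

#' BLUP shrinkage of progeny means
#'
#' Adjusts half-sib progeny means toward the grand mean by the progeny-mean
#' heritability: `adjusted_i = grand_mean + h_B2 * (mean_i - grand_mean)`.
#' Preserves the grand mean exactly and the ranking of progeny means for
#' any positive `h_B2`.
#'
#' @param progeny_means named numeric vector of progeny means.
#' @param h_B2 broad-sense heritability (progeny-mean basis) in `[0, 1]`.
#' @return adjusted phenotype vector.
#' @export
blup_adjust <- function(progeny_means, h_B2) {
  if (h_B2 < 0 || h_B2 > 1) stop("h_B2 must lie in [0, 1]")
  gm <- mean(progeny_means)
  gm + h_B2 * (progeny_means - gm)
}

#' Full BLUP phenotype adjustment of a progeny trial
#'
#' Convenience chain: variance components -> progeny-mean heritability ->
#' shrunken progeny means, the adjusted parent phenotypes used by the
#' genomic prediction models.
#'
#' @param trial a `TrialTable` data frame (see
#'   [estimate_variance_components()]).
#' @return named numeric vector of adjusted phenotypes with attributes
#'   `"variance_components"` and `"h_B2"`.
#' @export
blup_phenotypes <- function(trial) {
  vc <- estimate_variance_components(trial)
  h2 <- heritability_progeny_mean(vc)
  means <- tapply(trial$plot_value, trial$progeny_id, mean)
  adj <- blup_adjust(as.numeric(means), h2)
  names(adj) <- names(means)
  attr(adj, "variance_components") <- vc
  attr(adj, "h_B2") <- h2
  adj
}

#' Write / read a progeny trial table as TSV
#' @param trial trial data frame.
#' @param path file path.
#' @return `path` invisibly (writer); a trial data frame (reader).
#' @export
write_trial_tsv <- function(trial, path) {
  utils::write.table(trial, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_tsv
#' @export
read_trial_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
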