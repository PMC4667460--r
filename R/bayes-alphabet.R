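#' Bayesian whole-genome regression (Bayes A, Bayes B, Bayesian Lasso)
#'
#' Gibbs samplers for `y = mu + G u + e` with marker-specific shrinkage
#' priors on the effects:
#'
#' * **Bayes A** - each `u_j ~ N(0, sigma2_j)` with a scaled-inverse-chi^2
#'   prior on `sigma2_j` (marginally a scaled-t prior on the effect).
#' * **Bayes B** - a point mass at zero with prior probability `pi0` plus
#'   the Bayes A scaled-t slab, sampled through a per-marker inclusion
#'   indicator.
#' * **Bayesian Lasso** - double-exponential prior via the exponential
#'   scale mixture of normals (Park-Casella parameterization), with a
#'   Gamma hyper-prior on the regularization parameter.
#'
#' Marker columns are centered (the intercept absorbs the means);
#' reported effects and intercept are posterior means over the thinned
#' post-burn-in samples.  Default chain settings: 5000 iterations, 500
#' burn-in, thinning 5.
#'
#' Prior scales follow the conventional additive-variance heuristic: the
#' prior modes of the marker and residual variances split `var(y)` in
#' proportion `r2 : (1 - r2)` relative to the summed marker variance.
#'
#' @param G complete \{0,1,2\} genotype matrix.
#' @param y phenotype vector (finite).
#' @param variant `"A"`, `"B"` or `"Lasso"`.
#' @param n_iter,burn_in,thin Gibbs chain settings (defaults 5000/500/5).
#' @param seed integer seed.
#' @param pi0 Bayes B prior probability of a zero effect (default 0.95).
#' @param df prior degrees of freedom of the marker-variance scaled-t
#'   (default 4.2).
#' @param r2 prior proportion of phenotypic variance attributed to markers
#'   (default 0.5), used to solve the prior scales.
#' @return a `gs_fit` with posterior-mean `effects` and `mu`; Bayes B also
#'   reports posterior inclusion probabilities.
#' @export
fit_bayes <- function(G, y, variant = c("A", "B", "Lasso"),
                      n_iter = 5000L, burn_in = 500L, thin = 5L,
                      seed = 1L, pi0 = 0.95, df = 4.2, r2 = 0.5) {
  variant <- match.arg(variant)
  check_model_input(G, y)
  if (n_iter <= 0 || burn_in < 0 || thin <= 0 || burn_in >= n_iter) {
    stop("chain settings must be positive with burn_in < n_iter")
  }
  set.seed(seed)
  n <- nrow(G); p <- ncol(G)
  centers <- colMeans(G)
  X <- sweep(unclass(G), 2L, centers, "-")
  xx <- colSums(X^2)
  vy <- stats::var(y)
  if (vy == 0) vy <- 1e-8
  msx <- sum(xx) / (n - 1)
  if (msx == 0) msx <- 1e-8

  # scaled-inv-chi^2 prior scales solved from prior modes
  dfe <- 5
  Se <- vy * (1 - r2) * (dfe + 2) / dfe
  Su <- vy * r2 / msx * (df + 2) / df
  if (variant == "B") Su <- Su / max(1 - pi0, 1e-3)  # slab carries all signal

  mu <- mean(y)
  u <- rep(0, p)
  s2j <- rep(Su, p)                    # per-marker effect variances (A, B)
  tau2 <- rep(1, p)                    # Lasso local scales
  lam2 <- 1                            # Lasso lambda^2
  incl <- rep(variant != "B", p)
  s2e <- vy * (1 - r2)
  e <- y - mu                          # current residual (u = 0)

  keep <- seq(burn_in + thin, n_iter, by = thin)
  sum_u <- rep(0, p); sum_mu <- 0; sum_incl <- rep(0, p); n_keep <- 0L

  for (it in seq_len(n_iter)) {
    # intercept
    mu_new <- stats::rnorm(1L, mu + mean(e), sqrt(s2e / n))
    e <- e - (mu_new - mu)
    mu <- mu_new

    if (variant %in% c("A", "B")) {
      for (j in seq_len(p)) {
        if (xx[j] == 0) next
        if (incl[j] && u[j] != 0) e <- e + X[, j] * u[j]
        rhs <- sum(X[, j] * e)
        if (variant == "B") {
          v1 <- xx[j] * s2j[j] + s2e
          logodds <- log((1 - pi0) / pi0) - 0.5 * log(v1 / s2e) +
            0.5 * rhs^2 * s2j[j] / (s2e * v1)
          incl[j] <- stats::runif(1L) < 1 / (1 + exp(-logodds))
        }
        if (incl[j]) {
          Cj <- xx[j] + s2e / s2j[j]
          u[j] <- stats::rnorm(1L, rhs / Cj, sqrt(s2e / Cj))
          e <- e - X[, j] * u[j]
          s2j[j] <- (Su * df + u[j]^2) / stats::rchisq(1L, df + 1)
        } else {
          u[j] <- 0
          s2j[j] <- Su * df / stats::rchisq(1L, df)
        }
      }
      ss_u <- 0
    } else {
      for (j in seq_len(p)) {
        if (xx[j] == 0) next
        if (u[j] != 0) e <- e + X[, j] * u[j]
        rhs <- sum(X[, j] * e)
        Cj <- xx[j] + 1 / tau2[j]
        u[j] <- stats::rnorm(1L, rhs / Cj, sqrt(s2e / Cj))
        e <- e - X[, j] * u[j]
        if (abs(u[j]) > 1e-12) {
          inv_tau2 <- rinvgauss1(sqrt(lam2 * s2e / u[j]^2), lam2)
          tau2[j] <- 1 / inv_tau2
        } else {
          tau2[j] <- stats::rexp(1L, rate = lam2 / 2)
        }
      }
      lam2 <- stats::rgamma(1L, shape = p + 1, rate = sum(tau2) / 2 + 1e-4)
      ss_u <- sum(u^2 / tau2)
    }

    ss <- sum(e^2) + ss_u + Se * dfe
    s2e <- ss / stats::rchisq(1L, n + (variant == "Lasso") * p + dfe)

    if (it %in% keep) {
      n_keep <- n_keep + 1L
      sum_u <- sum_u + u
      sum_mu <- sum_mu + mu
      sum_incl <- sum_incl + incl
    }
  }

  new_gs_fit(paste0("Bayes", variant), mu = sum_mu / n_keep,
             effects = sum_u / n_keep, centers = centers, seed = seed,
             hyperparams = list(n_iter = n_iter, burn_in = burn_in,
                                thin = thin, pi0 = pi0, df = df, r2 = r2),
             extra = list(inclusion_prob = if (variant == "B")
               sum_incl / n_keep else NULL))
}
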