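#' Spectral REML for the variance ratio of a one-kernel mixed model
#'
#' Fits `y = X b + g + e` with `g ~ N(0, sigma2_u K)` and
#' `e ~ N(0, sigma2_e I)` by restricted maximum likelihood, profiling the
#' ratio `delta = sigma2_e / sigma2_u` after a single eigendecomposition of
#' the projected kernel (the efficient-mixed-model / spectral scheme: one
#' O(n^3) decomposition, then each likelihood evaluation is O(n)).
#'
#' @param y numeric response vector.
#' @param K positive semi-definite kernel matrix (`GG'` for the
#'   marker-effect model, a kinship matrix for association).
#' @param X fixed-effect design matrix (default an intercept column).
#' @param interval log10 search interval for `delta`.
#' @return list with `delta` (= the ridge parameter lambda), `sigma2_u`,
#'   `sigma2_e` and the maximized restricted log-likelihood `reml_loglik`.
#' @export
reml_variance_ratio <- function(y, K, X = NULL, interval = c(-8, 8)) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1L)
  q <- ncol(X)
  S <- diag(n) - X %*% solve(crossprod(X), t(X))
  # eigen of S(K+I)S keeps the spectrum strictly positive; subtract the
  # added identity from the retained eigenvalues afterwards
  eg <- eigen(S %*% (K + diag(n)) %*% S, symmetric = TRUE)
  xi <- eg$values[seq_len(n - q)] - 1
  xi <- pmax(xi, 1e-9)
  U <- eg$vectors[, seq_len(n - q), drop = FALSE]
  eta2 <- as.numeric(crossprod(U, y))^2

  rll <- function(log10d) {
    d <- 10^log10d
    0.5 * ((n - q) * (log((n - q) / (2 * pi)) - 1) -
             (n - q) * log(sum(eta2 / (xi + d))) -
             sum(log(xi + d)))
  }
  grid <- seq(interval[1], interval[2], length.out = 41L)
  vals <- vapply(grid, rll, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(rll, c(lo, hi), maximum = TRUE)
  delta <- 10^opt$maximum
  sigma2_u <- sum(eta2 / (xi + delta)) / (n - q)
  list(delta = delta, sigma2_u = sigma2_u, sigma2_e = delta * sigma2_u,
       reml_loglik = opt$objective)
}
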