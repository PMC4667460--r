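#' Whole-genome prediction models
#'
#' Seven models with a uniform fit/predict contract, all taking a complete
#' \{0,1,2\} genotype matrix `G` and a phenotype vector `y`:
#' `rrBLUP`, `BayesA`, `BayesB`, `BayesLasso` (see [fit_bayes()]),
#' `SVR-lin`, `SVR-gau` (see [fit_svr()]) and `RFR` (see [fit_rfr()]).
#'
#' @param G complete genotype matrix (individuals x markers).
#' @param y numeric phenotype vector, `length(y) == nrow(G)`.
#' @param model one of `"rrBLUP"`, `"BayesA"`, `"BayesB"`, `"BayesLasso"`,
#'   `"SVR-lin"`, `"SVR-gau"`, `"RFR"`.
#' @param params named list of model-specific hyperparameters passed
#'   through to the underlying fitter.
#' @param seed integer seed for the stochastic fitters (Bayesian samplers,
#'   random forest).
#' @return an object of class `gs_fit` supporting [predict.gs_fit()].
#' @export
gs_fit <- function(G, y, model = c("rrBLUP", "BayesA", "BayesB", "BayesLasso",
                                   "SVR-lin", "SVR-gau", "RFR"),
                   params = list(), seed = 1L) {
  model <- match.arg(model)
  check_model_input(G, y)
  switch(model,
    rrBLUP = do.call(fit_rrblup, c(list(G = G, y = y), params)),
    BayesA = do.call(fit_bayes, c(list(G = G, y = y, variant = "A",
                                       seed = seed), params)),
    BayesB = do.call(fit_bayes, c(list(G = G, y = y, variant = "B",
                                       seed = seed), params)),
    BayesLasso = do.call(fit_bayes, c(list(G = G, y = y, variant = "Lasso",
                                           seed = seed), params)),
    `SVR-lin` = do.call(fit_svr, c(list(G = G, y = y, kernel = "linear"),
                                   params)),
    `SVR-gau` = do.call(fit_svr, c(list(G = G, y = y, kernel = "gaussian"),
                                   params)),
    RFR = do.call(fit_rfr, c(list(G = G, y = y, seed = seed), params)))
}

check_model_input <- function(G, y) {
  if (anyNA(G)) stop("genotype matrix must be complete (impute first)")
  if (!all(is.finite(y))) stop("phenotypes must be finite")
  if (length(y) != nrow(G)) stop("length(y) must equal nrow(G)")
  invisible(TRUE)
}

new_gs_fit <- function(model_tag, mu, effects = NULL, centers = NULL,
                       machine = NULL, hyperparams = list(), seed = NULL,
                       extra = list()) {
  structure(c(list(model_tag = model_tag, mu = mu, effects = effects,
                   centers = centers, machine = machine,
                   hyperparams = hyperparams, seed = seed), extra),
            class = "gs_fit")
}

#' @export
print.gs_fit <- function(x, ...) {
  cat("Genomic prediction fit:", x$model_tag)
  if (!is.null(x$effects)) cat(" (", length(x$effects), " marker effects)",
                               sep = "")
  cat("\n")
  invisible(x)
}

#' Predict phenotypes from a fitted genomic prediction model
#'
#' @param object a `gs_fit`.
#' @param newdata complete genotype matrix on the same marker panel (same
#'   columns, same order) as the training matrix.
#' @param ... unused.
#' @return numeric vector of predicted phenotypes.
#' @export
predict.gs_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$effects)) {
    X <- sweep(newdata, 2L, object$centers, "-")
    return(as.numeric(object$mu + X %*% object$effects))
  }
  as.numeric(stats::predict(object$machine, newdata))
}

#' Ridge-regression BLUP with spectral REML
#'
#' Fits the additive model `y = mu + G u + e` with
#' `u ~ N(0, I sigma2_u)`, solving the closed form
#' `u_hat = G'(GG' + lambda I)^{-1}(y - mu)` where
#' `lambda = sigma2_e / sigma2_u` is the ridge parameter - the ratio of
#' residual to marker variance - estimated by restricted maximum likelihood
#' through a spectral decomposition of `GG'` ([reml_variance_ratio()])
#' unless supplied.  `mu` is the phenotype mean; marker columns are
#' centered before solving (the intercept absorbs the means) and
#' predictions re-add `mu`.
#'
#' @param G complete \{0,1,2\} genotype matrix, at least 3 individuals.
#' @param y phenotype vector.
#' @param lambda optional fixed ridge parameter; `NULL` (default) estimates
#'   it by REML.
#' @return a `gs_fit` with per-marker `effects`, `mu`, `lambda` and the
#'   REML variance components.
#' @export
fit_rrblup <- function(G, y, lambda = NULL) {
  check_model_input(G, y)
  n <- nrow(G)
  if (n < 3L) stop("rrBLUP needs at least 3 individuals")
  mu <- mean(y)
  centers <- colMeans(G)
  X <- sweep(unclass(G), 2L, centers, "-")
  if (stats::sd(y) == 0) {
    warning("zero-variance phenotype: marker effects set to 0")
    return(new_gs_fit("rrBLUP", mu, effects = rep(0, ncol(G)),
                      centers = centers,
                      extra = list(lambda = Inf, sigma2_u = 0, sigma2_e = 0)))
  }
  K <- tcrossprod(X)
  vcs <- NULL
  if (is.null(lambda)) {
    vcs <- reml_variance_ratio(y, K)
    lambda <- vcs$delta
  }
  u <- as.numeric(crossprod(X, solve(K + lambda * diag(n), y - mu)))
  new_gs_fit("rrBLUP", mu, effects = u, centers = centers,
             extra = list(lambda = lambda,
                          sigma2_u = vcs$sigma2_u %||% NA_real_,
                          sigma2_e = vcs$sigma2_e %||% NA_real_))
}

#' Support vector regression on markers
#'
#' Epsilon-insensitive support vector regression (residuals smaller than
#' `epsilon` in absolute value cost nothing; larger ones incur linear loss
#' under box constraint `C`), with a linear or Gaussian kernel, fitted
#' through the libsvm engine in \pkg{e1071}.  Defaults `C = 1`,
#' `epsilon = 0.1`.  The Gaussian bandwidth follows the median
#' pairwise-distance heuristic unless `gamma` is given.
#'
#' @param G complete genotype matrix.
#' @param y phenotype vector.
#' @param kernel `"linear"` or `"gaussian"`.
#' @param C box constraint (default 1).
#' @param epsilon insensitivity tube half-width (default 0.1).
#' @param gamma Gaussian kernel coefficient `exp(-gamma * |x - x'|^2)`;
#'   `NULL` uses `1 / (2 * median pairwise squared distance)`.
#' @return a `gs_fit` wrapping the fitted machine.
#' @export
fit_svr <- function(G, y, kernel = c("linear", "gaussian"), C = 1,
                    epsilon = 0.1, gamma = NULL) {
  kernel <- match.arg(kernel)
  check_model_input(G, y)
  X <- unclass(G)
  if (kernel == "gaussian" && is.null(gamma)) {
    idx <- seq_len(min(nrow(X), 500L))   # deterministic subset for large n
    d2 <- stats::dist(X[idx, , drop = FALSE])^2
    med <- stats::median(d2[d2 > 0])
    gamma <- if (is.finite(med) && med > 0) 1 / (2 * med) else 1 / ncol(X)
  }
  fit <- e1071::svm(x = X, y = y, type = "eps-regression",
                    kernel = if (kernel == "linear") "linear" else "radial",
                    cost = C, epsilon = epsilon,
                    gamma = gamma %||% 1 / ncol(X),
                    scale = FALSE, tolerance = 1e-3)
  new_gs_fit(if (kernel == "linear") "SVR-lin" else "SVR-gau",
             mu = mean(y), machine = fit,
             hyperparams = list(C = C, epsilon = epsilon, gamma = gamma))
}

#' Random forest regression on markers
#'
#' Bootstrap-aggregated regression trees with a random feature subset of
#' size `mtry = ceiling(p/3)` at each split; defaults
#' `n_trees = 500`, `min_node = 5`.
#'
#' @param G complete genotype matrix.
#' @param y phenotype vector.
#' @param n_trees number of trees (default 500).
#' @param mtry features tried per split (default `ceiling(p/3)`).
#' @param min_node minimum node size (default 5).
#' @param seed integer seed.
#' @return a `gs_fit` wrapping the forest.
#' @export
fit_rfr <- function(G, y, n_trees = 500L, mtry = NULL, min_node = 5L,
                    seed = 1L) {
  check_model_input(G, y)
  set.seed(seed)
  p <- ncol(G)
  fit <- randomForest::randomForest(
    x = unclass(G), y = y, ntree = n_trees,
    mtry = mtry %||% max(1L, ceiling(p / 3)), nodesize = min_node)
  new_gs_fit("RFR", mu = mean(y), machine = fit, seed = seed,
             hyperparams = list(n_trees = n_trees,
                                mtry = mtry %||% max(1L, ceiling(p / 3)),
                                min_node = min_node))
}
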