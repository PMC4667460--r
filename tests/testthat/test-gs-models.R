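test_that("rrBLUP closed form matches the primal ridge solution", {
  set.seed(21)
  for (dims in list(c(5, 3), c(10, 20), c(20, 50))) {
    G <- toy_geno(dims[1], dims[2], seed = dims[2])
    y <- rnorm(dims[1])
    for (lam in c(0.5, 1, 10)) {
      fit <- fit_rrblup(G, y, lambda = lam)
      Gc <- scale(unclass(G), scale = FALSE)
      beta <- solve(crossprod(Gc) + lam * diag(dims[2]),
                    crossprod(Gc, y - mean(y)))
      expect_lt(max(abs(fit$effects - as.numeric(beta))), 1e-8)
    }
  }
})

test_that("rrBLUP degenerate and limiting cases", {
  G <- toy_geno(10, 8, seed = 1)
  expect_warning(fit0 <- fit_rrblup(G, rep(2, 10)), "zero-variance")
  expect_true(all(fit0$effects == 0))
  expect_true(all(predict(fit0, G) == 2))
  y <- rnorm(10)
  fit_inf <- fit_rrblup(G, y, lambda = 1e12)
  expect_lt(sqrt(sum(fit_inf$effects^2)), 1e-8)
  expect_error(fit_rrblup(G[1:2, ], y[1:2]), "at least 3")
})

test_that("marker-effect and kinship forms of rrBLUP give equal predictions", {
  G <- toy_geno(40, 120, seed = 5)
  y <- rnorm(40) + rowSums(G[, 1:5])
  fit <- fit_rrblup(G, y)
  train <- 1:30; test <- 31:40
  fit_tr <- fit_rrblup(G[train, ], y[train], lambda = fit$lambda)
  pred_marker <- predict(fit_tr, G[test, ])
  # GBLUP form: K-blocks of the centered coding with the same lambda
  Gc <- sweep(unclass(G), 2, colMeans(G[train, ]), "-")
  Ktt <- tcrossprod(Gc[train, ])
  Knt <- Gc[test, ] %*% t(Gc[train, ])
  pred_kin <- mean(y[train]) +
    Knt %*% solve(Ktt + fit$lambda * diag(length(train)),
                  y[train] - mean(y[train]))
  expect_lt(max(abs(pred_marker - as.numeric(pred_kin))), 1e-6)
})

test_that("REML picks a heavier ridge for noisier phenotypes", {
  G <- toy_geno(80, 60, seed = 8)
  bv <- as.numeric(G[, 1:10] %*% rep(0.5, 10))
  set.seed(2)
  lam <- sapply(c(0.2, 2, 20), function(sd_e) {
    fit_rrblup(G, bv + rnorm(80, 0, sd_e))$lambda
  })
  expect_true(all(diff(lam) > 0))
})

test_that("support vector regression honours its study defaults and oracle", {
  G <- toy_geno(30, 10, seed = 3)
  y <- rnorm(30)
  fit <- fit_svr(G, y)
  expect_equal(fit$hyperparams$C, 1)
  expect_equal(fit$hyperparams$epsilon, 0.1)

  # epsilon-tube: an in-tube-achievable noiseless target is fitted within it
  beta <- c(0.3, -0.2, rep(0, 8))
  y_lin <- as.numeric(unclass(G) %*% beta)
  fit_lin <- fit_svr(G, y_lin, C = 100, epsilon = 0.1)
  # tube width plus the solver's own working tolerance
  expect_lt(max(abs(predict(fit_lin, G) - y_lin)), 0.1 + 5e-3)

  # independent quadratic-programming solve of the dual (kernlab::ipop)
  skip_if_not_installed("kernlab")
  set.seed(4)
  G6 <- matrix(rbinom(12, 2, 0.5), 6, 2)
  y6 <- rnorm(6)
  pred <- predict(fit_svr(G6, y6, kernel = "linear"), G6)
  K <- tcrossprod(G6)
  H <- rbind(cbind(K, -K), cbind(-K, K)) + diag(1e-8, 12)
  qp <- kernlab::ipop(c = c(0.1 - y6, 0.1 + y6), H = H,
                      A = matrix(c(rep(1, 6), rep(-1, 6)), 1), b = 0,
                      l = rep(0, 12), u = rep(1, 12), r = 0)
  ab <- kernlab::primal(qp)[1:6] - kernlab::primal(qp)[7:12]
  w <- crossprod(G6, ab)
  sv <- which(kernlab::primal(qp)[1:6] > 1e-5 &
                kernlab::primal(qp)[1:6] < 1 - 1e-5)
  b0 <- mean(y6[sv] - 0.1 - G6[sv, , drop = FALSE] %*% w)
  expect_lt(max(abs(pred - as.numeric(G6 %*% w + b0))), 1e-4)

  # gaussian kernel fits and predicts on the same contract
  fg <- fit_svr(G, y, kernel = "gaussian")
  expect_length(predict(fg, G), 30)
})

test_that("random forest regression uses the study settings", {
  G <- toy_geno(40, 30, seed = 6)
  fit <- suppressWarnings(fit_rfr(G, rep(7, 40), n_trees = 50))
  expect_true(all(abs(predict(fit, G) - 7) < 1e-10))
  fit2 <- fit_rfr(G, rnorm(40), n_trees = 50)
  expect_equal(fit2$hyperparams$mtry, ceiling(30 / 3))
  expect_equal(fit2$hyperparams$min_node, 5)
  expect_equal(formals(fit_rfr)$n_trees, 500L)
  # deterministic given the seed
  y <- rnorm(40)
  p1 <- predict(fit_rfr(G, y, n_trees = 30, seed = 9), G)
  p2 <- predict(fit_rfr(G, y, n_trees = 30, seed = 9), G)
  expect_identical(p1, p2)
})

test_that("Bayesian samplers shrink correctly and keep the study chain", {
  expect_equal(formals(fit_bayes)$n_iter, 5000L)
  expect_equal(formals(fit_bayes)$burn_in, 500L)
  expect_equal(formals(fit_bayes)$thin, 5L)
  G <- toy_geno(50, 40, seed = 7)
  # no signal: posterior mean effects collapse to zero
  fit0 <- fit_bayes(G, rep(1.3, 50), "A", n_iter = 1500, burn_in = 300,
                    seed = 2)
  expect_lt(max(abs(fit0$effects)), 0.01)
  # QTL effects shrink monotonically as the noise share of a unit-variance
  # trait grows (phenotypes standardized, as in cross-population use)
  bv <- as.numeric(G[, 1:5] %*% rep(1, 5))
  set.seed(11)
  noise <- rnorm(50)
  for (variant in c("A", "B", "Lasso")) {
    size <- sapply(c(0.5, 2, 8), function(s) {
      y <- bv + s * noise
      f <- fit_bayes(G, (y - mean(y)) / sd(y), variant, n_iter = 1200,
                     burn_in = 200, seed = 5)
      mean(abs(f$effects[1:5]))
    })
    expect_true(all(diff(size) < 0), info = variant)
  }
  # reproducible given the seed
  fa <- fit_bayes(G, bv + noise, "B", n_iter = 600, burn_in = 100, seed = 3)
  fb <- fit_bayes(G, bv + noise, "B", n_iter = 600, burn_in = 100, seed = 3)
  expect_identical(fa$effects, fb$effects)
  expect_error(fit_bayes(G, c(NA, bv[-1]), "A"), "finite")
  expect_error(fit_bayes(G, bv, "A", n_iter = 100, burn_in = 200), "burn_in")
})

test_that("the uniform gs_fit contract dispatches every model tag", {
  G <- toy_geno(30, 20, seed = 12)
  y <- rnorm(30) + G[, 1]
  for (tag in c("rrBLUP", "SVR-lin", "SVR-gau")) {
    fit <- gs_fit(G, y, tag)
    expect_s3_class(fit, "gs_fit")
    expect_length(predict(fit, G), 30)
  }
  fit_r <- gs_fit(G, y, "RFR", params = list(n_trees = 30), seed = 1)
  expect_length(predict(fit_r, G), 30)
  fit_b <- gs_fit(G, y, "BayesA",
                  params = list(n_iter = 400, burn_in = 100), seed = 1)
  expect_length(predict(fit_b, G), 30)
  expect_error(gs_fit(mask_missing(G, 0.5, seed = 1), y, "rrBLUP"),
               "complete")
})
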