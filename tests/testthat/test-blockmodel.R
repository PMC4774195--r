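test_that("E-step fixed points: trivial and symmetric cases", {
  A <- rand_sym(8, seed = 1)
  # Q = 1: posteriors are 1 after one sweep
  p1 <- m_step(A, tau = matrix(1, 8, 1), family = "gaussian")
  expect_equal(unname(e_step(A, params = p1, tau = matrix(1, 8, 1))),
               matrix(1, 8, 1))
  # two indistinguishable blocks: uniform tau is a fixed point
  Z <- (rand_sym(10, seed = 2) > 0.5) * 1
  diag(Z) <- 0
  params <- list(family = "bernoulli", alpha = c(0.5, 0.5),
                 pi = matrix(c(0.4, 0.4, 0.4, 0.4), 2))
  tau0 <- matrix(0.5, 10, 2)
  expect_equal(unname(e_step(Z, params = params, tau = tau0)), tau0,
               tolerance = 1e-12)
})

test_that("E-step posteriors are degenerate on a separated valued graph", {
  sim <- simulate_blockmodel_graph(sim_config(n = 8, Q = 2, alpha = c(.5, .5),
      mu = block_means(2, 1, 0), sigma = 0.05, seed = 5))
  fit <- fit_blockmodel(sim$network, family = "gaussian", Q = 2,
                        n_restarts = 4, seed = 5)
  expect_lt(max(abs(fit$tau - round(fit$tau))), 1e-3)
  # and the hardened labels match exhaustive enumeration on n = 8
  A <- auxnet:::as_adjacency(sim$network)
  labelings <- as.matrix(expand.grid(rep(list(1:2), 8)))
  best_oracle <- max(apply(labelings, 1, function(z)
    complete_loglik(A, list(), z, 2)))
  J_hard <- complete_loglik(A, list(), unname(fit$labels), 2)
  expect_equal(J_hard, best_oracle, tolerance = 1e-6)
})

test_that("M-step reduces to closed-form estimates", {
  A <- rand_sym(9, seed = 3)
  ut <- upper.tri(A)
  xv <- A[ut]
  # Q = 1, no covariate: mean and ML variance of the off-diagonal weights
  p <- m_step(A, tau = matrix(1, 9, 1), family = "gaussian")
  expect_equal(p$mu[1, 1], mean(xv), tolerance = 1e-9)
  expect_equal(p$sigma2, mean((xv - mean(xv))^2), tolerance = 1e-9)
  # Q = 1, one covariate: ordinary least squares (normal-equations oracle)
  Y <- rand_sym(9, seed = 4)
  pr <- m_step(A, covariates = list(Y = Y), tau = matrix(1, 9, 1),
               family = "gaussian_regression")
  ols <- coef(lm(xv ~ Y[ut]))
  expect_equal(unname(c(pr$mu[1, 1], pr$beta[1, 1, 1])), unname(ols),
               tolerance = 1e-5)
  # hard tau, bernoulli: pi is the observed block density
  Z <- (rand_sym(10, seed = 6) > 0.6) * 1
  labs <- rep(1:2, each = 5)
  pb <- m_step(Z, tau = hard_tau(labs), family = "bernoulli")
  within1 <- Z[1:5, 1:5][upper.tri(diag(5))]
  cross <- Z[1:5, 6:10]
  expect_equal(pb$pi[1, 1], mean(within1), tolerance = 1e-9)
  expect_equal(pb$pi[1, 2], mean(cross), tolerance = 1e-9)
  expect_identical(pb$pi, t(pb$pi))
})

test_that("the lower bound matches direct evaluation and is locally optimal", {
  A <- rand_sym(8, seed = 7)
  ut <- upper.tri(A)
  # Q = 1: J is the sum of log densities over unordered pairs
  p1 <- m_step(A, tau = matrix(1, 8, 1), family = "gaussian")
  expect_equal(lower_bound(A, params = p1, tau = matrix(1, 8, 1)),
               sum(dnorm(A[ut], p1$mu[1, 1], sqrt(p1$sigma2), log = TRUE)),
               tolerance = 1e-9)
  # hard tau: J equals the complete-data log-likelihood
  labs <- rep(1:2, each = 4)
  tauh <- hard_tau(labs)
  ph <- m_step(A, tau = tauh, family = "gaussian")
  direct <- sum(log(ph$alpha[labs])) +
    sum(vapply(which(ut), function(k) {
      i <- row(A)[k]; j <- col(A)[k]
      dnorm(A[i, j], ph$mu[labs[i], labs[j]], sqrt(ph$sigma2), log = TRUE)
    }, numeric(1)))
  expect_equal(lower_bound(A, params = ph, tau = tauh), direct,
               tolerance = 1e-9)
  # perturbing tau away from a converged fit does not increase J
  sim <- simulate_blockmodel_graph(sim_config(n = 20, Q = 2, alpha = c(.5, .5),
      mu = block_means(2, 0.9, 0.2), sigma = 0.1, seed = 8))
  fit <- fit_blockmodel(sim$network, family = "gaussian", Q = 2,
                        n_restarts = 3, seed = 8)
  params <- list(family = "gaussian", alpha = fit$alpha, mu = fit$mu,
                 beta = NULL, sigma2 = fit$sigma2)
  J0 <- lower_bound(sim$network, params = params, tau = fit$tau)
  for (s in 1:5) {
    eps <- withr::with_seed(s, matrix(runif(20 * 2, 0, 0.05), 20, 2))
    taup <- fit$tau + eps
    taup <- taup / rowSums(taup)
    Jp <- lower_bound(sim$network, params = params, tau = taup)
    expect_lte(Jp, J0 + 1e-8)
  }
})

test_that("variational EM recovers planted partitions and null coefficients", {
  sim <- simulate_blockmodel_graph(sim_config(n = 60, Q = 3,
      alpha = rep(1/3, 3), mu = block_means(3, 0.9, 0.3), sigma = 0.1,
      seed = 7))
  fit <- fit_blockmodel(sim$network, family = "gaussian", Q = 3,
                        n_restarts = 3, seed = 7)
  expect_equal(partition_match(fit$labels, sim$labels)$percent, 100)
  expect_true(fit$converged)
  expect_equal(sum(fit$alpha), 1, tolerance = 1e-9)
  expect_identical(fit$mu, t(fit$mu))
  # regression family with a signal-free covariate: beta near 0
  covs <- simulate_covariates(sim$labels, within_mean = 0.5,
                              between_mean = 0.5, jitter = 0.1, seed = 9)
  fitr <- fit_blockmodel(sim$network, covs, "gaussian_regression", Q = 3,
                         n_restarts = 2, seed = 9)
  expect_lt(max(abs(fitr$beta)), 0.1)
  # determinism under a fixed seed
  fit2 <- fit_blockmodel(sim$network, family = "gaussian", Q = 3,
                         n_restarts = 3, seed = 7)
  expect_identical(fit$J, fit2$J)
  expect_identical(fit$labels, fit2$labels)
})

test_that("model nesting: the saturated hard partition dominates smaller Q", {
  sim <- simulate_blockmodel_graph(sim_config(n = 6, Q = 2, alpha = c(.5, .5),
      mu = block_means(2, 0.8, 0.3), sigma = 0.15, seed = 10))
  A <- auxnet:::as_adjacency(sim$network)
  J_sat <- complete_loglik(A, list(), 1:6, 6)
  fit2 <- fit_blockmodel(A, family = "gaussian", Q = 2, n_restarts = 4,
                         seed = 10)
  expect_gte(J_sat, fit2$J)
})

test_that("gaussian_regression with zero covariates reproduces the gaussian fit", {
  sim <- simulate_blockmodel_graph(sim_config(n = 24, Q = 2, alpha = c(.5, .5),
      mu = block_means(2, 0.9, 0.3), sigma = 0.1, seed = 12))
  zero <- matrix(0, 24, 24,
                 dimnames = dimnames(auxnet:::as_adjacency(sim$network)))
  fg <- fit_blockmodel(sim$network, family = "gaussian", Q = 2,
                       n_restarts = 2, seed = 3)
  fr <- fit_blockmodel(sim$network, list(Y = zero), "gaussian_regression",
                       Q = 2, n_restarts = 2, seed = 3)
  expect_equal(fr$J, fg$J, tolerance = 1e-6)
})

test_that("ICL arithmetic follows the double-penalty formula", {
  expect_equal(blockmodel_param_count(4, 1), 35)
  expect_equal(icl_score(J = -12.3, n = 2, Q = 1, d = 0), -12.3)
  J <- -100; n <- 46
  expect_equal(icl_score(J, n, 3, 1),
               J - (3 - 1) / 2 * log(n) - 9 * 2 / 2 * log(n * (n - 1) / 2))
  # adding one covariate at fixed Q adds exactly Q^2 parameters
  for (Q in 1:6) {
    expect_equal(blockmodel_param_count(Q, 2) - blockmodel_param_count(Q, 1),
                 Q^2)
  }
  expect_equal(jeffreys_icl_threshold(), log(100))
  expect_equal(round(jeffreys_icl_threshold(), 1), 4.6)
})

test_that("model scans report softmax posterior probabilities", {
  sim <- simulate_blockmodel_graph(sim_config(n = 30, Q = 2, alpha = c(.5, .5),
      mu = block_means(2, 0.9, 0.3), sigma = 0.1, seed = 13))
  sc <- model_scan(sim$network, family = "gaussian", Q_range = 1:3,
                   n_restarts = 2, seed = 13)
  expect_equal(sum(sc$post_prob), 1, tolerance = 1e-9)
  expect_equal(sc$Q[sc$best], 2L)
  expect_equal(sc$post_prob, exp(sc$icl - max(sc$icl)) /
                 sum(exp(sc$icl - max(sc$icl))))
  one <- model_scan(sim$network, family = "gaussian", Q_range = 2,
                    n_restarts = 2, seed = 1)
  expect_equal(one$post_prob, 1)
})

test_that("tidy and glance expose symmetric cluster-pair parameters", {
  sim <- simulate_blockmodel_graph(sim_config(n = 20, Q = 2, alpha = c(.5, .5),
      family = "gaussian_regression", beta = matrix(0.5, 2, 2), sigma = 0.1,
      seed = 15))
  fit <- fit_blockmodel(sim$network, sim$covariates, "gaussian_regression",
                        Q = 2, n_restarts = 2, seed = 15)
  td <- tidy(fit)
  expect_equal(nrow(td), 3)  # unordered cluster pairs for Q = 2
  expect_true(all(c("mu", "beta1") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_params, blockmodel_param_count(2, 1))
  expect_equal(gl$Q, 2)
  expect_true(all(abs(fit$beta[1, , ] - t(fit$beta[1, , ])) == 0))
})
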