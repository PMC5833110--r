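# Gaussian process core: kernel closed forms, posterior against a dense
# linear-algebra oracle, marginal likelihood, and hyperparameter fitting.

h_of <- function(sf2, sn2, l) kernel_hyperparams(sf2, sn2, l)

test_that("squared-exponential kernel matches its closed form", {
  h <- h_of(2, 0.5, c(1, 2))
  x <- c(0.3, -1)
  expect_equal(sqexp_kernel(x, x, h, same_index = TRUE), 2.5)
  expect_equal(sqexp_kernel(x, x, h, same_index = FALSE), 2)
  h1 <- h_of(1, 0, 1)
  expect_equal(sqexp_kernel(0, 1, h1), exp(-0.5))
  expect_error(sqexp_kernel(c(1, 2), 1, h1), "dimension")
  # Gram matrix agrees with the scalar kernel entrywise
  X <- matrix(rnorm(6), ncol = 2)
  K <- kernel_matrix(X, X, h)
  for (i in 1:3) for (j in 1:3) {
    expect_equal(K[i, j], sqexp_kernel(X[i, ], X[j, ], h), tolerance = 1e-12)
  }
})

test_that("Gram matrices are symmetric positive semi-definite", {
  set.seed(14)
  for (rep in 1:20) {
    d <- sample(1:3, 1)
    n <- sample(3:25, 1)
    X <- matrix(rnorm(n * d, sd = runif(1, 0.1, 5)), ncol = d)
    h <- h_of(10^runif(1, -2, 2), 10^runif(1, -4, 0), 10^runif(d, -1, 1))
    K <- kernel_matrix(X, X, h, add_noise = TRUE)
    expect_equal(K, t(K))
    expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
})

test_that("noiseless GP interpolates its training targets", {
  set.seed(3)
  X <- matrix(runif(8, -2, 2), ncol = 1)
  y <- sin(X[, 1])
  train <- gp_training_set(X, y)
  h <- h_of(1, 0, 1)
  post <- gp_posterior(X, train, h)
  expect_lt(max(abs(post$mean - y)), 1e-6)
  expect_lt(max(diag(post$cov)), 1e-6)
})

test_that("single-point posterior matches the scalar closed form", {
  train <- gp_training_set(matrix(0.5), 2)
  h <- h_of(1.5, 0.3, 0.8)
  xq <- matrix(1.2)
  post <- gp_posterior(xq, train, h)
  k_star <- 1.5 * exp(-0.5 * ((1.2 - 0.5) / 0.8)^2)
  expect_equal(post$mean, k_star * 2 / (1.5 + 0.3), tolerance = 1e-12)
})

test_that("posterior mean/covariance match a brute-force dense oracle", {
  set.seed(21)
  for (rep in 1:5) {
    d <- sample(1:3, 1)
    n <- 5
    X <- matrix(rnorm(n * d), ncol = d)
    Xq <- matrix(rnorm(4 * d), ncol = d)
    y <- rnorm(n)
    h <- h_of(1.3, 0.2, runif(d, 0.5, 2))
    post <- gp_posterior(Xq, gp_training_set(X, y), h)
    # oracle: form and invert K explicitly
    K <- kernel_matrix(X, X, h) + diag(0.2, n)
    Ks <- kernel_matrix(Xq, X, h)
    Kss <- kernel_matrix(Xq, Xq, h, add_noise = TRUE)
    mu_o <- Ks %*% solve(K) %*% y
    S_o <- Kss - Ks %*% solve(K) %*% t(Ks)
    expect_lt(max(abs(post$mean - mu_o)), 1e-8)
    expect_lt(max(abs(post$cov - S_o)), 1e-8)
  }
})

test_that("posterior variance never exceeds the prior variance", {
  set.seed(33)
  for (rep in 1:10) {
    d <- sample(1:2, 1)
    X <- matrix(rnorm(12 * d), ncol = d)
    y <- rnorm(12)
    h <- h_of(10^runif(1, -1, 1), 10^runif(1, -3, -1), runif(d, 0.3, 3))
    post <- gp_posterior(matrix(rnorm(6 * d, sd = 2), ncol = d),
                         gp_training_set(X, y), h)
    expect_lt(max(diag(post$cov)),
              h$signal_variance + h$noise_variance + 1e-8)
  }
})

test_that("log marginal likelihood matches closed form and dense oracle", {
  # scalar case
  h <- h_of(1.2, 0.4, 2)
  train1 <- gp_training_set(matrix(0.7), 1.5)
  expect_equal(gp_log_marginal(train1, h),
               -0.5 * 1.5^2 / 1.6 - 0.5 * log(2 * pi * 1.6), tolerance = 1e-12)
  # with a Gamma prior on the lengthscale the log prior density is added
  pr <- list(c(6, 0.25))
  expect_equal(gp_log_marginal(train1, h, prior = pr),
               gp_log_marginal(train1, h) + dgamma(2, 6, scale = 0.25, log = TRUE),
               tolerance = 1e-12)
  # n = 3 dense oracle and permutation invariance
  set.seed(4)
  X <- matrix(rnorm(3), ncol = 1)
  y <- rnorm(3)
  h3 <- h_of(0.8, 0.1, 1.1)
  K <- kernel_matrix(X, X, h3) + diag(0.1, 3)
  oracle <- -0.5 * t(y) %*% solve(K) %*% y - 0.5 * log(det(K)) -
    1.5 * log(2 * pi)
  expect_equal(gp_log_marginal(gp_training_set(X, y), h3), drop(oracle),
               tolerance = 1e-8)
  perm <- c(3, 1, 2)
  expect_equal(gp_log_marginal(gp_training_set(X[perm, , drop = FALSE], y[perm]), h3),
               drop(oracle), tolerance = 1e-10)
})

test_that("analytic marginal-likelihood gradient matches finite differences", {
  set.seed(6)
  X <- matrix(rnorm(14), ncol = 2)
  y <- rnorm(7)
  prior <- list(c(6, 0.25), NULL)
  theta <- log(c(0.9, 0.2, 1.4, 0.7))
  obj <- fertgp:::.gp_nmap(theta, X, y, prior)
  num <- vapply(seq_along(theta), function(j) {
    e <- rep(0, length(theta)); e[j] <- 1e-6
    (fertgp:::.gp_nmap(theta + e, X, y, prior)$value -
       fertgp:::.gp_nmap(theta - e, X, y, prior)$value) / 2e-6
  }, numeric(1))
  expect_equal(obj$grad, num, tolerance = 1e-5)
})

test_that("constant targets give a flat predictive mean and tiny signal", {
  train <- gp_training_set(matrix(seq(0, 3, length.out = 6)), rep(4.2, 6))
  g <- fit_gp(train, seed = 2, n_restarts = 4)
  expect_lt(max(abs(predict(g, matrix(c(-1, 0.5, 4))) - 4.2)), 1e-6)
  expect_lt(g$h$signal_variance, 1e-4)
})

test_that("a known lengthscale is recovered within a factor of two", {
  set.seed(77)
  n <- 100
  X <- matrix(sort(runif(n, -5, 5)), ncol = 1)
  K <- kernel_matrix(X, X, h_of(1, 0, 1)) + diag(0.01, n)
  y <- drop(t(chol(K)) %*% rnorm(n))
  g <- fit_gp(gp_training_set(X, y), seed = 5, n_restarts = 6)
  expect_gt(g$h$lengthscales[1], 0.5)
  expect_lt(g$h$lengthscales[1], 2)
})

test_that("with uninformative data the SES prior pins its lengthscale mode", {
  # Gamma(6, 0.25) has mode (6 - 1) * 0.25 = 1.25
  train <- gp_training_set(matrix(c(1, 2, 3)), rep(0, 3))
  g <- fit_gp(train, prior = list(c(6, 0.25)), seed = 9, n_restarts = 6)
  expect_gt(g$h$lengthscales[1], 1.0)
  expect_lt(g$h$lengthscales[1], 1.6)
})

test_that("the achieved MAP objective is at least every initialiser's", {
  set.seed(12)
  X <- matrix(rnorm(20), ncol = 2)
  y <- rnorm(10)
  g <- fit_gp(gp_training_set(X, y), seed = 3, n_restarts = 8)
  expect_gte(g$objective + 1e-6, max(g$start_objectives))
})
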