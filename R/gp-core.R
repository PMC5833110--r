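# Gaussian process regression from scratch: squared-exponential kernel,
# posterior predictive mean/covariance via Cholesky factorisation, log
# marginal likelihood with an optional Gamma prior on chosen lengthscales
# (MAP objective), and multi-restart gradient-based hyperparameter fitting.

#' Squared-exponential kernel hyperparameters
#'
#' @param signal_variance sigma_f^2 (> 0): marginal variance of the latent
#'   function.
#' @param noise_variance sigma_n^2 (>= 0): observation noise added on the
#'   diagonal (zero only in interpolation mode).
#' @param lengthscales positive vector, one lengthscale per covariate
#'   dimension; the kernel's inverse squared-lengthscale matrix is
#'   `diag(lengthscales)^-2`.
#' @return object of class `kernel_hyperparams`.
#' @export
kernel_hyperparams <- function(signal_variance, noise_variance, lengthscales) {
  stopifnot(is.finite(signal_variance), signal_variance > 0,
            is.finite(noise_variance), noise_variance >= 0,
            all(is.finite(lengthscales)), all(lengthscales > 0))
  structure(list(signal_variance = signal_variance,
                 noise_variance = noise_variance,
                 lengthscales = as.numeric(lengthscales)),
            class = "kernel_hyperparams")
}

#' GP training set
#'
#' @param X matrix (or data.frame) of covariate vectors, one row per
#'   observation.
#' @param y numeric targets, one per row of `X`.
#' @return object of class `gp_training_set`.
#' @export
gp_training_set <- function(X, y) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(is.finite(X)), all(is.finite(y)))
  structure(list(X = X, y = y), class = "gp_training_set")
}

#' Squared-exponential covariance between two covariate vectors
#'
#' `sigma_f^2 * exp(-0.5 * sum(((x_i - x_j)/l)^2)) + sigma_n^2 * [same_index]`.
#'
#' @param x_i,x_j covariate vectors of equal dimension.
#' @param h a `kernel_hyperparams`.
#' @param same_index logical; `TRUE` adds the noise variance (the Kronecker
#'   delta term for identical observation indices).
#' @return scalar covariance.
#' @export
sqexp_kernel <- function(x_i, x_j, h, same_index = FALSE) {
  if (length(x_i) != length(x_j) || length(x_i) != length(h$lengthscales)) {
    stop("dimension mismatch between inputs and lengthscales")
  }
  d <- (x_i - x_j) / h$lengthscales
  h$signal_variance * exp(-0.5 * sum(d * d)) +
    if (isTRUE(same_index)) h$noise_variance else 0
}

#' Squared-exponential Gram matrix between two input sets
#'
#' @param X1,X2 input matrices (rows are covariate vectors).
#' @param h a `kernel_hyperparams`.
#' @param add_noise add `sigma_n^2` on the diagonal (only meaningful when
#'   `X1` and `X2` index the same observations).
#' @return `nrow(X1) x nrow(X2)` covariance matrix.
#' @export
kernel_matrix <- function(X1, X2, h, add_noise = FALSE) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  if (ncol(X1) != length(h$lengthscales) || ncol(X2) != length(h$lengthscales)) {
    stop("dimension mismatch between inputs and lengthscales")
  }
  A <- sweep(X1, 2, h$lengthscales, "/")
  B <- sweep(X2, 2, h$lengthscales, "/")
  D2 <- outer(rowSums(A * A), rowSums(B * B), "+") - 2 * tcrossprod(A, B)
  D2[D2 < 0] <- 0
  K <- h$signal_variance * exp(-0.5 * D2)
  if (add_noise) K <- K + diag(h$noise_variance, nrow(K))
  K
}

# Upper-triangular Cholesky factor with jitter escalation 1e-10 -> 1e-6.
gp_chol <- function(K) {
  n <- nrow(K)
  for (jit in c(0, 10^seq(-10, -6))) {
    U <- tryCatch(chol(K + diag(jit, n)), error = function(e) NULL)
    if (!is.null(U)) return(list(U = U, jitter = jit))
  }
  stop(sprintf(
    "Cholesky factorisation failed after jitter escalation to 1e-6 (n = %d, kappa ~ %.3g)",
    n, tryCatch(kappa(K), error = function(e) NA_real_)))
}

#' Posterior predictive distribution of a GP at query points
#'
#' Returns the posterior mean `K(X*,X) K(X,X)^-1 y` and covariance
#' `K(X*,X*) - K(X*,X) K(X,X)^-1 K(X,X*)`, computed through a Cholesky
#' factorisation of the noisy training Gram matrix (never an explicit
#' inverse). `K(X*,X*)` carries the noise variance on its diagonal when
#' `include_noise = TRUE` (the kernel's Kronecker-delta term applied to the
#' query set), giving the predictive distribution of noisy observations;
#' `include_noise = FALSE` gives the latent-function posterior.
#'
#' @param query matrix of query covariate vectors (rows).
#' @param train a `gp_training_set`.
#' @param h a `kernel_hyperparams`.
#' @param include_noise logical, see above.
#' @return object of class `gp_posterior`: list with `mean` and `cov`.
#' @export
gp_posterior <- function(query, train, h, include_noise = TRUE) {
  stopifnot(inherits(train, "gp_training_set"), nrow(train$X) >= 1)
  Xq <- as.matrix(query)
  K <- kernel_matrix(train$X, train$X, h, add_noise = TRUE)
  U <- gp_chol(K)$U
  Ks <- kernel_matrix(Xq, train$X, h)
  alpha <- backsolve(U, backsolve(U, train$y, transpose = TRUE))
  mu <- drop(Ks %*% alpha)
  V <- backsolve(U, t(Ks), transpose = TRUE)
  Kss <- kernel_matrix(Xq, Xq, h, add_noise = include_noise)
  Sigma <- Kss - crossprod(V)
  Sigma <- (Sigma + t(Sigma)) / 2
  structure(list(mean = mu, cov = Sigma), class = "gp_posterior")
}

# Sum of log Gamma prior densities over prior-carrying lengthscales.
# `prior` is a list of length d; each element NULL or c(shape, scale).
.log_lengthscale_prior <- function(lengthscales, prior) {
  if (is.null(prior)) return(0)
  stopifnot(length(prior) == length(lengthscales))
  lp <- 0
  for (d in seq_along(prior)) {
    pr <- prior[[d]]
    if (!is.null(pr)) {
      stopifnot(pr[1] > 0, pr[2] > 0)
      lp <- lp + stats::dgamma(lengthscales[d], shape = pr[1], scale = pr[2],
                               log = TRUE)
    }
  }
  lp
}

#' Log marginal likelihood (MAP objective) of GP hyperparameters
#'
#' `-0.5 * t(y) K^-1 y - 0.5 * log det K - (n/2) log(2 pi)` with
#' `K = K(X,X) + sigma_n^2 I`, plus the log Gamma prior density of any
#' prior-carrying lengthscale.
#'
#' @param train a `gp_training_set`.
#' @param h a `kernel_hyperparams`.
#' @param prior optional list, one element per covariate dimension: `NULL`
#'   for a flat prior or `c(shape, scale)` for a Gamma prior on that
#'   lengthscale.
#' @return scalar log marginal likelihood (plus log prior).
#' @export
gp_log_marginal <- function(train, h, prior = NULL) {
  stopifnot(inherits(train, "gp_training_set"))
  n <- nrow(train$X)
  K <- kernel_matrix(train$X, train$X, h, add_noise = TRUE)
  U <- gp_chol(K)$U
  alpha <- backsolve(U, backsolve(U, train$y, transpose = TRUE))
  -0.5 * sum(train$y * alpha) - sum(log(diag(U))) - 0.5 * n * log(2 * pi) +
    .log_lengthscale_prior(h$lengthscales, prior)
}

# Objective and analytic gradient of the negative MAP objective in
# theta = (log sf2, log sn2, log l_1..l_d). Gradient follows the standard
# trace identity dL/dtheta_j = 0.5 tr((alpha alpha' - K^-1) dK/dtheta_j).
.gp_nmap <- function(theta, X, y, prior) {
  d <- ncol(X)
  sf2 <- exp(theta[1]); sn2 <- exp(theta[2]); l <- exp(theta[2 + seq_len(d)])
  if (any(!is.finite(c(sf2, sn2, l)))) return(list(value = 1e12, grad = rep(0, length(theta))))
  h <- list(signal_variance = sf2, noise_variance = sn2, lengthscales = l)
  class(h) <- "kernel_hyperparams"
  n <- nrow(X)
  Ksig <- kernel_matrix(X, X, h)          # signal part only
  K <- Ksig + diag(sn2, n)
  ch <- tryCatch(gp_chol(K), error = function(e) NULL)
  if (is.null(ch)) return(list(value = 1e12, grad = rep(0, length(theta))))
  U <- ch$U
  alpha <- backsolve(U, backsolve(U, y, transpose = TRUE))
  val <- 0.5 * sum(y * alpha) + sum(log(diag(U))) + 0.5 * n * log(2 * pi) -
    .log_lengthscale_prior(l, prior)
  Kinv <- chol2inv(U)
  A <- tcrossprod(alpha) - Kinv           # alpha alpha' - K^-1
  grad <- numeric(length(theta))
  grad[1] <- -0.5 * sum(A * Ksig)                       # d/d log sf2
  grad[2] <- -0.5 * sum(diag(A)) * sn2                  # d/d log sn2
  for (j in seq_len(d)) {
    Dj <- outer(X[, j], X[, j], "-")^2 / l[j]^2
    grad[2 + j] <- -0.5 * sum(A * (Ksig * Dj))          # d/d log l_j
    pr <- if (is.null(prior)) NULL else prior[[j]]
    if (!is.null(pr)) grad[2 + j] <- grad[2 + j] - ((pr[1] - 1) - l[j] / pr[2])
  }
  list(value = val, grad = grad)
}

#' Fit GP hyperparameters by maximum marginal likelihood (MAP with priors)
#'
#' Optimises `(log sigma_f^2, log sigma_n^2, log l)` with L-BFGS-B and
#' analytic gradients from seeded restarts drawn log-uniformly over
#' `[1e-2, 1e2]` times data-derived scales (target variance for the
#' variances, per-dimension input ranges for the lengthscales). Targets are
#' centred internally (`center = TRUE`); predictions add the mean back.
#'
#' @param train a `gp_training_set` with at least 3 rows.
#' @param prior optional lengthscale prior list (see [gp_log_marginal()]).
#' @param seed seed for the restart draws.
#' @param n_restarts number of random restarts (in addition to the
#'   data-scale start and any warm start).
#' @param center subtract the target mean before fitting.
#' @param h0 optional `kernel_hyperparams` warm start.
#' @return object of class `gp_model`: fitted hyperparameters `h`, cached
#'   Cholesky factor and weight vector, the achieved objective, and the
#'   objective value at every initialiser.
#' @export
fit_gp <- function(train, prior = NULL, seed = 1L, n_restarts = 10,
                   center = TRUE, h0 = NULL) {
  stopifnot(inherits(train, "gp_training_set"), nrow(train$X) >= 3)
  X <- train$X
  d <- ncol(X)
  y_mean <- if (center) mean(train$y) else 0
  y <- train$y - y_mean

  vy <- stats::var(y)
  if (!is.finite(vy) || vy < 1e-10) vy <- 1e-10
  l_scale <- apply(X, 2, function(col) {
    r <- diff(range(col)) / 2
    if (r <= 0) 1 else r
  })
  base <- log(c(vy, 0.1 * vy, l_scale))

  starts <- list(base)
  if (!is.null(h0)) {
    starts <- c(starts, list(log(c(max(h0$signal_variance, 1e-12),
                                   max(h0$noise_variance, 1e-12),
                                   h0$lengthscales))))
  }
  if (n_restarts > 0) {
    jit <- with_seed(seed, matrix(stats::runif(n_restarts * (d + 2), -2, 2),
                                  ncol = d + 2))
    for (k in seq_len(n_restarts)) starts <- c(starts, list(base + log(10) * jit[k, ]))
  }

  fn <- function(theta) .gp_nmap(theta, X, y, prior)$value
  gr <- function(theta) .gp_nmap(theta, X, y, prior)$grad

  best <- NULL
  start_objectives <- numeric(length(starts))
  failures <- character(0)
  for (k in seq_along(starts)) {
    start_objectives[k] <- fn(starts[[k]])
    res <- tryCatch(
      stats::optim(starts[[k]], fn, gr, method = "L-BFGS-B",
                   lower = -30, upper = 30,
                   control = list(maxit = 300, factr = 1e4)),
      error = function(e) {failures <<- c(failures, conditionMessage(e)); NULL})
    if (!is.null(res) && is.finite(res$value) &&
        (is.null(best) || res$value < best$value)) {
      best <- res
    }
  }
  if (is.null(best)) {
    stop("all GP hyperparameter restarts failed; last errors: ",
         paste(utils::tail(unique(failures), 3), collapse = " | "))
  }

  h <- kernel_hyperparams(exp(best$par[1]), exp(best$par[2]),
                          exp(best$par[2 + seq_len(d)]))
  K <- kernel_matrix(X, X, h, add_noise = TRUE)
  U <- gp_chol(K)$U
  alpha <- backsolve(U, backsolve(U, y, transpose = TRUE))
  structure(list(
    train = gp_training_set(X, y),
    y_mean = y_mean,
    h = h,
    U = U,
    alpha = alpha,
    prior = prior,
    seed = seed,
    objective = -best$value,
    start_objectives = -start_objectives
  ), class = "gp_model")
}

#' Predict from a fitted GP model
#'
#' @param object a `gp_model`.
#' @param newdata matrix of query covariate vectors (rows).
#' @param se.fit also return pointwise posterior standard deviations (of the
#'   noisy predictive distribution).
#' @param ... unused.
#' @return vector of posterior means, or a list `(fit, se.fit)` when
#'   `se.fit = TRUE`.
#' @export
predict.gp_model <- function(object, newdata, se.fit = FALSE, ...) {
  Xq <- as.matrix(newdata)
  Ks <- kernel_matrix(Xq, object$train$X, object$h)
  mu <- drop(Ks %*% object$alpha) + object$y_mean
  if (!se.fit) return(mu)
  V <- backsolve(object$U, t(Ks), transpose = TRUE)
  var_q <- object$h$signal_variance + object$h$noise_variance - colSums(V * V)
  list(fit = mu, se.fit = sqrt(pmax(var_q, 0)))
}

#' @export
print.gp_model <- function(x, ...) {
  cat(sprintf(
    "GP model: n = %d, sigma_f^2 = %.4g, sigma_n^2 = %.4g, lengthscales = (%s)\n",
    nrow(x$train$X), x$h$signal_variance, x$h$noise_variance,
    paste(signif(x$h$lengthscales, 4), collapse = ", ")))
  invisible(x)
}
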