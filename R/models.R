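#' Prior specifications
#'
#' A prior is a list carrying the log-density and its gradient with respect to
#' the flat parameter vector. Any list with fields `log_density(theta)` and
#' `grad_log_density(theta)` works; the constructors below provide the two
#' built-in families plus an improper flat prior, all with closed-form
#' gradients and vectorized forms used internally over whole draw matrices.
#'
#' `prior_gaussian`: independent N(0, tau^2) components. `prior_student_t`:
#' independent scaled Student-t components, a simplified heavy-tailed
#' shrinkage prior whose marginal mimics hierarchical shrinkage families
#' while keeping the draw format free of latent scales. `prior_flat`: zero
#' log-density (improper); useful for likelihood-only analyses and oracles.
#'
#' @param tau standard deviation of the Gaussian components.
#' @param df,scale degrees of freedom and scale of the Student-t components.
#' @return A list of class `prior_spec`.
#' @name priors
NULL

#' @rdname priors
#' @export
prior_gaussian <- function(tau = 1) {
  stopifnot(tau > 0)
  structure(list(
    label = sprintf("gaussian(tau=%g)", tau),
    log_density = function(theta) sum(stats::dnorm(theta, 0, tau, log = TRUE)),
    grad_log_density = function(theta) -theta / tau^2,
    log_density_mat = function(draws) rowSums(stats::dnorm(draws, 0, tau, log = TRUE)),
    grad_mat = function(draws) -draws / tau^2
  ), class = "prior_spec")
}

#' @rdname priors
#' @export
prior_student_t <- function(df = 3, scale = 1) {
  stopifnot(df > 0, scale > 0)
  structure(list(
    label = sprintf("student_t(df=%g, scale=%g)", df, scale),
    log_density = function(theta) sum(stats::dt(theta / scale, df, log = TRUE) - log(scale)),
    grad_log_density = function(theta) -(df + 1) * theta / (df * scale^2 + theta^2),
    log_density_mat = function(draws) rowSums(stats::dt(draws / scale, df, log = TRUE) - log(scale)),
    grad_mat = function(draws) -(df + 1) * draws / (df * scale^2 + draws^2)
  ), class = "prior_spec")
}

#' @rdname priors
#' @export
prior_flat <- function() {
  structure(list(
    label = "flat",
    log_density = function(theta) 0,
    grad_log_density = function(theta) numeric(length(theta)),
    log_density_mat = function(draws) numeric(nrow(draws)),
    grad_mat = function(draws) array(0, dim(draws))
  ), class = "prior_spec")
}

# vectorized prior helpers with fallback for user-supplied priors
prior_logdens_mat <- function(prior, draws) {
  if (!is.null(prior$log_density_mat)) return(prior$log_density_mat(draws))
  apply(draws, 1L, prior$log_density)
}
prior_grad_mat <- function(prior, draws) {
  if (!is.null(prior$grad_mat)) return(prior$grad_mat(draws))
  t(apply(draws, 1L, prior$grad_log_density))
}

#' Sigmoidal classification model
#'
#' Binary classifiers of the form p(theta, x) = sigmoid(mu(theta, x)): the
#' likelihood, mean-function gradients, Hessian structure, and prior bundled
#' behind one interface — everything the stabilizing transformations consume.
#'
#' Two kinds are supported. `"logistic_regression"`: mu = x'beta, parameter
#' dimension `p_x`. `"relu_net_1hidden"`: mu = W2 %*% relu(W1 %*% x) + b2 with
#' `d` hidden units; the flat parameter layout is fixed as
#' (W1 row-major, W2, b2), so p = d*p_x + d + 1. A first-layer bias is
#' obtained by giving x a unit constant component, as in regression. The ReLU
#' derivative at exactly zero is taken to be 0 (left-continuous step).
#'
#' @param kind `"logistic_regression"` or `"relu_net_1hidden"`.
#' @param prior a prior spec, see [priors].
#' @param p_x number of covariates (input dimension).
#' @param d number of hidden units (ReLU kind only).
#' @return An object of class `sigmoidal_model` with fields `kind`, `prior`,
#'   `p_x`, `d`, `p` (flat parameter dimension) and `param_names`.
#' @export
sigmoidal_model <- function(kind = c("logistic_regression", "relu_net_1hidden"),
                            prior = prior_gaussian(), p_x, d = NULL) {
  kind <- match.arg(kind)
  stopifnot(p_x >= 1)
  if (kind == "logistic_regression") {
    p <- as.integer(p_x)
    param_names <- paste0("beta", seq_len(p_x))
    d <- NULL
  } else {
    if (is.null(d) || d < 1) stop("relu_net_1hidden requires d >= 1 hidden units", call. = FALSE)
    d <- as.integer(d)
    p <- as.integer(d * p_x + d + 1L)
    param_names <- c(paste0("W1_", rep(seq_len(d), each = p_x), "_", rep(seq_len(p_x), d)),
                     paste0("W2_", seq_len(d)), "b2")
  }
  structure(list(kind = kind, prior = prior, p_x = as.integer(p_x), d = d,
                 p = p, param_names = param_names),
            class = "sigmoidal_model")
}

#' @export
print.sigmoidal_model <- function(x, ...) {
  cat(sprintf("<sigmoidal_model> %s, p_x = %d%s, p = %d, prior = %s\n",
              x$kind, x$p_x,
              if (!is.null(x$d)) sprintf(", d = %d", x$d) else "",
              x$p, x$prior$label))
  invisible(x)
}

# unpack a flat relu parameter vector into W1 (d x p_x), W2 (d), b2
relu_unpack <- function(model, theta) {
  d <- model$d; p_x <- model$p_x
  list(W1 = matrix(theta[seq_len(d * p_x)], nrow = d, byrow = TRUE),
       W2 = theta[d * p_x + seq_len(d)],
       b2 = theta[d * p_x + d + 1L])
}

#' Mean function mu(theta, x)
#'
#' Logistic regression: the linear predictor `x' beta`. One-hidden-layer ReLU
#' network: `W2 %*% max(W1 %*% x, 0) + b2`.
#'
#' @param model a [sigmoidal_model()].
#' @param theta flat parameter vector of length `model$p`.
#' @param x covariate vector of length `model$p_x`.
#' @return Scalar mean-function value.
#' @export
mu <- function(model, theta, x) {
  if (length(theta) != model$p) stop("theta has length ", length(theta),
                                     ", expected ", model$p, call. = FALSE)
  if (length(x) != model$p_x) stop("x has length ", length(x),
                                   ", expected ", model$p_x, call. = FALSE)
  if (model$kind == "logistic_regression") return(sum(x * theta))
  pr <- relu_unpack(model, theta)
  z1 <- drop(pr$W1 %*% x)
  sum(pr$W2 * pmax(z1, 0)) + pr$b2
}

#' Gradient of the mean function with respect to the parameters
#'
#' Logistic regression: the covariate vector itself. ReLU network, in the
#' fixed (W1 row-major, W2, b2) layout: dW1[i,j] = W2[i] * step(z1[i]) * x[j],
#' dW2[i] = relu(z1[i]), db2 = 1, with step(0) = 0.
#'
#' @inheritParams mu
#' @return Numeric vector of length `model$p`.
#' @export
grad_mu <- function(model, theta, x) {
  if (model$kind == "logistic_regression") {
    if (length(x) != model$p_x) stop("dimension mismatch", call. = FALSE)
    return(as.numeric(x))
  }
  pr <- relu_unpack(model, theta)
  z1 <- drop(pr$W1 %*% x)
  act <- as.numeric(z1 > 0)                     # step function, a'(0) = 0
  gW1 <- (pr$W2 * act) %o% x                    # d x p_x, row i = W2[i] act[i] x
  c(as.numeric(t(gW1)), pmax(z1, 0), 1)         # row-major W1, then W2, then b2
}

#' Bernoulli log-likelihood of one observation
#'
#' `y log sigma(mu) + (1 - y) log(1 - sigma(mu))`, evaluated through the
#' numerically stable log-sigmoid so that large |mu| never overflows.
#'
#' @inheritParams mu
#' @param y label, 0 or 1.
#' @return Scalar log-likelihood (always <= 0).
#' @export
log_likelihood <- function(model, theta, x, y) {
  stopifnot(y %in% c(0, 1))
  m <- mu(model, theta, x)
  if (y == 1) stats::plogis(m, log.p = TRUE) else stats::plogis(-m, log.p = TRUE)
}

#' Nonzero Hessian eigenpairs of the ReLU network mean function
#'
#' The Hessian of mu for a one-hidden-layer ReLU network has only mixed
#' (W1 row k) x (W2 k) blocks; per hidden unit k it contributes the 2x2-type
#' coupling between u_k = step(z1_k) x (in the W1 row-k slot) and the unit
#' vector e_k (in the W2 slot), giving eigenvalues
#' `lambda_k(+/-) = +/- sqrt(step(z1_k) * sum(x^2))` (the step function
#' squared equals itself) and eigenvectors
#' `(u_k / (sqrt(2) |u_k|), +/- e_k / sqrt(2), 0)` in the flat layout. Dead
#' units (z1_k <= 0) have eigenvalue 0 and a zero vector column here; all
#' remaining Hessian eigenvalues are exactly 0.
#'
#' @inheritParams mu
#' @return A list with `values` (length 2d, ordered unit 1 +, unit 1 -, ...)
#'   and `vectors` (p x 2d matrix of the associated eigenvectors).
#' @export
relu_hessian_eigs <- function(model, theta, x) {
  if (model$kind != "relu_net_1hidden") {
    stop("relu_hessian_eigs requires a relu_net_1hidden model", call. = FALSE)
  }
  d <- model$d; p_x <- model$p_x; p <- model$p
  pr <- relu_unpack(model, theta)
  z1 <- drop(pr$W1 %*% x)
  act <- as.numeric(z1 > 0)
  xnorm <- sqrt(sum(x^2))
  values <- numeric(2L * d)
  vectors <- matrix(0, nrow = p, ncol = 2L * d)
  for (k in seq_len(d)) {
    lam <- act[k] * xnorm                       # act^2 = act for the step function
    values[2L * k - 1L] <- lam
    values[2L * k] <- -lam
    if (lam > 0) {
      u <- x / (sqrt(2) * xnorm)                # normalized W1 row-k block
      w1_slot <- (k - 1L) * p_x + seq_len(p_x)
      w2_slot <- d * p_x + k
      vectors[w1_slot, 2L * k - 1L] <- u
      vectors[w2_slot, 2L * k - 1L] <- 1 / sqrt(2)
      vectors[w1_slot, 2L * k] <- u
      vectors[w2_slot, 2L * k] <- -1 / sqrt(2)
    }
  }
  list(values = values, vectors = vectors)
}

#' Unnormalized log-posterior
#'
#' `log prior + sum_i log likelihood`; the unknown normalizer is never
#' computed (it is absorbed into the transformation step size downstream).
#'
#' @inheritParams mu
#' @param data a [loo_dataset()]; may have zero rows for the prior-only case
#'   when constructed internally.
#' @return Scalar unnormalized log-posterior density.
#' @export
log_posterior_unnorm <- function(model, theta, data) {
  ll <- 0
  if (!is.null(data) && data$n > 0) {
    for (i in seq_len(data$n)) {
      ll <- ll + log_likelihood(model, theta, data$X[i, ], data$y[i])
    }
  }
  model$prior$log_density(theta) + ll
}

#' Gradient of the unnormalized log-posterior
#'
#' Prior gradient plus `sum_j (y_j - sigma(mu_j)) grad mu_j`: the Bernoulli
#' score coefficient `y(1 - sigma) - (1 - y) sigma` simplifies algebraically
#' to the residual `y - sigma(mu)` (an equivalence exercised in the tests).
#'
#' @inheritParams log_posterior_unnorm
#' @return Numeric vector of length `model$p`.
#' @export
grad_log_posterior <- function(model, theta, data) {
  g <- model$prior$grad_log_density(theta)
  if (!is.null(data) && data$n > 0) {
    for (j in seq_len(data$n)) {
      resid <- data$y[j] - stats::plogis(mu(model, theta, data$X[j, ]))
      g <- g + resid * grad_mu(model, theta, data$X[j, ])
    }
  }
  g
}

## ---- vectorized internals over a full draw matrix -------------------------

# s x n matrix of mean-function values
mu_matrix <- function(model, draws_mat, X) {
  if (model$kind == "logistic_regression") return(draws_mat %*% t(X))
  s <- nrow(draws_mat)
  out <- matrix(0, s, nrow(X))
  for (k in seq_len(s)) {
    pr <- relu_unpack(model, draws_mat[k, ])
    Z <- pmax(pr$W1 %*% t(X), 0)                # d x n
    out[k, ] <- drop(pr$W2 %*% Z) + pr$b2
  }
  out
}

# s x n matrix of pointwise log-likelihoods, from the mu matrix
loglik_from_mu <- function(mu_mat, y) {
  out <- mu_mat
  for (j in seq_along(y)) {
    out[, j] <- if (y[j] == 1) stats::plogis(mu_mat[, j], log.p = TRUE)
                else stats::plogis(-mu_mat[, j], log.p = TRUE)
  }
  out
}

loglik_matrix <- function(model, draws_mat, data) {
  loglik_from_mu(mu_matrix(model, draws_mat, data$X), data$y)
}


# s-vector of unnormalized log-posteriors (optionally reusing a loglik matrix)
log_posterior_vec <- function(model, draws_mat, data, ll = NULL) {
  if (is.null(ll)) ll <- loglik_matrix(model, draws_mat, data)
  prior_logdens_mat(model$prior, draws_mat) + rowSums(ll)
}

# s x p matrix of mean-function gradients for a single covariate vector
grad_mu_all <- function(model, draws_mat, x) {
  s <- nrow(draws_mat)
  if (model$kind == "logistic_regression") {
    return(matrix(x, nrow = s, ncol = length(x), byrow = TRUE))
  }
  out <- matrix(0, s, model$p)
  for (k in seq_len(s)) out[k, ] <- grad_mu(model, draws_mat[k, ], x)
  out
}

# s x p matrix of unnormalized log-posterior gradients
grad_log_posterior_all <- function(model, draws_mat, data, mu_mat = NULL) {
  g <- prior_grad_mat(model$prior, draws_mat)
  if (is.null(mu_mat)) mu_mat <- mu_matrix(model, draws_mat, data$X)
  resid <- matrix(rep(data$y, each = nrow(draws_mat)), nrow(draws_mat)) -
    stats::plogis(mu_mat)                       # s x n
  if (model$kind == "logistic_regression") {
    g + resid %*% data$X
  } else {
    for (k in seq_len(nrow(draws_mat))) {
      acc <- numeric(model$p)
      for (j in seq_len(data$n)) {
        acc <- acc + resid[k, j] * grad_mu(model, draws_mat[k, ], data$X[j, ])
      }
      g[k, ] <- g[k, ] + acc
    }
    g
  }
}
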