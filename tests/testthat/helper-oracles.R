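# Shared oracles and fixture builders. Everything is generated in code under
# fixed seeds; no stored data.

# inverse-CDF generator for the generalized Pareto distribution (threshold 0)
rgpd_oracle <- function(n, k, sigma = 1) {
  u <- runif(n)
  if (abs(k) < 1e-12) -sigma * log(u) else sigma * expm1(-k * log(u)) / k
}

# small random logistic-regression problem
make_lr_problem <- function(n = 8, p = 5, seed = 1, prior = prior_gaussian(2)) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- rbinom(n, 1, 0.5)
  list(model = sigmoidal_model("logistic_regression", prior, p_x = p),
       data = loo_dataset(X, y))
}

# small random one-hidden-layer ReLU problem
make_relu_problem <- function(n = 6, p_x = 4, d = 3, seed = 1,
                              prior = prior_gaussian(2)) {
  set.seed(seed)
  X <- matrix(rnorm(n * p_x), n, p_x)
  y <- rbinom(n, 1, 0.5)
  list(model = sigmoidal_model("relu_net_1hidden", prior, p_x = p_x, d = d),
       data = loo_dataset(X, y))
}

# dense finite-difference Jacobian determinant of the map
# T(theta) = theta + h * Q(theta) for the KL/Var fields (c = 1 or 2)
fd_jac_det <- function(model, theta, obs, data, h, method) {
  cc <- if (method == "KL") 1 else 2
  Tmap <- function(t) {
    m <- mu(model, t, obs$x)
    coef <- (-1)^obs$y *
      exp(log(h) + log_posterior_unnorm(model, t, data) + cc * m * (1 - 2 * obs$y))
    t + coef * grad_mu(model, t, obs$x)
  }
  det(pracma::jacobian(Tmap, theta))
}

# Mann-Whitney concordance AUROC oracle (ties count one half)
concordance_auroc <- function(p, y) {
  pos <- p[y == 1]; neg <- p[y == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# keep the RNG state of one test from leaking into the next
local_seed <- function(seed, env = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  withr::defer(if (!is.null(old)) assign(".Random.seed", old, globalenv()), envir = env)
}
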