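#' Generate a synthetic sparse binary-classification problem
#'
#' Emulates the study design that makes raw 1/likelihood LOO importance
#' weights heavy-tailed: far more predictors than observations, a handful of
#' truly active coefficients, and optional equicorrelation among covariates
#' (a single-knob stand-in for the multicollinearity of expression-array
#' data). Covariates are standard normal (with common-factor correlation
#' `rho` when requested), the true coefficient vector has `sparsity` entries
#' of alternating sign and magnitude `effect_size`, and labels are Bernoulli
#' with success probability `sigmoid(X beta)`. The output is a pure function
#' of the seed.
#'
#' Defaults for the unstable regime are `n = 50`, `p_x = 300`,
#' `sparsity = 5`, `effect_size = 2`: a desk-scale n << p problem for which
#' raw importance sampling reliably produces observations with tail-shape
#' diagnostic above 0.7.
#'
#' @param n observations.
#' @param p_x predictors; the unstable regime requires `p_x > n`.
#' @param sparsity number of nonzero true coefficients.
#' @param effect_size magnitude of each nonzero coefficient.
#' @param regime `"unstable_npp"` (n << p, the default study condition) or
#'   `"stable"`.
#' @param seed integer seed.
#' @param rho equicorrelation of the covariates (0 = independent).
#' @return A list with `data` (a [loo_dataset()]) and `true_theta`.
#' @export
generate_classification <- function(n = 50, p_x = 300, sparsity = 5,
                                    effect_size = 2,
                                    regime = c("unstable_npp", "stable"),
                                    seed = 1L, rho = 0) {
  regime <- match.arg(regime)
  if (regime == "unstable_npp" && p_x <= n) {
    stop("unstable_npp regime requires p_x > n", call. = FALSE)
  }
  stopifnot(sparsity <= p_x, rho >= 0, rho < 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(child_seed(seed, 0L, "generate"))
  X <- matrix(stats::rnorm(n * p_x), n, p_x)
  if (rho > 0) {
    z <- stats::rnorm(n)
    X <- sqrt(rho) * z + sqrt(1 - rho) * X
  }
  beta <- numeric(p_x)
  if (sparsity > 0) {
    idx <- sample.int(p_x, sparsity)
    beta[idx] <- effect_size * (-1)^(seq_len(sparsity) - 1)
  }
  y <- stats::rbinom(n, 1, stats::plogis(drop(X %*% beta)))
  # degenerate all-one/all-zero label vectors make ROC undefined; resample
  # labels (only) with fresh sub-seeds until both classes appear
  tries <- 0L
  while (length(unique(y)) < 2L && tries < 100L) {
    tries <- tries + 1L
    set.seed(child_seed(seed, tries, "labels"))
    y <- stats::rbinom(n, 1, stats::plogis(drop(X %*% beta)))
  }
  colnames(X) <- paste0("x", seq_len(p_x))
  list(data = loo_dataset(X, y), true_theta = beta)
}

#' Deterministic grid posterior with i.i.d. resampled draws
#'
#' For parameter dimension at most 2, evaluates the unnormalized posterior on
#' a regular grid (the quadrature "truth" channel) and resamples `s`
#' independent draws from the grid probabilities. Grid limits default to the
#' posterior mode plus/minus `width` Laplace standard deviations.
#'
#' @param model a [sigmoidal_model()] with `model$p <= 2`.
#' @param data a [loo_dataset()].
#' @param grid_spec list with optional `lower`, `upper` (length-p limits),
#'   `n_grid` (points per dimension, default 160), `s` (number of resampled
#'   draws, default 4000), `seed`, `width` (default 8).
#' @return An object of class `grid_posterior`: `draws` (a
#'   [posterior_draws()]), `grid` (matrix of nodes), `log_density`
#'   (unnormalized, per node), `probs` (normalized node masses) and
#'   `log_norm` (log of the grid normalizer times the cell volume).
#' @export
grid_posterior_sampler <- function(model, data, grid_spec = list()) {
  p <- model$p
  if (p > 2L) stop("grid_posterior_sampler supports p <= 2 only", call. = FALSE)
  n_grid <- grid_spec$n_grid %||% 160L
  s <- grid_spec$s %||% 4000L
  seed <- grid_spec$seed %||% 1L
  width <- grid_spec$width %||% 8
  if (is.null(grid_spec$lower) || is.null(grid_spec$upper)) {
    opt <- stats::optim(numeric(p), function(th) -log_posterior_unnorm(model, th, data),
                        gr = function(th) -grad_log_posterior(model, th, data),
                        method = "BFGS", hessian = TRUE)
    sds <- sqrt(diag(solve(opt$hessian)))
    lower <- grid_spec$lower %||% (opt$par - width * sds)
    upper <- grid_spec$upper %||% (opt$par + width * sds)
  } else {
    lower <- grid_spec$lower; upper <- grid_spec$upper
  }
  axes <- lapply(seq_len(p), function(j) seq(lower[j], upper[j], length.out = n_grid))
  grid <- as.matrix(expand.grid(axes))
  colnames(grid) <- paste0("theta", seq_len(p))
  ld <- log_posterior_vec(model, grid, data)
  m <- max(ld)
  probs <- exp(ld - m)
  cell <- prod(vapply(axes, function(a) a[2] - a[1], 0.0))
  log_norm <- m + log(sum(probs)) + log(cell)
  probs <- probs / sum(probs)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(child_seed(seed, 0L, "grid_resample"))
  idx <- sample.int(nrow(grid), s, replace = TRUE, prob = probs)
  structure(list(draws = posterior_draws(grid[idx, , drop = FALSE],
                                         param_names = colnames(grid)),
                 grid = grid, log_density = ld, probs = probs,
                 log_norm = log_norm),
            class = "grid_posterior")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quadrature expectation over a grid posterior
#'
#' @param gp a `grid_posterior`.
#' @param f function of the parameter vector (vectorized over grid rows via
#'   `apply` unless `f_vec` supplies node values directly).
#' @param f_vec optional precomputed per-node values of f.
#' @return The posterior expectation of f under the grid measure.
#' @export
grid_expect <- function(gp, f = NULL, f_vec = NULL) {
  if (is.null(f_vec)) f_vec <- apply(gp$grid, 1L, f)
  sum(gp$probs * f_vec)
}

#' Adaptive random-walk Metropolis posterior sampler
#'
#' A lightweight stand-in for full MCMC: Gaussian random-walk Metropolis
#' targeting the unnormalized log-posterior, with two warmup phases (global
#' scale adaptation toward 23% acceptance, then componentwise preconditioning
#' from the warmup draws plus renewed scale adaptation). All adaptation is
#' frozen after warmup, so the sampling phase satisfies detailed balance.
#' Thinned draws are returned; acceptance diagnostics are attached as
#' attributes, reported but never enforced.
#'
#' @param model a [sigmoidal_model()].
#' @param data a [loo_dataset()].
#' @param n_draws number of retained draws.
#' @param seed integer seed.
#' @param warmup total warmup iterations (split across the two phases).
#' @param thin keep every `thin`-th post-warmup iteration.
#' @param init optional initial parameter vector (default zero).
#' @return A [posterior_draws()] object with attributes `accept_rate` and
#'   `proposal_scale`.
#' @export
mh_posterior_sampler <- function(model, data, n_draws = 1000L, seed = 1L,
                                 warmup = 4000L, thin = 5L, init = NULL) {
  p <- model$p
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(child_seed(seed, 0L, "mh"))
  theta <- if (is.null(init)) numeric(p) else init
  lp <- log_posterior_unnorm(model, theta, data)
  log_scale <- log(2.38 / sqrt(p))
  mass <- rep(1, p)
  half <- floor(warmup / 2)
  phase1 <- matrix(0, half, p)
  # fast log-posterior via one-row matrix routines
  lp_fun <- function(th) {
    ll <- loglik_from_mu(mu_matrix(model, rbind(th), data$X), data$y)
    model$prior$log_density(th) + sum(ll)
  }
  step <- function() {
    prop <- theta + exp(log_scale) * mass * stats::rnorm(p)
    lp_prop <- lp_fun(prop)
    if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp) {
      theta <<- prop; lp <<- lp_prop; TRUE
    } else FALSE
  }
  for (t in seq_len(half)) {
    acc <- step()
    log_scale <- log_scale + (as.numeric(acc) - 0.23) / sqrt(t)
    phase1[t, ] <- theta
  }
  sds <- apply(phase1[seq(max(1, half / 2), half), , drop = FALSE], 2L, stats::sd)
  if (any(sds > 0)) mass <- pmax(sds, max(sds) * 1e-3) / max(sds)
  for (t in seq_len(warmup - half)) {
    acc <- step()
    log_scale <- log_scale + (as.numeric(acc) - 0.23) / sqrt(t)
  }
  n_acc <- 0L
  out <- matrix(0, n_draws, p)
  for (k in seq_len(n_draws)) {
    for (j in seq_len(thin)) n_acc <- n_acc + as.numeric(step())
    out[k, ] <- theta
  }
  pd <- posterior_draws(out, param_names = model$param_names)
  attr(pd, "accept_rate") <- n_acc / (n_draws * thin)
  attr(pd, "proposal_scale") <- exp(log_scale)
  pd
}

#' Brute-force LOO by refitting: the oracle this package exists to avoid
#'
#' For each observation, re-runs inference (quadrature for p <= 2, the
#' Metropolis sampler otherwise) on the dataset with that observation
#' removed, and records the refit posterior expectation of the outcome
#' probability and the log LOO predictive density, with Monte Carlo standard
#' errors (zero for quadrature, which the package treats as exact).
#'
#' @param model a [sigmoidal_model()].
#' @param data a [loo_dataset()].
#' @param sampler_spec list with `type` (`"grid"` or `"mh"`), `seed`, and the
#'   sampler's own options (`n_grid`, `n_draws`, `warmup`, `thin`).
#' @return A data.frame with one row per observation: `index`, `p_loo`,
#'   `p_loo_se`, `elpd`, `elpd_se`.
#' @export
brute_force_loo <- function(model, data, sampler_spec = list(type = "grid")) {
  type <- sampler_spec$type %||% "grid"
  seed <- sampler_spec$seed %||% 1L
  n <- data$n
  out <- data.frame(index = seq_len(n), p_loo = NA_real_, p_loo_se = 0,
                    elpd = NA_real_, elpd_se = 0)
  for (i in seq_len(n)) {
    di <- loo_dataset(data$X[-i, , drop = FALSE], data$y[-i])
    x_i <- data$X[i, ]; y_i <- data$y[i]
    if (type == "grid") {
      if (model$p > 2L) stop("grid oracle requires p <= 2", call. = FALSE)
      gp <- grid_posterior_sampler(model, di,
                                   grid_spec = c(sampler_spec[c("n_grid", "lower", "upper", "width")],
                                                 list(s = 2L, seed = child_seed(seed, i, "bf"))))
      mu_g <- drop(mu_matrix(model, gp$grid, rbind(x_i)))
      p_g <- stats::plogis(mu_g)
      lik_g <- if (y_i == 1) p_g else 1 - p_g
      out$p_loo[i] <- sum(gp$probs * p_g)
      out$elpd[i] <- log(sum(gp$probs * lik_g))
    } else {
      if (model$p > 5L) stop("MH oracle intended for p <= 5", call. = FALSE)
      pd <- mh_posterior_sampler(model, di,
                                 n_draws = sampler_spec$n_draws %||% 4000L,
                                 seed = child_seed(seed, i, "bf"),
                                 warmup = sampler_spec$warmup %||% 2000L,
                                 thin = sampler_spec$thin %||% 2L)
      mu_d <- drop(mu_matrix(model, pd$draws, rbind(x_i)))
      p_d <- stats::plogis(mu_d)
      lik_d <- if (y_i == 1) p_d else 1 - p_d
      s <- length(p_d)
      out$p_loo[i] <- mean(p_d)
      out$p_loo_se[i] <- stats::sd(p_d) / sqrt(s)
      out$elpd[i] <- log(mean(lik_d))
      out$elpd_se[i] <- stats::sd(lik_d) / sqrt(s) / mean(lik_d)
    }
  }
  out
}
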