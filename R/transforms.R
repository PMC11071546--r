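#' Transformation result container
#'
#' Holds the transformed draws phi = T(theta), the per-draw log Jacobian
#' determinants of the map, the method label, and the realized and relative
#' step sizes.
#'
#' @param phi s x p matrix of transformed draws.
#' @param log_jac numeric vector of per-draw log |det J_T(theta_k)|.
#' @param method one of `"PMM1","PMM2","MM1","MM2","KL","Var","LL","identity"`.
#' @param h realized step size (0 for the identity).
#' @param hbar relative step size in posterior-standard-deviation units.
#' @param observation index of the held-out observation, or `NA` for the
#'   observation-independent moment-matching maps.
#' @param log_h log of the realized step size, kept alongside `h` because the
#'   unnormalized-posterior magnitude absorbed into `h` can place it outside
#'   double range.
#' @return An object of class `transform_result`.
#' @export
transform_result <- function(phi, log_jac, method, h, hbar,
                             observation = NA_integer_, log_h = log(h)) {
  stopifnot(method %in% c("PMM1", "PMM2", "MM1", "MM2", "KL", "Var", "LL", "identity"))
  if (any(!is.finite(phi))) stop("non-finite transformed draws", call. = FALSE)
  if (any(!is.finite(log_jac))) stop("non-finite log-Jacobian", call. = FALSE)
  structure(list(phi = phi, log_jac = log_jac, method = method, h = h,
                 hbar = hbar, observation = observation, log_h = log_h),
            class = "transform_result")
}

#' @export
print.transform_result <- function(x, ...) {
  cat(sprintf("<transform_result> %s, hbar = %g, h = %g, %d draws\n",
              x$method, x$hbar, x$h, nrow(x$phi)))
  invisible(x)
}

identity_transform <- function(draws_mat, hbar, observation = NA_integer_) {
  transform_result(draws_mat, numeric(nrow(draws_mat)), "identity",
                   h = 0, hbar = hbar, observation = observation, log_h = -Inf)
}

#' Partial moment matching of the first moment (PMM1)
#'
#' Translates every draw a fraction `hbar` of the way from the plain sample
#' mean to the importance-weighted mean: `phi_k = theta_k + hbar (m_w - m)`.
#' A pure translation, so the log Jacobian determinant is 0 for every draw.
#' `hbar = 1` recovers the full moment-matching map MM1.
#'
#' @param draws a [posterior_draws()] object or an s x p matrix.
#' @param nu self-normalized importance weights of length s.
#' @param hbar relative step size in `[0, 1]`.
#' @return A [transform_result()].
#' @export
pmm1 <- function(draws, nu, hbar) {
  theta <- if (inherits(draws, "posterior_draws")) draws$draws else as.matrix(draws)
  stopifnot(length(nu) == nrow(theta), abs(sum(nu) - 1) < 1e-8)
  m <- colMeans(theta)
  m_w <- drop(crossprod(nu, theta))
  shift <- hbar * (m_w - m)
  phi <- sweep(theta, 2L, shift, "+")
  transform_result(phi, numeric(nrow(theta)), "PMM1", h = hbar, hbar = hbar,
                   log_h = log(hbar))
}

#' Partial moment matching of the first two moments (PMM2)
#'
#' Componentwise affine map pulling both the mean and the marginal variance a
#' fraction `hbar` of the way to their importance-weighted targets:
#' `phi_k = theta_k + hbar ( sqrt(v_w / v) * (theta_k - m) + m_w - theta_k )`,
#' where `v` is the plain per-component variance (1/s denominator) and `v_w`
#' the nu-weighted second moment about the plain mean. The map is diagonal
#' affine, so the log Jacobian determinant,
#' `sum_a log |1 + hbar (sqrt(v_w/v)_a - 1)|`, is identical for all draws.
#' Components with zero plain variance are passed through unchanged.
#' `hbar = 1` recovers MM2: the transformed sample's plain mean and variance
#' equal the weighted targets exactly.
#'
#' @inheritParams pmm1
#' @return A [transform_result()].
#' @export
pmm2 <- function(draws, nu, hbar) {
  theta <- if (inherits(draws, "posterior_draws")) draws$draws else as.matrix(draws)
  s <- nrow(theta)
  stopifnot(length(nu) == s, abs(sum(nu) - 1) < 1e-8)
  m <- colMeans(theta)
  m_w <- drop(crossprod(nu, theta))
  cent <- sweep(theta, 2L, m)
  v <- colMeans(cent^2)
  v_w <- drop(crossprod(nu, cent^2))
  r <- rep(1, ncol(theta))
  pos <- v > 0
  r[pos] <- sqrt(v_w[pos] / v[pos])
  shift <- m_w - m
  shift[!pos] <- 0                             # constant components stay put
  fac <- 1 + hbar * (r - 1)
  if (any(fac <= 0)) stop("transformation not bijective: reduce hbar", call. = FALSE)
  # phi = theta + hbar * ((r - 1) * (theta - m) + m_w - m): exactly theta at
  # hbar = 0; zero-variance components have r = 1 and m_w = m, so they pass
  # through unchanged
  phi <- theta + hbar * sweep(sweep(cent, 2L, r - 1, "*"), 2L, shift, "+")
  lj <- rep(sum(log(fac)), s)
  transform_result(phi, lj, "PMM2", h = hbar, hbar = hbar, log_h = log(hbar))
}

## ---- gradient-flow perturbation fields ------------------------------------

# sign / log-magnitude / direction decomposition of Q for one draw.
# KL:  Q = (-1)^y  pi(theta|D) exp(  mu (1-2y)) grad mu
# Var: Q = (-1)^y  pi(theta|D) exp(2 mu (1-2y)) grad mu
# LL:  Q = (sigma(mu) - y) grad mu
q_decomp <- function(model, theta, observation, data, method) {
  x <- observation$x; y <- observation$y
  m <- mu(model, theta, x)
  dir <- grad_mu(model, theta, x)
  if (method == "LL") {
    r <- stats::plogis(m) - y
    return(list(sign = sign(r), log_mag = log(abs(r)), direction = dir))
  }
  cc <- if (method == "KL") 1 else 2
  list(sign = (-1)^y,
       log_mag = log_posterior_unnorm(model, theta, data) + cc * m * (1 - 2 * y),
       direction = dir)
}

#' Gradient-flow perturbation fields Q(theta)
#'
#' The three model-specific vector fields whose forward-Euler step
#' `T(theta) = theta + h Q(theta)` defines the gradient-flow transformations,
#' returned in an overflow-safe sign / log-magnitude / direction
#' decomposition (`Q = sign * exp(log_mag) * direction`):
#'
#' * `q_kl`: one step descending the KL divergence between the transformed
#'   proposal and the LOO target; for sigmoidal models
#'   `Q = (-1)^y pi(theta|D) exp(mu (1-2y)) grad mu`, equivalently
#'   `pi(theta|D) grad(1/likelihood)`. The posterior density is unnormalized;
#'   its constant is absorbed into the step size.
#' * `q_var`: one step descending the variance of the importance-sampling
#'   estimator of the complement outcome probability; same form with the
#'   exponent doubled.
#' * `q_ll`: descent of the held-out point's negative log-likelihood,
#'   `Q = (sigma(mu) - y) grad mu` — the comparison baseline.
#'
#' @param model a [sigmoidal_model()].
#' @param theta flat parameter vector.
#' @param observation list with elements `x` (covariates) and `y` (label) of
#'   the held-out point.
#' @param data the full [loo_dataset()] (used for the posterior density).
#' @return A list with `sign`, `log_mag` and `direction`.
#' @name q_fields
NULL

#' @rdname q_fields
#' @export
q_kl <- function(model, theta, observation, data) {
  q_decomp(model, theta, observation, data, "KL")
}

#' @rdname q_fields
#' @export
q_var <- function(model, theta, observation, data) {
  q_decomp(model, theta, observation, data, "Var")
}

#' @rdname q_fields
#' @export
q_ll <- function(model, theta, observation) {
  q_decomp(model, theta, observation, NULL, "LL")
}

# vectorized decomposition over a draw matrix; ctx may carry log_post (s),
# mu_i (s) and dir (s x p) precomputed
q_decomp_all <- function(model, draws_mat, i, data, method, ctx = NULL) {
  x <- data$X[i, ]; y <- data$y[i]
  mu_i <- if (!is.null(ctx$mu_mat)) ctx$mu_mat[, i] else drop(mu_matrix(model, draws_mat, rbind(x)))
  dir <- if (!is.null(ctx$dir)) ctx$dir else grad_mu_all(model, draws_mat, x)
  if (method == "LL") {
    r <- stats::plogis(mu_i) - y
    return(list(sign = sign(r), log_mag = log(abs(r)), dir = dir, mu_i = mu_i))
  }
  lp <- if (!is.null(ctx$log_post)) ctx$log_post else log_posterior_vec(model, draws_mat, data)
  cc <- if (method == "KL") 1 else 2
  list(sign = rep((-1)^y, nrow(draws_mat)),
       log_mag = lp + cc * mu_i * (1 - 2 * y),
       dir = dir, mu_i = mu_i)
}

#' Step size from the at-most-hbar-standard-deviations rule
#'
#' `h = hbar * min over draws k and components a of sd_a / |Q[k, a]|`, so that
#' every component of every draw moves at most `hbar` marginal posterior
#' standard deviations. Components with zero posterior standard deviation and
#' zero entries of Q are excluded from the minimum.
#'
#' @param Q_all s x p matrix of per-draw perturbation vectors.
#' @param posterior_sd length-p vector of marginal posterior standard
#'   deviations of the draws.
#' @param hbar relative step size.
#' @return The step size `h`, or `NA` (the identity-step sentinel) when every
#'   entry of `Q_all` is zero.
#' @export
step_size <- function(Q_all, posterior_sd, hbar) {
  Q_all <- as.matrix(Q_all)
  stopifnot(ncol(Q_all) == length(posterior_sd))
  use <- posterior_sd > 0
  A <- abs(Q_all[, use, drop = FALSE])
  if (all(A == 0)) return(NA_real_)
  ratio <- sweep(1 / A, 2L, posterior_sd[use], "*")   # sd / |Q|; Inf where Q = 0
  hbar * min(ratio)
}

# log-space step size: returns log h such that
# max_{k,a} (log_mag_k + log|dir_ka| - log sd_a) + log h = log hbar
step_size_log <- function(log_mag, dir, log_sd, hbar) {
  finite_sd <- is.finite(log_sd)
  A <- log(abs(dir[, finite_sd, drop = FALSE]))       # -Inf where dir = 0
  M <- sweep(A + log_mag, 2L, log_sd[finite_sd], "-")
  logM <- max(M)
  if (!is.finite(logM)) return(-Inf)                  # identity-step sentinel
  log(hbar) - logM
}

#' First-order log Jacobian determinant
#'
#' The divergence-only truncation `log |1 + h div Q(theta)|`, valid to O(h^2);
#' it sidesteps Hessian spectra entirely and is the rule used for models and
#' methods without a closed-form determinant. For maps whose Jacobian is rank
#' one (logistic regression with any of the three fields) the truncation is
#' exact.
#'
#' @param divergence scalar divergence of Q at theta.
#' @param h realized step size.
#' @return `log |1 + h * divergence|`.
#' @export
jac_logdet_first_order <- function(divergence, h) {
  v <- 1 + h * divergence
  if (v == 0) stop("degenerate first-order Jacobian; reduce h", call. = FALSE)
  log(abs(v))
}

#' Exact log Jacobian determinant: logistic regression, KL/Var fields
#'
#' For logistic regression the Jacobian of Q is rank one, so
#' `det(I + h grad Q) = 1 + h (-1)^y pi(theta|D) exp(c mu (1-2y))
#'  x' [grad log pi(theta|D) + c (1-2y) x]` with `c = 1` (KL) or `2` (Var);
#' all densities are unnormalized, with the same constant-into-h convention
#' used by the step-size rule.
#'
#' @inheritParams q_fields
#' @param h realized step size (> 0).
#' @param method `"KL"` or `"Var"`.
#' @param log_h optional log step size, overriding `log(h)`; lets callers
#'   keep the product `h * pi(theta|D)` in log space.
#' @return Scalar log |det J_T(theta)|.
#' @export
jac_logdet_lr_exact <- function(model, theta, observation, data, h,
                                method = c("KL", "Var"), log_h = log(h)) {
  method <- match.arg(method)
  if (model$kind != "logistic_regression") {
    stop("jac_logdet_lr_exact requires a logistic_regression model", call. = FALSE)
  }
  x <- observation$x; y <- observation$y
  cc <- if (method == "KL") 1 else 2
  m <- mu(model, theta, x)
  g <- grad_log_posterior(model, theta, data) + cc * (1 - 2 * y) * x
  amp <- exp(log_h + log_posterior_unnorm(model, theta, data) + cc * m * (1 - 2 * y))
  t_val <- (-1)^y * amp * sum(x * g)
  v <- 1 + t_val
  if (v == 0) stop("degenerate map: Jacobian determinant is zero", call. = FALSE)
  log(abs(v))
}

# log |det(I + alpha H + w v')| where H is the mean-function Hessian of a
# one-hidden-layer ReLU net, evaluated in the small invariant subspace
# spanned by the 2d' active eigenvectors plus w and v (dimension <= 2d'+2)
logdet_relu_core <- function(model, theta, x, alpha, w, v) {
  eig <- relu_hessian_eigs(model, theta, x)
  act <- which(eig$values != 0)
  basis <- cbind(eig$vectors[, act, drop = FALSE], w, v)
  keep <- colSums(abs(basis)) > 0
  basis <- basis[, keep, drop = FALSE]
  if (ncol(basis) == 0L) return(0)
  qrd <- qr(basis)
  S <- qr.Q(qrd)[, seq_len(qrd$rank), drop = FALSE]
  SV <- crossprod(S, eig$vectors[, act, drop = FALSE])      # m x 2d'
  small <- alpha * (SV %*% (eig$values[act] * t(SV))) +
    tcrossprod(crossprod(S, w), crossprod(S, v))
  dt <- determinant(diag(ncol(small)) + small, logarithm = TRUE)
  if (!is.finite(dt$modulus)) {
    stop("degenerate map: Jacobian determinant is zero", call. = FALSE)
  }
  as.numeric(dt$modulus)
}

#' Exact log Jacobian determinant: one-hidden-layer ReLU net, KL/Var fields
#'
#' `h grad Q = a [H_mu + grad g (grad mu)']` with
#' `a = h (-1)^y pi(theta|D) exp(c mu (1-2y))` and
#' `g = log pi(theta|D) + c mu (1-2y)`. The mean-function Hessian H_mu has at
#' most 2d nonzero eigenpairs with closed forms, so the determinant is
#' evaluated in the invariant subspace spanned by those eigenvectors plus the
#' two rank-one factor vectors — a dense matrix of dimension at most 2d + 2 —
#' leaving the orthogonal complement's contribution at exactly 1.
#'
#' @inheritParams jac_logdet_lr_exact
#' @return Scalar log |det J_T(theta)|.
#' @export
jac_logdet_relu_exact <- function(model, theta, observation, data, h,
                                  method = c("KL", "Var"), log_h = log(h)) {
  method <- match.arg(method)
  if (model$kind != "relu_net_1hidden") {
    stop("jac_logdet_relu_exact requires a relu_net_1hidden model", call. = FALSE)
  }
  x <- observation$x; y <- observation$y
  cc <- if (method == "KL") 1 else 2
  m <- mu(model, theta, x)
  dmu <- grad_mu(model, theta, x)
  gg <- grad_log_posterior(model, theta, data) + cc * (1 - 2 * y) * dmu
  alpha <- (-1)^y *
    exp(log_h + log_posterior_unnorm(model, theta, data) + cc * m * (1 - 2 * y))
  logdet_relu_core(model, theta, x, alpha, alpha * gg, dmu)
}

#' Apply a gradient-flow transformation to all draws
#'
#' Evaluates the chosen perturbation field Q at every draw, picks the step
#' size by the at-most-hbar-posterior-standard-deviations rule, forms
#' `phi_k = theta_k + h Q(theta_k)`, and attaches per-draw log Jacobian
#' determinants using the best available rule: exact for logistic regression
#' (KL/Var), exact eigenstructure-based for one-hidden-layer ReLU nets
#' (KL/Var), first-order divergence truncation otherwise. All magnitudes are
#' carried in log space, so the unnormalized-posterior factor inside Q never
#' overflows; results are invariant to adding any constant to the
#' unnormalized log-posterior.
#'
#' If every Q entry is zero (the identity-step sentinel) the identity
#' transform is returned with `method = "identity"`.
#'
#' @param draws a [posterior_draws()] object or s x p matrix.
#' @param model a [sigmoidal_model()].
#' @param observation index of the held-out observation in `data`.
#' @param data the full [loo_dataset()].
#' @param method `"KL"`, `"Var"` or `"LL"`.
#' @param hbar relative step size.
#' @param ctx optional precomputed context (internal use by [run_loo()]).
#' @return A [transform_result()].
#' @export
apply_gradient_transform <- function(draws, model, observation, data,
                                     method = c("KL", "Var", "LL"), hbar,
                                     ctx = NULL) {
  method <- match.arg(method)
  theta <- if (inherits(draws, "posterior_draws")) draws$draws else as.matrix(draws)
  i <- observation
  qa <- q_decomp_all(model, theta, i, data, method, ctx)
  log_sd <- if (!is.null(ctx$log_sd)) ctx$log_sd else {
    sds <- apply(theta, 2L, stats::sd)
    ifelse(sds > 0, log(sds), -Inf)
  }
  log_h <- step_size_log(qa$log_mag, qa$dir, log_sd, hbar)
  if (!is.finite(log_h)) {
    return(identity_transform(theta, hbar, i))
  }
  coef <- qa$sign * exp(log_h + qa$log_mag)            # h * sign * |Q magnitude|
  phi <- theta + coef * qa$dir
  x <- data$X[i, ]; y <- data$y[i]
  cc <- if (method == "KL") 1 else 2
  if (method %in% c("KL", "Var") && model$kind == "logistic_regression") {
    gpost <- if (!is.null(ctx$grad_post)) ctx$grad_post else
      grad_log_posterior_all(model, theta, data)
    g <- sweep(gpost, 2L, cc * (1 - 2 * y) * x, "+")
    t_val <- coef * drop(g %*% x)
    v <- 1 + t_val
    if (any(v == 0)) stop("degenerate map: Jacobian determinant is zero", call. = FALSE)
    lj <- log(abs(v))
  } else if (method %in% c("KL", "Var") && model$kind == "relu_net_1hidden") {
    gpost <- if (!is.null(ctx$grad_post)) ctx$grad_post else
      grad_log_posterior_all(model, theta, data)
    lj <- vapply(seq_len(nrow(theta)), function(k) {
      gg <- gpost[k, ] + cc * (1 - 2 * y) * qa$dir[k, ]
      logdet_relu_core(model, theta[k, ], x, coef[k], coef[k] * gg, qa$dir[k, ])
    }, 0.0)
  } else {
    # LL (or any other field): first-order divergence rule; the trace of the
    # mean-function Hessian is identically zero for both model kinds, so
    # div Q_LL = sigma'(mu) |grad mu|^2
    sig <- stats::plogis(qa$mu_i)
    h_div <- exp(log_h) * sig * (1 - sig) * rowSums(qa$dir^2)
    v <- 1 + h_div
    if (any(v == 0)) stop("degenerate first-order Jacobian; reduce h", call. = FALSE)
    lj <- log(abs(v))
  }
  transform_result(phi, lj, method, h = exp(log_h), hbar = hbar,
                   observation = i, log_h = log_h)
}
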