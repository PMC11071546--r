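test_that("PMM1 translates the sample toward the weighted mean", {
  local_seed(51)
  dm <- matrix(rnorm(300 * 4), 300)
  nu <- self_normalize(rnorm(300))
  # zero step: identity with zero log-Jacobian
  tr0 <- pmm1(dm, nu, 0)
  expect_identical(tr0$phi, dm)
  expect_identical(tr0$log_jac, rep(0, 300))
  # uniform weights: the weighted mean equals the plain mean
  tru <- pmm1(dm, rep(1 / 300, 300), 1)
  expect_equal(tru$phi, dm, tolerance = 1e-12)
  # full step: the transformed plain mean equals the weighted mean
  tr1 <- pmm1(dm, nu, 1)
  expect_equal(colMeans(tr1$phi), drop(crossprod(nu, dm)), tolerance = 1e-12)
  expect_identical(tr1$log_jac, rep(0, 300))
})

test_that("PMM2 matches both moments at full step with a diagonal Jacobian", {
  local_seed(52)
  dm <- matrix(rnorm(500 * 3, sd = c(1, 4, 0.2)), 500, byrow = TRUE)
  nu <- self_normalize(0.7 * rnorm(500))
  tr0 <- pmm2(dm, nu, 0)
  expect_equal(tr0$phi, dm)
  expect_identical(tr0$log_jac, rep(0, 500))
  tr1 <- pmm2(dm, nu, 1)
  m_w <- drop(crossprod(nu, dm))
  cent <- sweep(dm, 2, colMeans(dm))
  v_w <- drop(crossprod(nu, cent^2))
  expect_equal(colMeans(tr1$phi), m_w, tolerance = 1e-12)
  phic <- sweep(tr1$phi, 2, colMeans(tr1$phi))
  expect_equal(colMeans(phic^2), v_w, tolerance = 1e-12)
  # the log-Jacobian is the diagonal affine determinant, equal across draws
  v <- colMeans(cent^2)
  expect_equal(tr1$log_jac[1], sum(log(sqrt(v_w / v))), tolerance = 1e-12)
  expect_equal(length(unique(tr1$log_jac)), 1L)
  # already matched moments: identity at any hbar
  tr_id <- pmm2(dm, rep(1 / 500, 500), 0.37)
  expect_equal(tr_id$phi, dm, tolerance = 1e-12)
  # a zero-variance component passes through unchanged
  dm2 <- cbind(dm, 2.5)
  tr2 <- pmm2(dm2, nu, 1)
  expect_identical(tr2$phi[, 4], rep(2.5, 500))
})

test_that("the KL and Var fields have the right sign, limits and oracle form", {
  prob <- make_lr_problem(n = 6, p = 3, seed = 53, prior = prior_flat())
  md <- prob$model; da <- prob$data
  local_seed(53)
  th <- rnorm(3)
  i <- 2
  obs <- list(x = da$X[i, ], y = da$y[i])
  # flipping the label flips the sign of Q
  q1 <- q_kl(md, th, list(x = obs$x, y = 1), da)
  q0 <- q_kl(md, th, list(x = obs$x, y = 0), da)
  expect_equal(q1$sign, -q0$sign)
  expect_identical(q1$direction, q0$direction)
  # well-classified limit: y = 1 and large mu make the magnitude vanish
  th_big <- obs$x * 10
  qb <- q_kl(md, th_big, list(x = obs$x, y = 1), da)
  qs <- q_kl(md, th, list(x = obs$x, y = 1), da)
  expect_lt(qb$log_mag, qs$log_mag - 50)
  # oracle: Q_KL = pi(theta|D) * grad(1 / likelihood) by finite differences
  inv_lik <- function(t) {
    m <- mu(md, t, obs$x)
    exp(-(obs$y * plogis(m, log.p = TRUE) + (1 - obs$y) * plogis(-m, log.p = TRUE)))
  }
  q_oracle <- exp(log_posterior_unnorm(md, th, da)) * pracma::grad(inv_lik, th)
  qk <- q_kl(md, th, obs, da)
  expect_equal(qk$sign * exp(qk$log_mag) * qk$direction, q_oracle,
               tolerance = 1e-5 * max(abs(q_oracle)))
  # Var doubles the exponent: equal magnitude at mu = 0, larger when
  # misclassified
  th0 <- rep(0, 3)
  expect_equal(q_var(md, th0, obs, da)$log_mag, q_kl(md, th0, obs, da)$log_mag)
  th_mis <- -obs$x * 2
  obs1 <- list(x = obs$x, y = 1)
  expect_gt(q_var(md, th_mis, obs1, da)$log_mag, q_kl(md, th_mis, obs1, da)$log_mag)
  # Var oracle: the general composite field pi * (f/l) * grad(f/l) with f the
  # complement-probability function reduces to the sigmoidal closed form
  fl <- function(t) {
    m <- mu(md, t, obs$x)
    p <- plogis(m)
    (p^(1 - obs$y) * (1 - p)^obs$y) / (p^obs$y * (1 - p)^(1 - obs$y))
  }
  qv_oracle <- exp(log_posterior_unnorm(md, th, da)) * fl(th) * pracma::grad(fl, th)
  qv <- q_var(md, th, obs, da)
  expect_equal(qv$sign * exp(qv$log_mag) * qv$direction, qv_oracle,
               tolerance = 1e-5 * max(abs(qv_oracle)))
})

test_that("the LL field is the held-out negative log-likelihood gradient", {
  md <- sigmoidal_model("logistic_regression", prior_flat(), p_x = 2)
  q <- q_ll(md, c(0, 0), list(x = c(2, 0), y = 1))
  expect_equal(q$sign * exp(q$log_mag) * q$direction, c(-1, 0))
  # stationary when perfectly calibrated
  qs <- q_ll(md, c(0, 0), list(x = c(0, 0), y = plogis(0)))
  expect_identical(exp(qs$log_mag), 0)
  local_seed(54)
  th <- rnorm(2); obs <- list(x = c(0.5, -1.2), y = 0)
  fd <- pracma::grad(function(t) -log_likelihood(md, t, obs$x, obs$y), th)
  qf <- q_ll(md, th, obs)
  expect_equal(qf$sign * exp(qf$log_mag) * qf$direction, fd, tolerance = 1e-6)
})

test_that("the step-size rule binds at hbar posterior standard deviations", {
  expect_equal(step_size(matrix(2, 1, 1), 1, 1), 0.5)
  local_seed(55)
  Q <- matrix(rnorm(40 * 3), 40)
  sd_v <- c(0.5, 2, 1)
  h <- step_size(Q, sd_v, 0.25)
  # homogeneity: degree -1 in Q, degree +1 in sd and hbar
  expect_equal(step_size(10 * Q, sd_v, 0.25), h / 10, tolerance = 1e-12)
  expect_equal(step_size(Q, 2 * sd_v, 0.25), 2 * h, tolerance = 1e-12)
  expect_equal(step_size(Q, sd_v, 0.5), 2 * h, tolerance = 1e-12)
  # the realized step h * Q is invariant to rescaling Q
  expect_equal(step_size(10 * Q, sd_v, 0.25) * (10 * Q), h * Q, tolerance = 1e-12)
  # binding constraint: the largest standardized move equals hbar
  expect_equal(max(sweep(abs(h * Q), 2, sd_v, "/")), 0.25, tolerance = 1e-12)
  # all-zero field: identity-step sentinel
  expect_true(is.na(step_size(matrix(0, 5, 2), c(1, 1), 1)))
})

test_that("gradient transforms are continuous at hbar -> 0 and move where Q != 0", {
  prob <- make_lr_problem(n = 6, p = 3, seed = 56)
  local_seed(56)
  pd <- posterior_draws(matrix(rnorm(60 * 3, sd = 0.5), 60))
  for (method in c("KL", "Var", "LL")) {
    tr <- apply_gradient_transform(pd, prob$model, 2, prob$data, method, 1e-8)
    expect_equal(tr$phi, pd$draws, tolerance = 1e-7)
    expect_equal(tr$log_jac, rep(0, 60), tolerance = 1e-6)
    tr2 <- apply_gradient_transform(pd, prob$model, 2, prob$data, method, 0.5)
    moved <- abs(tr2$phi - pd$draws) > 0
    nonzero_dir <- abs(prob$data$X[2, ]) > 0
    expect_true(all(moved[, nonzero_dir]))
  }
})

test_that("the exact LR Jacobian matches the dense finite-difference oracle", {
  prob <- make_lr_problem(n = 8, p = 5, seed = 57)
  md <- prob$model; da <- prob$data
  local_seed(57)
  for (rep_i in 1:25) {
    th <- rnorm(5)
    i <- sample(8, 1)
    obs <- list(x = da$X[i, ], y = da$y[i])
    for (method in c("KL", "Var")) {
      h <- 1e-3 * exp(-log_posterior_unnorm(md, th, da))
      j_ex <- exp(jac_logdet_lr_exact(md, th, obs, da, h, method))
      j_fd <- abs(fd_jac_det(md, th, obs, da, h, method))
      expect_equal(j_ex, j_fd, tolerance = 1e-6)
    }
  }
  # dead covariate: Q vanishes identically, determinant is exactly 1
  da0 <- loo_dataset(rbind(rep(0, 5), da$X[-1, ]), da$y)
  expect_equal(jac_logdet_lr_exact(md, rnorm(5), list(x = rep(0, 5), y = 1),
                                   da0, 0.1, "KL"), 0)
})

test_that("the exact ReLU Jacobian matches the dense finite-difference oracle", {
  prob <- make_relu_problem(n = 6, p_x = 4, d = 3, seed = 58)
  md <- prob$model; da <- prob$data
  local_seed(58)
  for (rep_i in 1:15) {
    th <- rnorm(md$p)
    i <- sample(6, 1)
    obs <- list(x = da$X[i, ], y = da$y[i])
    for (method in c("KL", "Var")) {
      h <- 1e-3 * exp(-log_posterior_unnorm(md, th, da))
      j_ex <- exp(jac_logdet_relu_exact(md, th, obs, da, h, method))
      j_fd <- abs(fd_jac_det(md, th, obs, da, h, method))
      expect_equal(j_ex, j_fd, tolerance = 1e-5)
    }
  }
  # all units dead: the structure collapses to the rank-one b2-only form
  th_dead <- c(rep(-2, 12), rnorm(3), 0.3)
  x_pos <- c(1, 1, 1, 1)
  dead_data <- loo_dataset(matrix(1, 4, 4), c(1, 0, 1, 0))
  obs <- list(x = x_pos, y = 1)
  h <- 1e-2 * exp(-log_posterior_unnorm(md, th_dead, dead_data))
  j_ex <- jac_logdet_relu_exact(md, th_dead, obs, dead_data, h, "KL")
  # with H = 0 the determinant is 1 + w'v where v has only the b2 slot
  dmu <- grad_mu(md, th_dead, x_pos)
  gg <- grad_log_posterior(md, th_dead, dead_data) - dmu
  amp <- -exp(log(h) + log_posterior_unnorm(md, th_dead, dead_data) - mu(md, th_dead, x_pos))
  expect_equal(j_ex, log(abs(1 + amp * sum(gg * dmu))), tolerance = 1e-12)
})

test_that("the first-order rule is exact for rank-one maps and O(h^2) otherwise", {
  expect_equal(jac_logdet_first_order(0.7, 0), 0)
  expect_equal(jac_logdet_first_order(-1, 0.5), log(0.5))
  expect_error(jac_logdet_first_order(-1, 1), "degenerate")
  # logistic regression: the Jacobian of Q is rank one, so the divergence
  # truncation IS the exact determinant
  prob <- make_lr_problem(n = 6, p = 4, seed = 59, prior = prior_flat())
  md <- prob$model; da <- prob$data
  local_seed(59)
  th <- rnorm(4); i <- 3
  obs <- list(x = da$X[i, ], y = da$y[i])
  h <- 0.1 * exp(-log_posterior_unnorm(md, th, da))
  cc <- 1
  g <- grad_log_posterior(md, th, da) + cc * (1 - 2 * obs$y) * obs$x
  div <- (-1)^obs$y * exp(log_posterior_unnorm(md, th, da) +
                            cc * mu(md, th, obs$x) * (1 - 2 * obs$y)) * sum(obs$x * g)
  expect_equal(jac_logdet_first_order(div, h),
               jac_logdet_lr_exact(md, th, obs, da, h, "KL"), tolerance = 1e-12)
  # ReLU net: the truncation error decays at rate O(h^2) against the exact
  # eigenstructure rule
  probn <- make_relu_problem(n = 5, p_x = 4, d = 3, seed = 60)
  mdn <- probn$model; dan <- probn$data
  local_seed(60)
  thn <- rnorm(mdn$p); i <- 2
  obsn <- list(x = dan$X[i, ], y = dan$y[i])
  scale <- exp(-log_posterior_unnorm(mdn, thn, dan))
  hs <- 10^(-(1:4)) * scale
  errs <- vapply(hs, function(h) {
    dmu <- grad_mu(mdn, thn, obsn$x)
    gn <- grad_log_posterior(mdn, thn, dan) + (1 - 2 * obsn$y) * dmu
    divn <- (-1)^obsn$y * exp(log_posterior_unnorm(mdn, thn, dan) +
                                mu(mdn, thn, obsn$x) * (1 - 2 * obsn$y)) * sum(dmu * gn)
    abs(exp(jac_logdet_first_order(divn, h)) -
          exp(jac_logdet_relu_exact(mdn, thn, obsn, dan, h, "KL")))
  }, 0.0)
  slope <- coef(lm(log10(errs) ~ log10(hs / scale)))[2]
  expect_lt(abs(slope - 2), 0.1)
})

test_that("transforms and Jacobians are invariant to the unknown normalizer", {
  prob <- make_lr_problem(n = 6, p = 3, seed = 61)
  local_seed(61)
  pd <- posterior_draws(matrix(rnorm(50 * 3, sd = 0.5), 50))
  base_prior <- prob$model$prior
  for (const in c(-123, 57)) {
    shifted <- structure(list(
      label = "shifted",
      log_density = function(th) base_prior$log_density(th) + const,
      grad_log_density = base_prior$grad_log_density,
      log_density_mat = function(d) base_prior$log_density_mat(d) + const,
      grad_mat = base_prior$grad_mat
    ), class = "prior_spec")
    md2 <- prob$model; md2$prior <- shifted
    for (method in c("KL", "Var")) {
      t1 <- apply_gradient_transform(pd, prob$model, 2, prob$data, method, 0.25)
      t2 <- apply_gradient_transform(pd, md2, 2, prob$data, method, 0.25)
      expect_equal(t2$phi, t1$phi, tolerance = 1e-10)
      expect_equal(t2$log_jac, t1$log_jac, tolerance = 1e-10)
    }
  }
})
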