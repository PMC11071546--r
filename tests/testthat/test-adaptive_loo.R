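test_that("identity transform reproduces the raw ratios bit-exactly", {
  prob <- make_lr_problem(n = 8, p = 3, seed = 71)
  local_seed(71)
  pd <- posterior_draws(matrix(rnorm(120 * 3, sd = 0.5), 120))
  idt <- adaptloo:::identity_transform(pd$draws, hbar = 0, observation = 4L)
  lw <- transformed_log_weights(pd, idt, prob$model, prob$data, 4)
  raw <- raw_loo_log_ratios(adaptloo:::loglik_matrix(prob$model, pd$draws, prob$data)[, 4])
  expect_identical(lw, raw)
})

test_that("transformed weights are invariant to constants in the log-posterior", {
  prob <- make_lr_problem(n = 6, p = 3, seed = 72)
  local_seed(72)
  pd <- posterior_draws(matrix(rnorm(80 * 3, sd = 0.5), 80))
  nu <- self_normalize(rnorm(80))
  tr <- pmm1(pd, nu, 0.5); tr$observation <- 2L
  base_prior <- prob$model$prior
  md2 <- prob$model
  md2$prior <- structure(list(
    label = "shifted",
    log_density = function(th) base_prior$log_density(th) + 321,
    grad_log_density = base_prior$grad_log_density,
    log_density_mat = function(d) base_prior$log_density_mat(d) + 321,
    grad_mat = base_prior$grad_mat
  ), class = "prior_spec")
  w1 <- self_normalize(transformed_log_weights(pd, tr, prob$model, prob$data, 2))
  w2 <- self_normalize(transformed_log_weights(pd, tr, md2, prob$data, 2))
  expect_equal(w1, w2, tolerance = 1e-12)
})

test_that("a shifted Gaussian proposal recovers closed-form moments via eta weights", {
  # 1-d Gaussian toy: target N(0, 1) (prior only, n kept but likelihood-free
  # via zero covariates), proposal = target draws shifted by delta through a
  # translation transform. The eta-weighted mean of theta must recover 0.
  local_seed(73)
  md <- sigmoidal_model("logistic_regression", prior_gaussian(1), p_x = 1)
  da <- loo_dataset(matrix(0, 2, 1), c(0, 1))   # zero covariates: loglik constant
  s <- 4000
  pd <- posterior_draws(matrix(rnorm(s), s, 1))
  delta <- 0.6
  tr <- transform_result(pd$draws + delta, numeric(s), "PMM1", h = 1, hbar = 1,
                         observation = 1L)
  lw <- transformed_log_weights(pd, tr, md, da, 1)
  w <- self_normalize(lw)
  est <- sum(w * tr$phi[, 1])
  se <- adaptloo:::snis_se(w, tr$phi[, 1])
  # the LOO target here equals the posterior itself (constant likelihood)
  expect_lt(abs(est - 0), 3 * se)
  # and the weights must undo the shift: eta proportional to N(phi)/N(phi-delta)
  ratio <- dnorm(tr$phi[, 1]) / dnorm(pd$draws[, 1])
  expect_equal(w, ratio / sum(ratio), tolerance = 1e-10)
})

test_that("variational-corrected weights reduce to raw weights and fix mismatch", {
  prob <- make_lr_problem(n = 6, p = 2, seed = 74)
  md <- prob$model; da <- prob$data
  local_seed(74)
  s <- 3000
  draws_mat <- matrix(rnorm(s * 2, sd = 0.6), s, 2)
  pd <- posterior_draws(draws_mat, source = "variational")
  idt <- adaptloo:::identity_transform(draws_mat, 0, 3L)
  # pihat equal to the true unnormalized posterior (plus a constant): chi
  # reduces to the raw 1/likelihood weights
  var_logpdf <- function(th) log_posterior_unnorm(md, th, da) + 17
  chi <- variational_corrected_log_weights(pd, idt, md, da, 3, var_logpdf)
  raw <- raw_loo_log_ratios(adaptloo:::loglik_matrix(md, draws_mat, da)[, 3])
  expect_equal(self_normalize(chi), self_normalize(raw), tolerance = 1e-12)
  # rescaling the variational density does not change the weights
  chi2 <- variational_corrected_log_weights(pd, idt, md, da, 3,
                                            function(th) var_logpdf(th) - 5.5)
  expect_equal(self_normalize(chi2), self_normalize(chi), tolerance = 1e-13)
  # overdispersed Gaussian pihat: chi-weighted LOO mean matches quadrature
  gp <- grid_posterior_sampler(md, loo_dataset(da$X[-3, , drop = FALSE], da$y[-3]),
                               grid_spec = list(n_grid = 120, s = 2))
  truth <- grid_expect(gp, f_vec = plogis(drop(gp$grid %*% da$X[3, ])))
  vd <- posterior_draws(matrix(rnorm(s * 2, sd = 1.2), s, 2), source = "variational")
  idtv <- adaptloo:::identity_transform(vd$draws, 0, 3L)
  chi3 <- variational_corrected_log_weights(vd, idtv, md, da, 3,
    function(th) sum(dnorm(th, 0, 1.2, log = TRUE)))
  w3 <- self_normalize(chi3)
  p3 <- plogis(drop(vd$draws %*% da$X[3, ]))
  est <- sum(w3 * p3)
  expect_lt(abs(est - truth), 3 * adaptloo:::snis_se(w3, p3) + 1e-4)
})

test_that("adaptation exits early when raw weights are stable and records failures", {
  prob <- make_lr_problem(n = 10, p = 2, seed = 75)
  local_seed(75)
  pd <- posterior_draws(matrix(rnorm(400 * 2, sd = 0.3), 400))
  rec <- adapt_observation(pd, prob$model, prob$data, 1, run_config())
  expect_identical(rec$winner, "raw")
  expect_true(all(is.na(rec$khat_by_method)))
  # vacuous search: no transformations configured, forced-low threshold
  cfg0 <- run_config(khat_threshold = 1e-6, transform_order = character(0))
  rec0 <- adapt_observation(pd, prob$model, prob$data, 1, cfg0)
  if (!is.na(rec0$khat_raw) && rec0$khat_raw > 1e-6) {
    expect_identical(rec0$winner, "none")
  }
})

test_that("LOO-IC accumulates log predictive densities correctly", {
  # single-draw degeneracy: LOO-IC = -2 sum log-lik at that draw
  ll1 <- matrix(c(-0.3, -1.2, -0.7), 1)
  out <- loo_ic(list(1, 1, 1), ll1)
  expect_equal(out$loo_ic, -2 * sum(ll1))
  expect_equal(out$elpd, as.numeric(ll1))
  # raw 1/likelihood weights make each term the harmonic mean of the
  # likelihood over draws
  local_seed(76)
  ll <- matrix(log(runif(200 * 3)), 200)
  w <- lapply(1:3, function(i) self_normalize(-ll[, i]))
  out <- loo_ic(w, ll)
  harm <- vapply(1:3, function(i) 1 / mean(1 / exp(ll[, i])), 0.0)
  expect_equal(out$elpd, log(harm), tolerance = 1e-12)
})

test_that("LOO predictive probabilities are convex combinations", {
  local_seed(77)
  p <- runif(500)
  expect_equal(loo_predictive(rep(1 / 500, 500), p), mean(p))
  w <- self_normalize(rnorm(500))
  expect_equal(loo_predictive(w, rep(0.42, 500)), 0.42, tolerance = 1e-12)
  est <- loo_predictive(w, p)
  expect_gte(est, 0); expect_lte(est, 1)
})

test_that("ROC/PRC agree with a concordance oracle and handle edge shapes", {
  # perfect separation
  out <- roc_prc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(out$auroc, 1)
  expect_equal(out$auprc, 1)
  # constant scores: no information
  out <- roc_prc(rep(0.5, 10), rep(c(0, 1), 5))
  expect_equal(out$auroc, 0.5)
  # random scores incl. ties: trapezoidal AUROC equals Mann-Whitney concordance
  local_seed(78)
  for (rep_i in 1:20) {
    n <- 40
    p <- round(runif(n), 2)                    # ties on purpose
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    out <- roc_prc(p, y)
    expect_equal(out$auroc, concordance_auroc(p, y), tolerance = 1e-12)
    if (rep_i == 1) {
      ref <- pROC::roc(y, p, direction = "<", levels = c(0, 1), quiet = TRUE)
      expect_equal(out$auroc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
    }
  }
  expect_error(roc_prc(runif(5), rep(1, 5)), "both classes")
})

test_that("run_loo is observation-order independent and stable on easy data", {
  prob <- make_lr_problem(n = 12, p = 2, seed = 79)
  local_seed(79)
  pd <- posterior_draws(matrix(rnorm(500 * 2, sd = 0.3), 500))
  cfg <- run_config(hbar_grid = 4^-(0:3))
  rep1 <- run_loo(pd, prob$model, prob$data, cfg)
  # easy regime: every observation is handled by the raw weights
  expect_identical(unique(vapply(rep1$per_obs, function(r) r$winner, "")), "raw")
  expect_identical(rep1$n_failed, 0L)
  # permuting the observations permutes the records identically
  perm <- sample(12)
  data_p <- loo_dataset(prob$data$X[perm, ], prob$data$y[perm])
  rep2 <- run_loo(pd, prob$model, data_p, cfg)
  for (j in seq_along(perm)) {
    r1 <- rep1$per_obs[[perm[j]]]
    r2 <- rep2$per_obs[[j]]
    expect_equal(r2$khat_raw, r1$khat_raw, tolerance = 1e-12)
    expect_equal(r2$p_loo, r1$p_loo, tolerance = 1e-12)
    expect_equal(r2$elpd_i, r1$elpd_i, tolerance = 1e-12)
  }
  expect_equal(rep2$loo_ic, rep1$loo_ic, tolerance = 1e-12)
  expect_equal(rep2$auroc, rep1$auroc, tolerance = 1e-12)
})

test_that("diagnose_loo reports the raw tail shapes without adapting", {
  prob <- make_lr_problem(n = 8, p = 2, seed = 80)
  local_seed(80)
  pd <- posterior_draws(matrix(rnorm(300 * 2, sd = 0.4), 300))
  dg <- diagnose_loo(pd, prob$model, prob$data)
  expect_identical(nrow(dg), 8L)
  rep <- run_loo(pd, prob$model, prob$data)
  kh <- vapply(rep$per_obs, function(r) r$khat_raw, 0.0)
  expect_equal(dg$khat, kh, tolerance = 1e-12)
})
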