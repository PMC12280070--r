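test_that("pseudo-R2 matches hand arithmetic", {
  expect_equal(pseudo_r2(240 * log(0.5), 240), 0)
  expect_equal(pseudo_r2(0, 240), 1)
  expect_equal(pseudo_r2(-120, 240), 1 - 120 / (240 * log(2)),
               tolerance = 1e-12)
  expect_equal(pseudo_r2(-120, 240), 0.2786525, tolerance = 1e-6)
})

test_that("Laplace evidence matches the analytic Gaussian integral", {
  # toy: log posterior = -0.5 * sum((x - mu)^2 / s2), a d-dim Gaussian whose
  # true log integral is (d/2) log(2 pi) + 0.5 * sum(log(s2))
  for (d in 1:3) {
    s2 <- seq(0.5, 1.5, length.out = d)
    lp_at_max <- 0
    H <- diag(1 / s2, d)
    ev <- laplace_log_evidence(lp_at_max, H)
    expect_equal(ev$log_evidence,
                 0.5 * d * log(2 * pi) + 0.5 * sum(log(s2)),
                 tolerance = 1e-12)
    expect_false(ev$regularized)
  }
  # no free parameters: evidence is the log-likelihood itself
  expect_equal(laplace_log_evidence(-42, NULL)$log_evidence, -42)
  # singular Hessian is regularized and flagged
  ev <- laplace_log_evidence(0, matrix(c(1, 1, 1, 1), 2))
  expect_true(ev$regularized)
  expect_true(is.finite(ev$log_evidence))
})

test_that("MAP fitting recovers generating parameters on informative data", {
  d <- main_design
  sub <- sim_subject_trials("kalman_qu", c(beta_q = 3, beta_u = -1),
                            seed = 60)
  f <- fit_map("kalman_qu", sub, "learning", d, seed = 1)
  expect_true(f$convergence)
  expect_lt(abs(f$par[["beta_q"]] - 3), 1.2)
  expect_lt(abs(f$par[["beta_u"]] + 1), 1.2)
  expect_gt(f$pseudo_r2, 0)
  expect_lt(f$log_evidence, f$log_lik)  # evidence pays a complexity price
  # a learner with a rate parameter, self-consistent on its own data
  sub2 <- sim_subject_trials("1alpha_q", c(alpha = 0.3, beta_q = 4),
                             seed = 61)
  f2 <- fit_map("1alpha_q", sub2, "learning", d, seed = 1)
  expect_lt(abs(f2$par[["alpha"]] - 0.3), 0.25)
})

test_that("random choices shrink decision weights toward the prior mean", {
  d <- main_design
  sub <- sim_subject_trials("kalman_qu", c(beta_q = 0, beta_u = 0),
                            seed = 62)
  f <- fit_map("kalman_qu", sub, "learning", d, seed = 1)
  expect_lt(abs(f$par[["beta_q"]]), 0.5)
  # tightening the prior pulls the weakly identified weights to the mean
  tight <- fit_map("kalman_qu", sub, "learning", d,
                   priors = default_priors(0.01), seed = 1)
  expect_lt(abs(tight$par[["beta_u"]]), abs(f$par[["beta_u"]]) + 1e-8)
  expect_lt(abs(tight$par[["beta_u"]]), 0.3)
})

test_that("doubling the prior variance barely moves an informative MAP", {
  d <- main_design
  sub <- sim_subject_trials("kalman_qu", c(beta_q = 3, beta_u = -2),
                            seed = 63)
  f1 <- fit_map("kalman_qu", sub, "learning", d,
                priors = default_priors(16.25), seed = 1)
  f2 <- fit_map("kalman_qu", sub, "learning", d,
                priors = default_priors(32.5), seed = 1)
  expect_equal(f1$par, f2$par, tolerance = 0.05)
})

test_that("test-phase fits score test choices on replayed frozen beliefs", {
  d <- main_design
  sub <- sim_subject_trials("kalman_qu", c(beta_q = 3, beta_u = -1),
                            params_test = c(beta_q = 1.2, beta_u = -5.5),
                            seed = 64)
  f <- fit_map("kalman_qu", sub, "test", d, seed = 1)
  expect_equal(f$n_trials, 180)
  expect_lt(f$par[["beta_u"]], -2)
  # likelihood at the MAP can only improve on the generating values
  ll_gen <- phase_log_likelihood("kalman_qu",
                                 c(beta_q = 1.2, beta_u = -5.5),
                                 sub, "test", d)
  expect_gte(f$log_lik, ll_gen - 1e-8)
})

test_that("evidence penalizes a redundant learning rate on average", {
  d <- main_design
  set.seed(65)
  wins <- 0
  n <- 8
  for (i in 1:n) {
    sub <- sim_subject_trials("1alpha_q",
                              c(alpha = runif(1, 0.2, 0.8),
                                beta_q = runif(1, 2, 5)),
                              seed = 650 + i)
    f1 <- fit_map("1alpha_q", sub, "learning", d, n_restarts = 5, seed = 1)
    f2 <- fit_map("2alpha_q", sub, "learning", d, n_restarts = 5, seed = 1)
    if (f1$log_evidence > f2$log_evidence) wins <- wins + 1
  }
  expect_gt(wins, n / 2)
})

test_that("fitting never mutates the dataset", {
  d <- main_design
  sub <- sim_subject_trials("kalman_qu", c(beta_q = 2, beta_u = -1),
                            seed = 66)
  snapshot <- sub
  invisible(fit_map("kalman_qu", sub, "learning", d, seed = 1))
  invisible(phase_log_likelihood("range_q", c(alpha = .5, alpha_r = .5,
                                              beta_q = 1), sub,
                                 "learning", d))
  expect_identical(sub, snapshot)
})
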