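test_that("belief initialization uses the alphabet mean and spread", {
  b <- init_beliefs("kalman_qu", main_design)
  expect_equal(b$q0, 0)
  expect_equal(sqrt(b$s20), sqrt(2 / 3))
  expect_true(all(b$q == 0))
  expect_true(all(b$s2 == 2 / 3))
  expect_true(all(b$v == 0) && all(b$r_max == 0) && all(b$r_min == 0))

  bv <- init_beliefs("kalman_qu", make_validation_design("interleaved"))
  expect_equal(bv$q0, 11 / 3)
  expect_equal(sqrt(bv$s20), sqrt(101 / 3 - (11 / 3)^2))
  expect_equal(sqrt(bv$s20), 4.4969, tolerance = 1e-4)

  expect_error(init_beliefs("nonsense", main_design))
})

test_that("single-rate and dual-rate updates follow their rules", {
  expect_equal(qlearn_update(0, 0.5, 1)$q, 0.5)
  expect_equal(qlearn_update(0, 0.5, 1)$delta, 1)
  expect_equal(qlearn_update(0.5, 1, 0)$q, 0)
  expect_equal(qlearn_update(0.5, 0.5, 0)$q, 0.25)

  expect_equal(dual_rate_update(0, 0.8, 0.2, 1)$q, 0.8)
  expect_equal(dual_rate_update(0.5, 0.8, 0.2, 0)$q, 0.4)
  expect_equal(dual_rate_update(0.5, 0.8, 0.2, 0.5)$q, 0.5)  # zero error
  # equal rates reproduce single-rate learning on any sequence
  set.seed(1)
  q1 <- q2 <- 0
  for (r in sample(c(-1, 0, 1), 25, replace = TRUE)) {
    q1 <- qlearn_update(q1, 0.3, r)$q
    q2 <- dual_rate_update(q2, 0.3, 0.3, r)$q
  }
  expect_equal(q1, q2)
})

test_that("selected/rejected update mirrors the prediction error", {
  u <- select_reject_update(0, 0, 0.5, 0.5, 1)
  expect_equal(u$q_selected, 0.5)
  expect_equal(u$q_rejected, -0.5)
  u <- select_reject_update(0.2, 0.1, 0.5, 0.5, 0)
  expect_equal(u$q_selected, 0.1)
  expect_equal(u$q_rejected, 0.2)
  # zero rejected rate leaves the rejected option unchanged
  u <- select_reject_update(0.3, 0.7, 0.4, 0, -1)
  expect_equal(u$q_rejected, 0.7)
})

test_that("relative update centres outcomes on the context value", {
  u <- relative_update(0, 0, 0, 0.5, 0.5, 1)
  expect_equal(u$q_selected, 0.5)
  expect_equal(u$v, 0.25)
  # outcome equal to V_c + q gives zero option prediction error
  u <- relative_update(0.3, 0.1, 0.2, 0.7, 0.4, 0.5)
  expect_equal(u$delta, 0)
  expect_equal(u$q_selected, 0.3)
  # alpha_c = 0 freezes the context value
  u <- relative_update(0, 0, 0.2, 0.5, 0, 1)
  expect_equal(u$v, 0.2)
})

test_that("range update normalizes with current trackers then moves them", {
  u <- range_update(0, 10, 0, 0.5, 0.5, 10)
  expect_equal(u$r_ran, 10 / 11)
  u <- range_update(0, 10, 0, 0.5, 0.5, 0)
  expect_equal(u$r_ran, 0)
  u <- range_update(0, 0, 0, 0.5, 1, 10)
  expect_equal(u$r_max, 10)
  expect_equal(u$r_min, 0)
  # r_ran stays in [0, 1] whenever the outcome lies within the tracked range
  set.seed(2)
  for (i in 1:50) {
    rmin <- runif(1, -2, 0); rmax <- runif(1, 0, 2)
    r <- runif(1, rmin, rmax)
    u <- range_update(runif(1), rmax, rmin, runif(1), runif(1), r)
    expect_gte(u$r_ran, 0)
    expect_lte(u$r_ran, 1)
  }
})

test_that("Kalman recursion matches its closed forms to 1e-12", {
  s20 <- 2 / 3
  # first observation uses rate 1/2
  expect_equal(kalman_update(0, s20, s20, 1)$alpha_used, 0.5)
  set.seed(3)
  for (rep in 1:5) {
    outcomes <- sample(c(-1, 0, 1), 100, replace = TRUE)
    q <- 0; s2 <- s20
    for (k in seq_along(outcomes)) {
      u <- kalman_update(q, s2, s20, outcomes[k])
      q <- u$q; s2 <- u$s2
      expect_equal(u$alpha_used, 1 / (k + 1), tolerance = 1e-12)
      expect_equal(s2, s20 / (k + 1), tolerance = 1e-12)
      expect_equal(q, (0 + sum(outcomes[1:k])) / (k + 1), tolerance = 1e-12)
    }
  }
})

test_that("attaching the uncertainty tracker composes learner and sigma", {
  expect_equal(attach_uncertainty_tracker("range"), "range_qu")
  expect_error(attach_uncertainty_tracker("bogus"))
  d <- main_design
  # sigma trajectory of a tracked non-Kalman learner equals the Kalman
  # sigma for the same choice sequence
  sched <- build_learning_schedule(d, seed = 4)[1:16, ]
  p <- c(alpha = 0.4, beta_q = 3, beta_u = -1)
  sim <- simulate_learning_phase("1alpha_qu", p, d, sched, seed = 4)
  simk <- simulate_learning_phase(
    "kalman_qu", c(beta_q = 3, beta_u = -1), d, sched, seed = 4)
  counts <- table(sim$trials$choice)
  for (opt in names(counts)) {
    expect_equal(sim$beliefs$s2[[opt]], (2 / 3) / (counts[[opt]] + 1),
                 tolerance = 1e-12)
  }
  # tracked range model keeps q in [0, 1] while sigma decays from sigma0
  simr <- simulate_learning_phase(
    "range_qu", c(alpha = 0.5, alpha_r = 0.5, beta_q = 3, beta_u = -1),
    d, sched, seed = 5)
  chosen <- unique(simr$trials$choice)
  expect_true(all(simr$beliefs$q[chosen] >= 0 & simr$beliefs$q[chosen] <= 1))
  expect_true(all(simr$beliefs$s2[chosen] < 2 / 3))
})

test_that("options not shown in a trial keep their beliefs", {
  d <- main_design
  for (model in c("1alpha_q", "2alpha_q", "relative_q", "range_q",
                  "kalman_q")) {
    info <- model_info(model)
    params <- c(stats::setNames(rep(0.4, length(info$alphas)), info$alphas),
                beta_q = 2)
    b <- init_beliefs(model, d)
    b2 <- belief_step(b, "b1_p100_G", "b1_p100_B", "b1_p100", 1, params)
    untouched <- setdiff(names(b$q), c("b1_p100_G", "b1_p100_B"))
    expect_equal(b2$q[untouched], b$q[untouched])
    expect_equal(b2$s2[untouched], b$s2[untouched])
  }
  # select_reject touches the rejected option too, but no other
  b <- init_beliefs("select_reject_q", d)
  b2 <- belief_step(b, "b1_p100_G", "b1_p100_B", "b1_p100", 1,
                    c(alpha_selected = 0.5, alpha_rejected = 0.5,
                      beta_q = 2))
  expect_equal(b2$q[["b1_p100_B"]], -0.5)
  untouched <- setdiff(names(b$q), c("b1_p100_G", "b1_p100_B"))
  expect_equal(b2$q[untouched], b$q[untouched])
})

test_that("model registry exposes exactly the free parameters per model", {
  expect_equal(model_info("1alpha_q")$alphas, "alpha")
  expect_equal(model_info("2alpha_qu")$alphas, c("alpha_plus", "alpha_minus"))
  expect_equal(model_info("select_reject_q")$alphas,
               c("alpha_selected", "alpha_rejected"))
  expect_equal(model_info("relative_q")$alphas, c("alpha", "alpha_c"))
  expect_equal(model_info("range_qu")$alphas, c("alpha", "alpha_r"))
  expect_equal(model_info("kalman_qu")$alphas, character(0))
  expect_equal(model_info("kalman_q")$betas, "beta_q")
  expect_equal(model_info("kalman_qu")$betas, c("beta_q", "beta_u"))
  expect_length(all_model_ids(), 12)
  expect_error(model_info("kalman"))
})
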