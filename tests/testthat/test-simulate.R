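test_that("cohorts are reproducible and have design-matched counts", {
  d <- main_design
  co <- generate_cohort(3, "kalman_qu", d, seed = 50)
  co2 <- generate_cohort(3, "kalman_qu", d, seed = 50)
  expect_identical(co$trials, co2$trials)
  expect_identical(co$params, co2$params)
  expect_equal(nrow(co$trials), 3 * (240 + 180))
  expect_equal(sum(co$trials$phase == "learning"), 3 * 240)
  # test rows carry no outcome; learning rows always do
  expect_true(all(is.na(co$trials$outcome[co$trials$phase == "test"])))
  expect_true(all(!is.na(co$trials$outcome[co$trials$phase == "learning"])))
  # single-subject cohort is accepted by fitting
  co1 <- generate_cohort(1, "1alpha_q", d, seed = 51)
  f <- fit_dataset("1alpha_q", co1$trials, "learning", d,
                   n_restarts = 3, seed = 1)
  expect_equal(nrow(f), 1)
})

test_that("indifferent agents choose at chance in both phases", {
  d <- main_design
  sub <- sim_subject_trials("kalman_qu", c(beta_q = 0, beta_u = 0),
                            seed = 52)
  perf <- learning_performance(sub, by = "condition")
  # 240 Bernoulli(.5) trials: overall rate within a generous binomial CI
  overall <- mean(perf$performance)
  expect_gt(overall, 0.5 - 3 * sqrt(0.25 / 240))
  expect_lt(overall, 0.5 + 3 * sqrt(0.25 / 240))
  rates <- test_selection_rates(sub)
  expect_gt(mean(rates$selection_rate), 0.5 - 3 * sqrt(0.25 / 180))
  expect_lt(mean(rates$selection_rate), 0.5 + 3 * sqrt(0.25 / 180))
})

test_that("a greedy value-driven agent converges on the good option", {
  d <- main_design
  sub <- sim_subject_trials("kalman_q", c(beta_q = 20, beta_u = 0),
                            seed = 53)
  perf <- learning_performance(sub, by = "pair")
  # last half of each pair's streak should be dominated by the good option
  learn <- sub[sub$phase == "learning", ]
  roles <- parse_options(learn$choice)$role
  late <- unlist(lapply(split(seq_len(nrow(learn)), learn$pair_id),
                        function(i) i[9:16]))
  expect_gt(mean(roles[late] == "good"), 0.8)
  # good options selected above chance in good-vs-bad test pairs
  rates <- test_selection_rates(sub)
  expect_gt(mean(rates$selection_rate[rates$pair_type == "GvB"]), 0.7)
})

test_that("uncertainty-averse agents leave bad options more uncertain", {
  d <- main_design
  sub <- sim_subject_trials("kalman_qu", c(beta_q = 2.9, beta_u = -1.1),
                            seed = 54)
  counts <- table(sub$choice[sub$phase == "learning"])
  sr <- sampling_rates(sub)
  good_more <- tapply(sr$sampling_rate, sr$role, mean)
  expect_gt(good_more[["good"]], good_more[["bad"]])
  # sigma after learning is larger for the less-sampled option of each pair
  traj <- belief_trajectory("kalman_qu", c(beta_q = 2.9, beta_u = -1.1),
                            sub, d)
  ot <- design_option_table(d)
  for (pid in unique(sub$pair_id[sub$phase == "learning"])) {
    opts <- unique(c(sub$option_left[sub$pair_id == pid],
                     sub$option_right[sub$pair_id == pid]))
    n <- sapply(opts, function(o) sum(sub$choice == o &
                                        sub$phase == "learning"))
    if (n[1] == n[2]) next
    s2 <- (2 / 3) / (n + 1)
    expect_gt(s2[which.min(n)], s2[which.max(n)])
  }
})

test_that("sampling rates are the exact bookkeeping complement", {
  sub <- sim_subject_trials("kalman_qu", c(beta_q = 3, beta_u = -1),
                            seed = 55)
  sr <- sampling_rates(sub)
  perf <- learning_performance(sub, by = "pair")
  m <- merge(sr[sr$role == "good", ], perf,
             by = c("subject", "pair_id"))
  expect_equal(m$sampling_rate, m$performance)
  both <- merge(sr[sr$role == "good", c("pair_id", "sampling_rate")],
                sr[sr$role == "bad", c("pair_id", "sampling_rate")],
                by = "pair_id")
  expect_equal(both$sampling_rate.x + both$sampling_rate.y,
               rep(1, nrow(both)))
  # audit against raw counts
  learn <- sub[sub$phase == "learning", ]
  for (i in seq_len(nrow(sr))) {
    n_opt <- sum(learn$choice == sr$option[i] &
                   learn$pair_id == sr$pair_id[i])
    n_tot <- sum(learn$pair_id == sr$pair_id[i])
    expect_equal(sr$sampling_rate[i], n_opt / n_tot)
  }
})

test_that("test-phase simulation never updates beliefs or pays outcomes", {
  d <- main_design
  lsched <- build_learning_schedule(d, seed = 56)
  tsched <- build_test_schedule(d, lsched, seed = 56)
  sim <- simulate_learning_phase("kalman_qu", c(beta_q = 3, beta_u = -2),
                                 d, lsched, seed = 56)
  before <- sim$beliefs
  test <- simulate_test_phase("kalman_qu", c(beta_q = 3, beta_u = -2),
                              sim$beliefs, tsched, seed = 57)
  expect_true(all(is.na(test$outcome)))
  expect_identical(before, sim$beliefs)
  # unknown option in the schedule is rejected
  bad <- tsched
  bad$option_left[1] <- "b9_p999_G"
  expect_error(simulate_test_phase("kalman_qu", c(beta_q = 3, beta_u = -2),
                                   sim$beliefs, bad), "without beliefs")
})

test_that("parameter samplers respect their ranges", {
  s <- sample_parameters("kalman_qu", 500, seed = 58)
  expect_true(all(s$beta_q >= 0.5 & s$beta_q <= 6))
  expect_true(all(s$beta_u >= -8 & s$beta_u <= 0))
  s2 <- sample_parameters("range_qu", 100, seed = 59)
  expect_true(all(s2$alpha >= 0 & s2$alpha <= 1))
  expect_named(s2, c("alpha", "alpha_r", "beta_q", "beta_u"))
})
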