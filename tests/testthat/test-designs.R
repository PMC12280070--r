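# enumeration oracle: walk the four (context, valence) branches explicitly
enum_outcomes <- function(cond, role) {
  p <- cond$p_appetitive
  q <- if (role == "good") cond$p_pos_good else cond$p_pos_bad
  data.frame(
    outcome = c(cond$mag_app_pos, cond$mag_app_neg, cond$mag_av_pos,
                cond$mag_av_neg),
    prob = c(p * q, p * (1 - q), (1 - p) * q, (1 - p) * (1 - q))
  )
}

test_that("main design matches the stated five-condition structure", {
  d <- main_design
  expect_equal(nrow(d$conditions), 5)
  expect_setequal(d$conditions$p_appetitive, c(1, 0.75, 0.5, 0.25, 0))
  expect_equal(sort(d$alphabet), c(-1, 0, 1))
  expect_equal(d$n_blocks * nrow(d$conditions) * d$trials_per_pair, 240)
})

test_that("expected values match the worked examples and the closed form", {
  d <- main_design
  expect_equal(expected_value(d$conditions[3, ], "good"), 0.25)
  expect_equal(expected_value(d$conditions[5, ], "bad"), -0.75)
  for (i in 1:5) {
    cond <- d$conditions[i, ]
    for (role in c("good", "bad")) {
      q <- if (role == "good") cond$p_pos_good else cond$p_pos_bad
      ev_enum <- with(enum_outcomes(cond, role), sum(outcome * prob))
      expect_equal(expected_value(cond, role), ev_enum)
      expect_equal(expected_value(cond, role), cond$p_appetitive - (1 - q))
    }
  }
})

test_that("good minus bad expected-value gap is 0.5 in every condition", {
  d <- main_design
  gap <- vapply(1:5, function(i) {
    expected_value(d$conditions[i, ], "good") -
      expected_value(d$conditions[i, ], "bad")
  }, numeric(1))
  expect_equal(gap, rep(0.5, 5))
})

test_that("outcome entropy matches enumeration and is symmetric in p", {
  d <- main_design
  # p_app = 1, good: {+1: .75, 0: .25}
  expect_equal(outcome_entropy(d$conditions[1, ], "good"),
               -(0.75 * log(0.75) + 0.25 * log(0.25)),
               tolerance = 1e-12)
  # p_app = 0.5, good: {+1: .375, 0: .5, -1: .125}
  expect_equal(outcome_entropy(d$conditions[3, ], "good"),
               -(0.375 * log(0.375) + 0.5 * log(0.5) + 0.125 * log(0.125)),
               tolerance = 1e-12)
  # point-mass outcome has zero entropy (validation bad option never pays
  # when p_pos = 0 would be degenerate; construct one directly)
  degen <- data.frame(condition_id = "x", p_appetitive = 1, p_pos_good = 1,
                      p_pos_bad = 0, mag_app_pos = 1, mag_app_neg = 1,
                      mag_av_pos = 0, mag_av_neg = 0)
  expect_equal(outcome_entropy(degen, "good"), 0)
  # H(p) = H(1 - p) with roles swapped: condition i, good vs condition
  # 6 - i, bad have mirrored outcome distributions
  for (i in 1:5) {
    expect_equal(outcome_entropy(d$conditions[i, ], "good"),
                 outcome_entropy(d$conditions[6 - i, ], "bad"),
                 tolerance = 1e-12)
  }
  # bits = nats / ln 2
  expect_equal(outcome_entropy(d$conditions[3, ], "good", base = 2),
               outcome_entropy(d$conditions[3, ], "good") / log(2))
})

test_that("learning schedules have the stated counts and block structure", {
  d <- main_design
  s <- build_learning_schedule(d, seed = 7)
  expect_equal(nrow(s), 240)
  expect_equal(as.vector(table(s$block)), rep(80L, 3))
  # 16-trial streaks per pair
  expect_true(all(table(s$pair_id) == 16))
  # block 3 condition order reverses block 1
  ord <- function(b) unique(s$condition[s$block == b])
  expect_equal(ord(3), rev(ord(1)))
  # reproducible bit-for-bit; different seeds differ
  expect_identical(s, build_learning_schedule(d, seed = 7))
  expect_false(identical(s, build_learning_schedule(d, seed = 8)))
  # fresh stimuli per block
  ids <- unique(c(s$option_left, s$option_right))
  expect_equal(length(ids), 30)
})

test_that("main test schedule has 180 trials and 30/30/30 unique pairs", {
  d <- main_design
  ls <- build_learning_schedule(d, seed = 3)
  ts <- build_test_schedule(d, ls, seed = 3)
  expect_equal(nrow(ts), 180)
  upairs <- unique(ts[, c("pair_id", "pair_type", "block")])
  expect_equal(as.vector(table(upairs$pair_type)[c("GvG", "BvB", "GvB")]),
               c(30L, 30L, 30L))
  # 10 within-block pairs of each same-role type per block
  expect_true(all(table(upairs$block[upairs$pair_type == "GvG"]) == 10))
  # every unique pair exactly twice
  expect_true(all(table(ts$pair_id) == 2))
  # every test option was learned
  expect_true(all(c(ts$option_left, ts$option_right) %in%
                    c(ls$option_left, ls$option_right)))
})

test_that("validation designs encode the four-pair structure", {
  expect_error(make_validation_design("nope"))
  for (variant in c("interleaved", "blocked")) {
    d <- make_validation_design(variant)
    expect_equal(sort(d$alphabet), c(0, 1, 10))
    expect_setequal(d$conditions$mag_app_pos, c(1, 10))
    ls <- build_learning_schedule(d, seed = 2)
    ts <- build_test_schedule(d, ls, seed = 2)
    expect_equal(nrow(ls), 120)
    expect_equal(nrow(ts), 120)
    expect_setequal(unique(ts$pair_id),
                    c("A1|C1", "B1|D1", "A2|D2", "B2|C2"))
    expect_true(all(table(ts$pair_id) == 30))
    if (variant == "blocked") {
      # consecutive presentation: each pair occupies one contiguous run
      runs <- rle(ls$pair_id)
      expect_equal(length(runs$lengths), 4)
    }
  }
  # ground-truth EVs: big-reward good option 7.5, small-reward bad 0.25
  d <- make_validation_design("interleaved")
  expect_equal(expected_value(d$conditions[1, ], "good"), 7.5)
  expect_equal(expected_value(d$conditions[3, ], "bad"), 0.25)
})

test_that("option ids parse back to block, condition and role", {
  p <- parse_options(c("b2_p075_G", "b3_p000_B", "A1", "D2"))
  expect_equal(p$block, c(2L, 3L, 1L, 1L))
  expect_equal(p$condition, c("p075", "p000", "A1B1", "C2D2"))
  expect_equal(p$role, c("good", "bad", "good", "bad"))
})
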