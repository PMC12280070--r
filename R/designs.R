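#' Experimental designs for two-armed bandit learning/test experiments
#'
#' An `rl_design` is a declarative description of a probabilistic two-armed
#' bandit experiment with a learning phase (partial feedback) and a
#' feedback-free test phase. Each condition holds one Good option
#' (positive-feedback probability 0.75) and one Bad option (0.25). On every
#' feedback, a context is drawn (appetitive with probability `p_appetitive`,
#' aversive otherwise) and a valence (positive with the option's
#' positive-feedback probability); the (context, valence) cell indexes a
#' currency magnitude.
#'
#' @name rl_design
#' @keywords internal
NULL

MAIN_CONDITIONS <- c("p100", "p075", "p050", "p025", "p000")

new_design <- function(name, type, conditions, n_blocks, trials_per_pair,
                       alphabet, test_repeats, presentation) {
  structure(
    list(
      name = name,
      type = type,
      conditions = conditions,
      n_blocks = n_blocks,
      trials_per_pair = trials_per_pair,
      alphabet = alphabet,
      test_repeats = test_repeats,
      presentation = presentation
    ),
    class = "rl_design"
  )
}

#' Main five-condition appetitive/aversive design
#'
#' Builds the main experiment: five conditions differing in the probability
#' `p_appetitive` (1.0, 0.75, 0.5, 0.25, 0.0) that feedback is drawn from an
#' appetitive context (positive/negative feedback = +1/0 currency units)
#' rather than an aversive one (0/-1). Three learning blocks of 5 pairs x 16
#' consecutive trials each (240 learning trials), followed by a 180-trial
#' test phase built from 30 good-vs-good, 30 bad-vs-bad and 30 good-vs-bad
#' unique recombined pairs, each shown twice.
#'
#' @return An object of class `rl_design`.
#' @seealso [make_validation_design()], [build_learning_schedule()]
#' @examples
#' d <- make_main_design()
#' d$conditions
#' @export
make_main_design <- function() {
  conditions <- data.frame(
    condition_id = MAIN_CONDITIONS,
    p_appetitive = c(1.0, 0.75, 0.5, 0.25, 0.0),
    p_pos_good   = 0.75,
    p_pos_bad    = 0.25,
    mag_app_pos  = 1,
    mag_app_neg  = 0,
    mag_av_pos   = 0,
    mag_av_neg   = -1,
    stringsAsFactors = FALSE
  )
  new_design(
    name = "main", type = "main", conditions = conditions,
    n_blocks = 3L, trials_per_pair = 16L,
    alphabet = c(-1, 0, 1), test_repeats = 2L,
    presentation = "blocked"
  )
}

#' Four-pair validation designs with magnitude manipulation
#'
#' Builds one of the two public validation experiments: four learning pairs
#' (`A1B1`, `A2B2` rewarded +10 points; `C1D1`, `C2D2` rewarded +1 point;
#' non-reward always 0) with Good/Bad reward probabilities 0.75/0.25, 30
#' learning trials per pair, and four test pairs (`A1C1`, `B1D1`, `A2D2`,
#' `B2C2`) each presented 30 times without feedback. In the `interleaved`
#' variant pairs are randomly inter-mixed within each phase; in the
#' `blocked` variant each pair's trials are presented consecutively.
#'
#' @param variant `"interleaved"` or `"blocked"`.
#' @return An object of class `rl_design`.
#' @examples
#' make_validation_design("interleaved")$conditions
#' @export
make_validation_design <- function(variant = c("interleaved", "blocked")) {
  variant <- match.arg(variant)
  conditions <- data.frame(
    condition_id = c("A1B1", "A2B2", "C1D1", "C2D2"),
    p_appetitive = 1.0,
    p_pos_good   = 0.75,
    p_pos_bad    = 0.25,
    mag_app_pos  = c(10, 10, 1, 1),
    mag_app_neg  = 0,
    mag_av_pos   = 0,
    mag_av_neg   = 0,
    stringsAsFactors = FALSE
  )
  new_design(
    name = paste0("validation_", variant), type = "validation",
    conditions = conditions,
    n_blocks = 1L, trials_per_pair = 30L,
    alphabet = c(0, 1, 10), test_repeats = 30L,
    presentation = variant
  )
}

#' @export
print.rl_design <- function(x, ...) {
  cat("<rl_design>", x$name, "\n")
  cat("  conditions:", nrow(x$conditions),
      " blocks:", x$n_blocks,
      " trials/pair:", x$trials_per_pair, "\n")
  cat("  outcome alphabet: {", paste(x$alphabet, collapse = ", "), "}\n")
  invisible(x)
}

get_condition <- function(design, condition_id) {
  i <- match(condition_id, design$conditions$condition_id)
  if (is.na(i)) stop("unknown condition: ", condition_id)
  as.list(design$conditions[i, ])
}

#' Outcome distribution of one option
#'
#' Enumerates the categorical outcome distribution of a Good or Bad option
#' under the generative feedback rule: context ~ Bernoulli(`p_appetitive`),
#' valence ~ Bernoulli(positive-feedback probability of the role), outcome =
#' magnitude of the (context, valence) cell. Outcomes with equal currency
#' value are aggregated.
#'
#' @param cond A condition: one row of `design$conditions` (or the result of
#'   a list subset with the same fields).
#' @param role `"good"` or `"bad"`.
#' @return A data.frame with columns `outcome` and `prob` (probabilities sum
#'   to 1; zero-probability outcomes dropped).
#' @export
outcome_distribution <- function(cond, role = c("good", "bad")) {
  role <- match.arg(role)
  cond <- as.list(cond)
  p <- cond$p_appetitive
  q <- if (role == "good") cond$p_pos_good else cond$p_pos_bad
  cells <- data.frame(
    outcome = c(cond$mag_app_pos, cond$mag_app_neg,
                cond$mag_av_pos, cond$mag_av_neg),
    prob = c(p * q, p * (1 - q), (1 - p) * q, (1 - p) * (1 - q))
  )
  agg <- stats::aggregate(prob ~ outcome, data = cells, FUN = sum)
  agg <- agg[agg$prob > 0, , drop = FALSE]
  agg[order(agg$outcome), , drop = FALSE]
}

#' Expected value of an option
#'
#' Expected currency outcome of an option, by enumeration of the four
#' (context, valence) feedback cells. For the main design this reduces to
#' the closed form `p_appetitive - (1 - q)` where `q` is the role's
#' positive-feedback probability.
#'
#' @inheritParams outcome_distribution
#' @return Expected value in currency units.
#' @examples
#' d <- make_main_design()
#' expected_value(d$conditions[3, ], "good")  # 0.25
#' expected_value(d$conditions[5, ], "bad")   # -0.75
#' @export
expected_value <- function(cond, role = c("good", "bad")) {
  dist <- outcome_distribution(cond, role)
  sum(dist$outcome * dist$prob)
}

#' Shannon entropy of an option's outcome distribution
#'
#' @inheritParams outcome_distribution
#' @param base Base of the logarithm; `exp(1)` (default) reports nats,
#'   `2` reports bits.
#' @return Entropy (non-negative).
#' @examples
#' d <- make_main_design()
#' outcome_entropy(d$conditions[1, ], "good")  # 0.5623 nats
#' @export
outcome_entropy <- function(cond, role = c("good", "bad"), base = exp(1)) {
  dist <- outcome_distribution(cond, role)
  p <- dist$prob[dist$prob > 0]
  -sum(p * log(p, base = base))
}

option_id <- function(block, condition_id, role) {
  paste0("b", block, "_", condition_id, "_", ifelse(role == "good", "G", "B"))
}

validation_option_ids <- function(condition_id) {
  # "A1B1" -> good "A1", bad "B1"; "C2D2" -> good "C2", bad "D2"
  c(good = paste0(substr(condition_id, 1, 2)),
    bad  = paste0(substr(condition_id, 3, 4)))
}

#' Parse option identifiers
#'
#' Recovers block, condition and role (Good/Bad) from option ids as produced
#' by the schedule builders: main-design ids look like `"b1_p050_G"`;
#' validation ids are the option letters `"A1"`, `"B1"`, `"C2"`, `"D2"`, ...
#' (A/C are Good, B/D Bad).
#'
#' @param ids Character vector of option ids.
#' @return data.frame with columns `option`, `block`, `condition`, `role`
#'   (`"good"`/`"bad"`).
#' @export
parse_options <- function(ids) {
  main <- grepl("^b\\d+_", ids)
  block <- rep(1L, length(ids))
  block[main] <- as.integer(sub("^b(\\d+)_.*$", "\\1", ids[main]))
  condition <- ifelse(main, sub("^b\\d+_([^_]+)_[GB]$", "\\1", ids), NA)
  role <- ifelse(main,
                 ifelse(grepl("_G$", ids), "good", "bad"),
                 ifelse(substr(ids, 1, 1) %in% c("A", "C"), "good", "bad"))
  # validation: condition is the learning pair the option belongs to
  vletter <- substr(ids, 1, 1)
  vindex <- substr(ids, 2, 2)
  vcond <- ifelse(vletter %in% c("A", "B"),
                  paste0("A", vindex, "B", vindex),
                  paste0("C", vindex, "D", vindex))
  condition <- ifelse(main, condition, vcond)
  data.frame(option = ids, block = block, condition = condition,
             role = role, stringsAsFactors = FALSE)
}

randomize_sides <- function(df, seed_done = TRUE) {
  flip <- stats::runif(nrow(df)) < 0.5
  left <- ifelse(flip, df$option_b, df$option_a)
  right <- ifelse(flip, df$option_a, df$option_b)
  df$option_left <- left
  df$option_right <- right
  df$option_a <- NULL
  df$option_b <- NULL
  df
}

#' Build the learning-phase trial schedule
#'
#' Deterministic given `(design, seed)`. For the main design each block
#' presents all five conditions in 16-trial streaks of fresh stimuli; the
#' condition order of block 1 is a random permutation, block 2 is an
#' independent permutation, and block 3 reverses block 1. For validation
#' designs the four pairs are presented 30 times each, inter-mixed or in
#' consecutive blocks according to the design's presentation mode. Screen
#' side (left/right) is randomized uniformly per trial.
#'
#' @param design An `rl_design`.
#' @param seed Integer seed.
#' @return data.frame with columns `phase`, `block`, `trial`, `pair_id`,
#'   `condition`, `option_left`, `option_right`.
#' @export
build_learning_schedule <- function(design, seed = 1L) {
  stopifnot(inherits(design, "rl_design"))
  set.seed(seed)
  conds <- design$conditions$condition_id
  if (design$type == "main") {
    order1 <- sample(conds)
    order2 <- sample(conds)
    orders <- list(order1, order2, rev(order1))
    rows <- list()
    for (b in seq_len(design$n_blocks)) {
      for (cid in orders[[b]]) {
        rows[[length(rows) + 1L]] <- data.frame(
          phase = "learning", block = b,
          pair_id = paste0("b", b, "_", cid), condition = cid,
          option_a = option_id(b, cid, "good"),
          option_b = option_id(b, cid, "bad"),
          stringsAsFactors = FALSE
        )[rep(1L, design$trials_per_pair), ]
      }
    }
    sched <- do.call(rbind, rows)
  } else {
    rows <- lapply(conds, function(cid) {
      opts <- validation_option_ids(cid)
      data.frame(
        phase = "learning", block = 1L, pair_id = cid, condition = cid,
        option_a = unname(opts["good"]), option_b = unname(opts["bad"]),
        stringsAsFactors = FALSE
      )[rep(1L, design$trials_per_pair), ]
    })
    sched <- do.call(rbind, rows)
    if (design$presentation == "interleaved") {
      sched <- sched[sample(nrow(sched)), ]
    } else {
      pair_order <- sample(conds)
      sched <- do.call(rbind, lapply(seq_along(pair_order), function(i) {
        s <- sched[sched$pair_id == pair_order[i], ]
        s$block <- i
        s
      }))
    }
  }
  sched <- randomize_sides(sched)
  sched$trial <- seq_len(nrow(sched))
  rownames(sched) <- NULL
  sched[, c("phase", "block", "trial", "pair_id", "condition",
            "option_left", "option_right")]
}

main_test_pairs <- function(design) {
  conds <- design$conditions$condition_id
  rows <- list()
  for (b in seq_len(design$n_blocks)) {
    cc <- utils::combn(conds, 2)
    for (j in seq_len(ncol(cc))) {
      # within-block good-vs-good and bad-vs-bad recombinations
      rows[[length(rows) + 1L]] <- data.frame(
        block = b, pair_type = "GvG",
        condition = paste(cc[1, j], cc[2, j], sep = "|"),
        option_a = option_id(b, cc[1, j], "good"),
        option_b = option_id(b, cc[2, j], "good"),
        stringsAsFactors = FALSE
      )
      rows[[length(rows) + 1L]] <- data.frame(
        block = b, pair_type = "BvB",
        condition = paste(cc[1, j], cc[2, j], sep = "|"),
        option_a = option_id(b, cc[1, j], "bad"),
        option_b = option_id(b, cc[2, j], "bad"),
        stringsAsFactors = FALSE
      )
    }
  }
  # cross-block good-vs-bad, same condition, all ordered block pairs
  for (cid in conds) {
    for (bg in seq_len(design$n_blocks)) {
      for (bb in seq_len(design$n_blocks)) {
        if (bg == bb) next
        rows[[length(rows) + 1L]] <- data.frame(
          block = NA_integer_, pair_type = "GvB", condition = cid,
          option_a = option_id(bg, cid, "good"),
          option_b = option_id(bb, cid, "bad"),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

validation_test_pairs <- function() {
  data.frame(
    block = 1L,
    pair_type = c("GvG", "BvB", "GvB", "GvB"),
    condition = c("A1C1", "B1D1", "A2D2", "B2C2"),
    option_a = c("A1", "B1", "A2", "B2"),
    option_b = c("C1", "D1", "D2", "C2"),
    stringsAsFactors = FALSE
  )
}

#' Build the test-phase trial schedule
#'
#' Main design: per learning block all C(5,2) = 10 good-vs-good and 10
#' bad-vs-bad within-block recombinations, plus 30 cross-block good-vs-bad
#' pairs (same condition, Good and Bad from different blocks); each unique
#' pair repeated twice and the 180 trials presented in randomized order.
#' Validation designs: the four pairs `A1C1`, `B1D1`, `A2D2`, `B2C2`, 30
#' presentations each, inter-mixed or blocked per the design.
#'
#' @param design An `rl_design`.
#' @param learning_schedule The learning schedule built from the same design
#'   (used to check that every test option was learned).
#' @param seed Integer seed.
#' @return data.frame with the same columns as the learning schedule plus
#'   `pair_type` (`GvG`, `BvB`, `GvB`); `pair_id` joins the two option ids.
#' @export
build_test_schedule <- function(design, learning_schedule, seed = 1L) {
  stopifnot(inherits(design, "rl_design"))
  set.seed(seed + 1L)
  pairs <- if (design$type == "main") main_test_pairs(design) else
    validation_test_pairs()
  learned <- unique(c(learning_schedule$option_left,
                      learning_schedule$option_right))
  missing <- setdiff(c(pairs$option_a, pairs$option_b), learned)
  if (length(missing) > 0) {
    stop("test options never shown in learning: ",
         paste(missing, collapse = ", "))
  }
  pairs$pair_id <- paste(pairs$option_a, pairs$option_b, sep = "|")
  sched <- pairs[rep(seq_len(nrow(pairs)), each = design$test_repeats), ]
  if (design$type == "main" || design$presentation == "interleaved") {
    sched <- sched[sample(nrow(sched)), ]
  } else {
    pair_order <- sample(pairs$pair_id)
    sched <- do.call(rbind, lapply(pair_order, function(p) {
      sched[sched$pair_id == p, ]
    }))
  }
  sched$phase <- "test"
  sched <- randomize_sides(sched)
  sched$trial <- seq_len(nrow(sched))
  rownames(sched) <- NULL
  sched[, c("phase", "block", "trial", "pair_id", "pair_type", "condition",
            "option_left", "option_right")]
}

#' Per-option metadata table for a design
#'
#' Lists every learnable option of a design with its block, condition, role,
#' generative feedback probabilities and ground-truth expected value and
#' outcome entropy.
#'
#' @param design An `rl_design`.
#' @return data.frame with one row per option.
#' @export
design_option_table <- function(design) {
  rows <- list()
  for (i in seq_len(nrow(design$conditions))) {
    cond <- design$conditions[i, ]
    for (b in seq_len(design$n_blocks)) {
      for (role in c("good", "bad")) {
        id <- if (design$type == "main") {
          option_id(b, cond$condition_id, role)
        } else {
          unname(validation_option_ids(cond$condition_id)[role])
        }
        rows[[length(rows) + 1L]] <- data.frame(
          option = id, block = b, condition = cond$condition_id,
          role = role,
          p_appetitive = cond$p_appetitive,
          p_pos = if (role == "good") cond$p_pos_good else cond$p_pos_bad,
          ev = expected_value(cond, role),
          entropy = outcome_entropy(cond, role),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sample one feedback outcome for an option
#'
#' Draws context ~ Bernoulli(`p_appetitive`) and valence ~ Bernoulli(role's
#' positive-feedback probability) and maps the pair to its currency
#' magnitude. Uses the current RNG stream.
#'
#' @inheritParams outcome_distribution
#' @param n Number of draws.
#' @return Numeric vector of outcomes.
#' @export
sample_outcome <- function(cond, role = c("good", "bad"), n = 1L) {
  role <- match.arg(role)
  cond <- as.list(cond)
  q <- if (role == "good") cond$p_pos_good else cond$p_pos_bad
  appetitive <- stats::runif(n) < cond$p_appetitive
  positive <- stats::runif(n) < q
  ifelse(appetitive,
         ifelse(positive, cond$mag_app_pos, cond$mag_app_neg),
         ifelse(positive, cond$mag_av_pos, cond$mag_av_neg))
}
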