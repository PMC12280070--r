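#' Default parameter sampler for virtual participants
#'
#' Generating parameters for recovery studies are drawn uniformly over the
#' range of plausibly fitted values: learning rates over `[0, 1]`, the value
#' weight `beta_q` over `[0.5, 6]` and the uncertainty weight `beta_u` over
#' `[-8, 0]` (uncertainty-averse). All ranges are configurable by editing
#' the returned list.
#'
#' @param model_id Model identifier.
#' @return Named list of `c(lower, upper)` ranges, one per free parameter.
#' @export
default_sampler <- function(model_id) {
  info <- model_info(model_id)
  ranges <- list()
  for (a in info$alphas) ranges[[a]] <- c(0, 1)
  ranges[["beta_q"]] <- c(0.5, 6)
  if ("beta_u" %in% info$betas) ranges[["beta_u"]] <- c(-8, 0)
  ranges
}

#' Sample parameter sets for virtual participants
#'
#' @param model_id Model identifier.
#' @param n Number of parameter sets.
#' @param sampler Named list of ranges as returned by [default_sampler()].
#' @param seed Optional seed; uses the current RNG stream when `NULL`.
#' @return data.frame, one row per virtual subject, one column per
#'   parameter.
#' @export
sample_parameters <- function(model_id, n, sampler = default_sampler(model_id),
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(sampler, function(r) stats::runif(n, r[1], r[2]))
  as.data.frame(out)
}

# Shared fast state for the simulation loop: plain vectors indexed by
# integers, mirroring the compiled replay engine.
sim_state <- function(design, opts) {
  q0 <- mean(design$alphabet)
  s20 <- mean(design$alphabet^2) - q0^2
  list(q0 = q0, s20 = s20,
       q = rep(q0, nrow(opts)), s2 = rep(s20, nrow(opts)))
}

sim_update <- function(st, info, a, ci, oi, ki, R, ctx) {
  switch(info$learner,
    "1alpha" = st$q[ci] <- st$q[ci] + a[1] * (R - st$q[ci]),
    "2alpha" = {
      d <- R - st$q[ci]
      if (d > 0) st$q[ci] <- st$q[ci] + a[1] * d
      else if (d < 0) st$q[ci] <- st$q[ci] + a[2] * d
    },
    "select_reject" = {
      d <- R - st$q[ci]
      st$q[ci] <- st$q[ci] + a[1] * d
      st$q[oi] <- st$q[oi] - a[2] * d
    },
    "relative" = {
      d <- R - ctx$v[ki] - st$q[ci]
      st$q[ci] <- st$q[ci] + a[1] * d
      ctx$v[ki] <- ctx$v[ki] + a[2] * ((R + st$q[oi]) / 2 - ctx$v[ki])
    },
    "range" = {
      rran <- (R - ctx$rmin[ki]) / (1 + ctx$rmax[ki] - ctx$rmin[ki])
      st$q[ci] <- st$q[ci] + a[1] * (rran - st$q[ci])
      if (R > ctx$rmax[ki]) ctx$rmax[ki] <- ctx$rmax[ki] + a[2] * (R - ctx$rmax[ki])
      if (R < ctx$rmin[ki]) ctx$rmin[ki] <- ctx$rmin[ki] + a[2] * (R - ctx$rmin[ki])
    },
    "kalman" = {
      al <- st$s2[ci] / (st$s2[ci] + st$s20)
      st$q[ci] <- st$q[ci] + al * (R - st$q[ci])
      st$s2[ci] <- st$s2[ci] - al * st$s2[ci]
    }
  )
  if (info$track_sigma && info$learner != "kalman") {
    al <- st$s2[ci] / (st$s2[ci] + st$s20)
    st$s2[ci] <- st$s2[ci] - al * st$s2[ci]
  }
  list(st = st, ctx = ctx)
}

#' Simulate one virtual participant through the learning phase
#'
#' Runs a (learner, decider, parameters) agent along a learning schedule:
#' each trial the choice is sampled from the softmax over the current
#' utilities, the chosen option's outcome is drawn from its condition's
#' generative feedback rule (partial feedback: only the chosen option's
#' outcome is seen and learned from), and beliefs are updated.
#'
#' @param model_id Model identifier.
#' @param params Named numeric vector of model parameters.
#' @param design The `rl_design`.
#' @param schedule Learning schedule from [build_learning_schedule()].
#' @param seed Optional seed for choice and outcome draws.
#' @return List with `trials` (the schedule plus `choice` and `outcome`
#'   columns) and `beliefs` (the final `rl_beliefs` state).
#' @export
simulate_learning_phase <- function(model_id, params, design, schedule,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  info <- model_info(model_id)
  p <- split_params(info, params)
  opts <- design_option_table(design)
  opt_index <- stats::setNames(seq_len(nrow(opts)), opts$option)
  pair_ids <- unique(schedule$pair_id)
  ctx <- list(v = rep(0, length(pair_ids)),
              rmax = rep(0, length(pair_ids)),
              rmin = rep(0, length(pair_ids)))
  st <- sim_state(design, opts)
  n <- nrow(schedule)
  li <- opt_index[schedule$option_left]
  ri <- opt_index[schedule$option_right]
  ki <- match(schedule$pair_id, pair_ids)
  cond_rows <- lapply(seq_len(nrow(design$conditions)),
                      function(i) as.list(design$conditions[i, ]))
  cond_of_opt <- match(opts$condition, design$conditions$condition_id)
  choice <- character(n)
  outcome <- numeric(n)
  qu <- info$decider == "qu"
  for (t in seq_len(n)) {
    l <- li[t]; r <- ri[t]
    ud <- p$beta_q * (st$q[l] - st$q[r])
    if (qu) ud <- ud + p$beta_u * (sqrt(st$s2[l]) - sqrt(st$s2[r]))
    pick_left <- stats::runif(1) < stats::plogis(ud)
    ci <- if (pick_left) l else r
    oi <- if (pick_left) r else l
    R <- sample_outcome(cond_rows[[cond_of_opt[ci]]], opts$role[ci], 1L)
    upd <- sim_update(st, info, p$alphas, ci, oi, ki[t], R, ctx)
    st <- upd$st; ctx <- upd$ctx
    choice[t] <- opts$option[ci]
    outcome[t] <- R
  }
  trials <- schedule
  trials$choice <- choice
  trials$outcome <- outcome
  beliefs <- init_beliefs(model_id, design)
  beliefs$q[opts$option] <- st$q
  beliefs$s2[opts$option] <- st$s2
  beliefs$v[pair_ids] <- ctx$v
  beliefs$r_max[pair_ids] <- ctx$rmax
  beliefs$r_min[pair_ids] <- ctx$rmin
  list(trials = trials, beliefs = beliefs)
}

#' Simulate one virtual participant through the feedback-free test phase
#'
#' Choices are sampled from the softmax over the frozen beliefs carried out
#' of the learning phase; no outcomes are delivered and no beliefs are
#' updated.
#'
#' @param model_id Model identifier (determines the decider; its utilities
#'   read `q` and, for `qu`, `sigma` from the frozen beliefs).
#' @param params Named numeric vector with the test-phase decision weights.
#' @param beliefs Final `rl_beliefs` from the same subject's learning phase.
#' @param schedule Test schedule from [build_test_schedule()].
#' @param seed Optional seed.
#' @return The schedule with a `choice` column and `outcome` set to `NA`.
#' @export
simulate_test_phase <- function(model_id, params, beliefs, schedule,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  info <- model_info(model_id)
  p <- split_params(info, params)
  unknown <- setdiff(unique(c(schedule$option_left, schedule$option_right)),
                     names(beliefs$q))
  if (length(unknown) > 0) {
    stop("options in test schedule without beliefs: ",
         paste(unknown, collapse = ", "))
  }
  ql <- beliefs$q[schedule$option_left]
  qr <- beliefs$q[schedule$option_right]
  ud <- p$beta_q * (ql - qr)
  if (info$decider == "qu") {
    ud <- ud + p$beta_u * (sqrt(beliefs$s2[schedule$option_left]) -
                             sqrt(beliefs$s2[schedule$option_right]))
  }
  pick_left <- stats::runif(nrow(schedule)) < stats::plogis(ud)
  trials <- schedule
  trials$choice <- ifelse(pick_left, schedule$option_left,
                          schedule$option_right)
  trials$outcome <- NA_real_
  trials
}

#' Generate a synthetic cohort of virtual participants
#'
#' For each virtual subject: draw model parameters from the sampler, build
#' subject-specific learning and test schedules, simulate the learning
#' phase, then the feedback-free test phase on the frozen beliefs. The
#' test-phase decision weights are drawn independently of the learning-phase
#' weights (set `independent_test_betas = FALSE` to reuse them). Each
#' subject's draws come from an RNG stream derived from the master seed, so
#' cohorts are bit-for-bit reproducible.
#'
#' @param n_subjects Number of virtual participants.
#' @param model_id Model identifier.
#' @param design The `rl_design`.
#' @param seed Master seed.
#' @param sampler Parameter ranges, see [default_sampler()].
#' @param independent_test_betas Draw separate test-phase decision weights
#'   (default `TRUE`).
#' @return List of class `rl_cohort` with `trials` (all subjects, learning
#'   and test rows), `params` (one row per subject: generating values;
#'   test-phase weights prefixed `test_`), `model_id` and `design`.
#' @export
generate_cohort <- function(n_subjects, model_id, design, seed = 1L,
                            sampler = default_sampler(model_id),
                            independent_test_betas = TRUE) {
  stopifnot(n_subjects >= 1)
  info <- model_info(model_id)
  set.seed(seed)
  params <- sample_parameters(model_id, n_subjects, sampler)
  test_betas <- params[, info$betas, drop = FALSE]
  if (independent_test_betas) {
    test_betas <- sample_parameters(model_id, n_subjects,
                                    sampler)[, info$betas, drop = FALSE]
  }
  names(test_betas) <- paste0("test_", names(test_betas))
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  all_trials <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    ssd <- subject_seeds[i]
    lsched <- build_learning_schedule(design, seed = ssd)
    tsched <- build_test_schedule(design, lsched, seed = ssd)
    pl <- unlist(params[i, , drop = FALSE])
    sim <- simulate_learning_phase(model_id, pl, design, lsched, seed = ssd)
    pt <- pl
    pt[info$betas] <- unlist(test_betas[i, , drop = FALSE])
    test <- simulate_test_phase(model_id, pt, sim$beliefs, tsched,
                                seed = ssd + 1L)
    lt <- sim$trials
    lt$pair_type <- NA_character_
    lt <- lt[, c("phase", "block", "trial", "pair_id", "pair_type",
                 "condition", "option_left", "option_right", "choice",
                 "outcome")]
    tt <- test[, c("phase", "block", "trial", "pair_id", "pair_type",
                   "condition", "option_left", "option_right", "choice",
                   "outcome")]
    sub <- rbind(lt, tt)
    sub$subject <- sprintf("s%03d", i)
    all_trials[[i]] <- sub
  }
  trials <- do.call(rbind, all_trials)
  trials <- trials[, c("subject", "phase", "block", "trial", "pair_id",
                       "pair_type", "condition", "option_left",
                       "option_right", "choice", "outcome")]
  rownames(trials) <- NULL
  structure(
    list(trials = trials,
         params = cbind(data.frame(subject = sprintf("s%03d",
                                                     seq_len(n_subjects))),
                        params, test_betas),
         model_id = model_id, design = design, seed = seed),
    class = "rl_cohort"
  )
}

#' @export
print.rl_cohort <- function(x, ...) {
  cat("<rl_cohort>", x$model_id, "-",
      length(unique(x$trials$subject)), "subjects,",
      nrow(x$trials), "trials\n")
  invisible(x)
}
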