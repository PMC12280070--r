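#' @useDynLib kalmanbandit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

learner_code <- function(learner) {
  match(learner, LEARNER_IDS) - 1L
}

#' Prepare one subject's trials for belief replay
#'
#' Indexes a chronologically ordered set of trials (learning first, then
#' test) for the replay engine: 0-based option and context indices, the
#' chosen/unchosen option per trial, outcomes, and which rows update
#' beliefs (learning rows only).
#'
#' @param trials data.frame of one subject's trials in the trial-table
#'   layout (see [read_trials()]).
#' @param design The `rl_design` the trials come from (supplies the outcome
#'   alphabet, hence `q0` and `sigma0`).
#' @return A list used by [phase_log_likelihood()] and [belief_trajectory()].
#' @keywords internal
replay_data <- function(trials, design) {
  stopifnot(all(c("phase", "trial", "pair_id", "option_left", "option_right",
                  "choice") %in% names(trials)))
  ord <- order(match(trials$phase, c("learning", "test")), trials$trial)
  trials <- trials[ord, ]
  opts <- sort(unique(c(trials$option_left, trials$option_right)))
  ctxs <- unique(trials$pair_id)
  chosen_is_left <- trials$choice == trials$option_left
  bad <- !chosen_is_left & trials$choice != trials$option_right
  if (any(bad)) {
    stop("choice is neither shown option in rows: ",
         paste(utils::head(which(bad)), collapse = ", "))
  }
  unchosen <- ifelse(chosen_is_left, trials$option_right, trials$option_left)
  is_learning <- trials$phase == "learning"
  outcome <- trials$outcome
  outcome[!is_learning] <- 0
  if (anyNA(outcome[is_learning])) {
    stop("learning trials with missing outcome")
  }
  q0 <- mean(design$alphabet)
  s20 <- mean(design$alphabet^2) - q0^2
  list(
    chosen = match(trials$choice, opts) - 1L,
    other = match(unchosen, opts) - 1L,
    ctx = match(trials$pair_id, ctxs) - 1L,
    outcome = as.numeric(outcome),
    is_learning = is_learning,
    n_options = length(opts),
    n_ctx = length(ctxs),
    options = opts,
    q0 = q0, s20 = s20,
    trials = trials
  )
}

split_params <- function(info, params) {
  params <- unlist(params)
  need <- c(info$alphas, info$betas)
  miss <- setdiff(need, names(params))
  if (length(miss) > 0) {
    stop("missing parameters for ", info$model_id, ": ",
         paste(miss, collapse = ", "))
  }
  list(alphas = unname(params[info$alphas]),
       beta_q = params[["beta_q"]],
       beta_u = if ("beta_u" %in% need) params[["beta_u"]] else 0)
}

#' Log-likelihood of one subject's choices in one phase
#'
#' Replays the subject's actual choices and outcomes through the model's
#' belief updates and accumulates the log softmax probability of each
#' choice, evaluated on the beliefs held before that trial's update. For
#' `phase = "test"` the learning trials are replayed first (partial
#' feedback means the subject's own choices determine what was sampled) to
#' obtain the frozen beliefs, and only test choices are scored.
#'
#' @param model_id Model identifier.
#' @param params Named numeric vector of the model's free parameters.
#' @param trials One subject's trials (must include the learning phase when
#'   `phase = "test"`).
#' @param phase `"learning"` or `"test"`.
#' @param design The `rl_design` of the experiment.
#' @return Log-likelihood in nats (non-positive).
#' @export
phase_log_likelihood <- function(model_id, params, trials, phase, design) {
  rd <- replay_data(trials, design)
  phase_log_likelihood_rd(model_id, params, rd, phase)
}

phase_log_likelihood_rd <- function(model_id, params, rd, phase) {
  info <- model_info(model_id)
  p <- split_params(info, params)
  score <- if (phase == "learning") rd$is_learning else !rd$is_learning
  if (!any(score)) stop("no ", phase, " trials to score")
  -replay_negll_cpp(
    learner_code(info$learner), info$decider == "qu", info$track_sigma,
    rd$chosen, rd$other, rd$ctx, rd$outcome,
    rd$is_learning, score,
    rd$n_options, rd$n_ctx, rd$q0, rd$s20,
    p$alphas, p$beta_q, p$beta_u
  )
}

#' Belief trajectory along one subject's trials
#'
#' Returns the chosen and unchosen option's expected value and
#' estimation-uncertainty at decision time on every trial, in trial order
#' (learning first, then test with frozen beliefs).
#'
#' @inheritParams phase_log_likelihood
#' @return data.frame with the trial bookkeeping columns plus `q_chosen`,
#'   `q_other`, `sigma_chosen`, `sigma_other`.
#' @export
belief_trajectory <- function(model_id, params, trials, design) {
  info <- model_info(model_id)
  rd <- replay_data(trials, design)
  p <- split_params(info, c(params, beta_q = 0, beta_u = 0)[
    unique(c(names(params), "beta_q", "beta_u"))])
  tr <- replay_traj_cpp(
    learner_code(info$learner), info$track_sigma,
    rd$chosen, rd$other, rd$ctx, rd$outcome, rd$is_learning,
    rd$n_options, rd$n_ctx, rd$q0, rd$s20, p$alphas
  )
  cbind(rd$trials[, c("subject", "phase", "trial", "pair_id")],
        as.data.frame(tr))
}

# Pure-R reference replay: same contract as replay_negll_cpp, built from the
# exported single-step update functions. Used as the independent oracle in
# the test suite; not optimized.
replay_negll_r <- function(model_id, params, rd, phase) {
  info <- model_info(model_id)
  p <- split_params(info, params)
  score <- if (phase == "learning") rd$is_learning else !rd$is_learning
  q <- rep(rd$q0, rd$n_options)
  s2 <- rep(rd$s20, rd$n_options)
  v <- rmax <- rmin <- rep(0, rd$n_ctx)
  a <- p$alphas
  ll <- 0
  for (t in seq_along(rd$chosen)) {
    c_ <- rd$chosen[t] + 1L
    o_ <- rd$other[t] + 1L
    k_ <- rd$ctx[t] + 1L
    if (score[t]) {
      ud <- p$beta_q * (q[c_] - q[o_])
      if (info$decider == "qu") {
        ud <- ud + p$beta_u * (sqrt(s2[c_]) - sqrt(s2[o_]))
      }
      ll <- ll + log_softmax_prob(ud, 0)
    }
    if (rd$is_learning[t]) {
      R <- rd$outcome[t]
      switch(info$learner,
        "1alpha" = {
          q[c_] <- qlearn_update(q[c_], a[1], R)$q
        },
        "2alpha" = {
          q[c_] <- dual_rate_update(q[c_], a[1], a[2], R)$q
        },
        "select_reject" = {
          u <- select_reject_update(q[c_], q[o_], a[1], a[2], R)
          q[c_] <- u$q_selected; q[o_] <- u$q_rejected
        },
        "relative" = {
          u <- relative_update(q[c_], q[o_], v[k_], a[1], a[2], R)
          q[c_] <- u$q_selected; v[k_] <- u$v
        },
        "range" = {
          u <- range_update(q[c_], rmax[k_], rmin[k_], a[1], a[2], R)
          q[c_] <- u$q; rmax[k_] <- u$r_max; rmin[k_] <- u$r_min
        },
        "kalman" = {
          u <- kalman_update(q[c_], s2[c_], rd$s20, R)
          q[c_] <- u$q; s2[c_] <- u$s2
        }
      )
      if (info$track_sigma && info$learner != "kalman") {
        al <- s2[c_] / (s2[c_] + rd$s20)
        s2[c_] <- s2[c_] - al * s2[c_]
      }
    }
  }
  -ll
}
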