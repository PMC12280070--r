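#' Learning models
#'
#' Six trial-by-trial learning rules over per-option expected values `q`:
#'
#' * `1alpha` — constant-rate Q-learning, `q <- q + alpha * (R - q)`.
#' * `2alpha` — separate rates for positive (`alpha_plus`) and negative
#'   (`alpha_minus`) prediction errors; a zero prediction error updates
#'   nothing.
#' * `select_reject` — the selected option is updated with its prediction
#'   error at rate `alpha_selected`, and the rejected option with the
#'   reverse-signed prediction error at rate `alpha_rejected`.
#' * `relative` — outcomes are centred on a learned context value `V_c`
#'   (one per stimulus pair); `V_c` tracks `(R + q_rejected)/2` at rate
#'   `alpha_c`.
#' * `range` — outcomes are normalized by learned context trackers
#'   `R_MIN`/`R_MAX`: `R_RAN = (R - R_MIN) / (1 + R_MAX - R_MIN)`; trackers
#'   move toward outcomes that exceed them at rate `alpha_r`.
#' * `kalman` — a Kalman-filter learner with a per-option
#'   estimation-uncertainty `sigma`; the learning rate
#'   `alpha = sigma^2 / (sigma^2 + sigma0^2)` is dynamic and the variance
#'   shrinks as `sigma^2 <- sigma^2 - alpha * sigma^2`. No free learning
#'   parameter.
#'
#' Any non-Kalman learner can be composed with the Kalman uncertainty
#' recursion (see [attach_uncertainty_tracker()]); its `q` then follows the
#' base rule while its `sigma` follows the Kalman recursion for the chosen
#' option, enabling uncertainty-sensitive decisions for every learner.
#'
#' @name learning-models
NULL

LEARNER_IDS <- c("1alpha", "2alpha", "select_reject", "relative", "range",
                 "kalman")
DECIDER_IDS <- c("q", "qu")

learner_alpha_names <- function(learner) {
  switch(learner,
    "1alpha" = "alpha",
    "2alpha" = c("alpha_plus", "alpha_minus"),
    "select_reject" = c("alpha_selected", "alpha_rejected"),
    "relative" = c("alpha", "alpha_c"),
    "range" = c("alpha", "alpha_r"),
    "kalman" = character(0),
    stop("unknown learner: ", learner)
  )
}

#' Model registry: learner x decider combinations
#'
#' Model identifiers join a learner and a decider with an underscore, e.g.
#' `"kalman_qu"` is the Kalman-filter learner deciding on expected values
#' and estimation-uncertainties. `model_info()` resolves an identifier into
#' its parts and free parameters.
#'
#' @param model_id Model identifier such as `"1alpha_q"` or `"kalman_qu"`.
#' @return A list with elements `model_id`, `learner`, `decider`,
#'   `track_sigma` (whether the uncertainty recursion runs), and
#'   `param_names` split into `alphas` and `betas`.
#' @examples
#' model_info("kalman_qu")
#' all_model_ids()
#' @export
model_info <- function(model_id) {
  m <- regmatches(model_id, regexec("^(.*)_(qu|q)$", model_id))[[1]]
  if (length(m) != 3 || !(m[2] %in% LEARNER_IDS)) {
    stop("unknown model_id: ", model_id)
  }
  learner <- m[2]
  decider <- m[3]
  list(
    model_id = model_id,
    learner = learner,
    decider = decider,
    track_sigma = decider == "qu" || learner == "kalman",
    alphas = learner_alpha_names(learner),
    betas = if (decider == "q") "beta_q" else c("beta_q", "beta_u")
  )
}

#' @rdname model_info
#' @export
all_model_ids <- function() {
  as.vector(outer(LEARNER_IDS, DECIDER_IDS, paste, sep = "_"))
}

#' Compose a learner with the Kalman uncertainty tracker
#'
#' Returns the model identifier of the given learner equipped with the
#' Kalman estimation-uncertainty recursion and the uncertainty-sensitive
#' decider: the option values follow the base learning rule, while each
#' option's `sigma` shrinks with its number of observations exactly as under
#' the Kalman learner (the recursion depends only on the choice sequence).
#'
#' @param learner One of the non-Kalman learner identifiers.
#' @return The composite model id, e.g. `"range_qu"`.
#' @export
attach_uncertainty_tracker <- function(learner) {
  if (!learner %in% LEARNER_IDS) stop("unknown learner: ", learner)
  paste0(learner, "_qu")
}

#' Initialize beliefs for a design
#'
#' Every option starts at `q0`, the expected value of a randomly selected
#' outcome from the design's alphabet (probability 1/|alphabet| each), with
#' initial estimation-uncertainty `sigma0`, the standard deviation of that
#' categorical distribution. Context trackers start at `V_c = 0` and
#' `R_MAX = R_MIN = 0` (the omnipresent non-reward outcome).
#'
#' @param model_id Model identifier (see [model_info()]).
#' @param design An `rl_design`.
#' @return A list of class `rl_beliefs` with named vectors `q` and `s2`
#'   (variance) over option ids, context tracker vectors `v`, `r_max`,
#'   `r_min` over pair ids, and constants `q0`, `s20`.
#' @examples
#' b <- init_beliefs("kalman_qu", make_main_design())
#' b$q0          # 0
#' sqrt(b$s20)   # sigma0 = sqrt(2/3)
#' @export
init_beliefs <- function(model_id, design) {
  info <- model_info(model_id)
  opts <- design_option_table(design)
  q0 <- mean(design$alphabet)
  s20 <- mean(design$alphabet^2) - q0^2
  pair_ids <- if (design$type == "main") {
    unique(paste0("b", opts$block, "_", opts$condition))
  } else {
    unique(opts$condition)
  }
  q <- stats::setNames(rep(q0, nrow(opts)), opts$option)
  s2 <- stats::setNames(rep(s20, nrow(opts)), opts$option)
  v <- stats::setNames(rep(0, length(pair_ids)), pair_ids)
  structure(
    list(model_id = model_id, q = q, s2 = s2,
         v = v, r_max = v, r_min = v, q0 = q0, s20 = s20),
    class = "rl_beliefs"
  )
}

#' Single-option Q-learning update
#'
#' @param q Current expected value of the chosen option.
#' @param alpha Learning rate in `[0, 1]`.
#' @param outcome Received outcome `R`.
#' @return List with the updated value `q`, the prediction error `delta`
#'   and the effective learning rate `alpha_used`.
#' @export
qlearn_update <- function(q, alpha, outcome) {
  delta <- outcome - q
  list(q = q + alpha * delta, delta = delta, alpha_used = alpha)
}

#' Dual-rate Q-learning update
#'
#' Applies `alpha_plus` to positive and `alpha_minus` to negative prediction
#' errors; a zero prediction error leaves the value unchanged.
#'
#' @inheritParams qlearn_update
#' @param alpha_plus,alpha_minus Learning rates in `[0, 1]`.
#' @export
dual_rate_update <- function(q, alpha_plus, alpha_minus, outcome) {
  delta <- outcome - q
  a <- if (delta > 0) alpha_plus else if (delta < 0) alpha_minus else 0
  list(q = q + a * delta, delta = delta, alpha_used = a)
}

#' Selected/rejected update
#'
#' The selected option learns from its prediction error; the rejected option
#' learns from the reverse-signed prediction error of the selected option.
#'
#' @param q_selected,q_rejected Current expected values.
#' @param alpha_selected,alpha_rejected Learning rates in `[0, 1]`.
#' @param outcome Received outcome for the selected option.
#' @export
select_reject_update <- function(q_selected, q_rejected,
                                 alpha_selected, alpha_rejected, outcome) {
  delta <- outcome - q_selected
  list(q_selected = q_selected + alpha_selected * delta,
       q_rejected = q_rejected + alpha_rejected * (-delta),
       delta = delta)
}

#' Context-centred (relative) update
#'
#' The selected option's prediction error is computed against the outcome
#' centred on the context value, `delta = R - V_c - q`; afterwards the
#' context value moves toward `(R + q_rejected) / 2` at rate `alpha_c`.
#'
#' @param q_selected,q_rejected Current expected values.
#' @param v Context value `V_c` of the pair.
#' @param alpha,alpha_c Learning rates in `[0, 1]`.
#' @param outcome Received outcome.
#' @return List with updated `q_selected`, `v`, and the two prediction
#'   errors `delta` and `delta_c`.
#' @export
relative_update <- function(q_selected, q_rejected, v, alpha, alpha_c,
                            outcome) {
  delta <- outcome - v - q_selected
  q_new <- q_selected + alpha * delta
  delta_c <- (outcome + q_rejected) / 2 - v
  list(q_selected = q_new, v = v + alpha_c * delta_c,
       delta = delta, delta_c = delta_c)
}

#' Range-normalization update
#'
#' The outcome is normalized by the context's current range trackers,
#' `R_RAN = (R - R_MIN) / (1 + R_MAX - R_MIN)`, and drives a Q-learning
#' update at rate `alpha`; the trackers then move toward outcomes exceeding
#' them at rate `alpha_r`.
#'
#' @param q Current expected value of the chosen option.
#' @param r_max,r_min Context range trackers.
#' @param alpha,alpha_r Learning rates in `[0, 1]`.
#' @param outcome Received outcome `R_OBJ`.
#' @return List with updated `q`, `r_max`, `r_min`, the normalized outcome
#'   `r_ran` and prediction error `delta`.
#' @export
range_update <- function(q, r_max, r_min, alpha, alpha_r, outcome) {
  r_ran <- (outcome - r_min) / (1 + r_max - r_min)
  delta <- r_ran - q
  q_new <- q + alpha * delta
  if (outcome > r_max) r_max <- r_max + alpha_r * (outcome - r_max)
  if (outcome < r_min) r_min <- r_min + alpha_r * (outcome - r_min)
  list(q = q_new, r_max = r_max, r_min = r_min, r_ran = r_ran, delta = delta)
}

#' Kalman-filter update
#'
#' Dynamic learning rate `alpha = sigma^2 / (sigma^2 + sigma0^2)`; the value
#' moves toward the outcome at that rate and the estimation variance shrinks
#' as `sigma^2 <- sigma^2 - alpha * sigma^2`. Starting from `sigma^2 =
#' sigma0^2`, after `k` observations `sigma^2 = sigma0^2 / (k + 1)` and `q`
#' equals the pseudo-count running mean `(q0 + sum(R)) / (k + 1)`.
#'
#' @param q Current expected value.
#' @param s2 Current estimation variance `sigma^2`.
#' @param s20 Constant observation variance `sigma0^2`.
#' @param outcome Received outcome.
#' @return List with updated `q`, `s2`, plus `delta` and `alpha_used`.
#' @export
kalman_update <- function(q, s2, s20, outcome) {
  alpha <- s2 / (s2 + s20)
  delta <- outcome - q
  list(q = q + alpha * delta, s2 = s2 - alpha * s2,
       delta = delta, alpha_used = alpha)
}

#' One full belief-state transition (reference implementation)
#'
#' Applies one trial's update to an `rl_beliefs` state for any model:
#' value update of the chosen (and, where the model says so, unchosen)
#' option, context-tracker updates, and the Kalman sigma recursion when the
#' model tracks uncertainty. This pure-R transition is the reference against
#' which the compiled replay engine is checked; simulation also uses it.
#'
#' @param beliefs An `rl_beliefs` state.
#' @param chosen,unchosen Option ids shown this trial.
#' @param pair_id Context (pair) id.
#' @param outcome Received outcome.
#' @param params Named numeric vector with the learner's rate parameters.
#' @return The updated `rl_beliefs`.
#' @export
belief_step <- function(beliefs, chosen, unchosen, pair_id, outcome, params) {
  info <- model_info(beliefs$model_id)
  b <- beliefs
  switch(info$learner,
    "1alpha" = {
      u <- qlearn_update(b$q[[chosen]], params[["alpha"]], outcome)
      b$q[[chosen]] <- u$q
    },
    "2alpha" = {
      u <- dual_rate_update(b$q[[chosen]], params[["alpha_plus"]],
                            params[["alpha_minus"]], outcome)
      b$q[[chosen]] <- u$q
    },
    "select_reject" = {
      u <- select_reject_update(b$q[[chosen]], b$q[[unchosen]],
                                params[["alpha_selected"]],
                                params[["alpha_rejected"]], outcome)
      b$q[[chosen]] <- u$q_selected
      b$q[[unchosen]] <- u$q_rejected
    },
    "relative" = {
      u <- relative_update(b$q[[chosen]], b$q[[unchosen]], b$v[[pair_id]],
                           params[["alpha"]], params[["alpha_c"]], outcome)
      b$q[[chosen]] <- u$q_selected
      b$v[[pair_id]] <- u$v
    },
    "range" = {
      u <- range_update(b$q[[chosen]], b$r_max[[pair_id]],
                        b$r_min[[pair_id]], params[["alpha"]],
                        params[["alpha_r"]], outcome)
      b$q[[chosen]] <- u$q
      b$r_max[[pair_id]] <- u$r_max
      b$r_min[[pair_id]] <- u$r_min
    },
    "kalman" = {
      u <- kalman_update(b$q[[chosen]], b$s2[[chosen]], b$s20, outcome)
      b$q[[chosen]] <- u$q
      b$s2[[chosen]] <- u$s2
    }
  )
  if (info$track_sigma && info$learner != "kalman") {
    a <- b$s2[[chosen]] / (b$s2[[chosen]] + b$s20)
    b$s2[[chosen]] <- b$s2[[chosen]] - a * b$s2[[chosen]]
  }
  b
}
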