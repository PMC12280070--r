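#' Decision models
#'
#' Beliefs are mapped to binary choice probabilities through a softmax over
#' option utilities. Decision model `Q` weighs expected values only; model
#' `QU` adds the estimation-uncertainty, so a negative `beta_u` expresses
#' uncertainty aversion.
#'
#' @name decision-models
NULL

#' Utility of an option under decision model Q
#'
#' `u = q * beta_q`.
#'
#' @param q Expected value.
#' @param beta_q Decision weight for expected value.
#' @return Utility.
#' @export
utility_q <- function(q, beta_q) q * beta_q

#' Utility of an option under decision model QU
#'
#' `u = q * beta_q + sigma * beta_u`.
#'
#' @inheritParams utility_q
#' @param sigma Estimation-uncertainty (standard deviation).
#' @param beta_u Decision weight for estimation-uncertainty; negative values
#'   penalize uncertain options.
#' @export
utility_qu <- function(q, sigma, beta_q, beta_u) q * beta_q + sigma * beta_u

#' Softmax choice probability for two options
#'
#' `p_i = exp(u_i) / (exp(u_i) + exp(u_j))`, evaluated as the logistic of
#' the utility difference so that large utilities (|beta| up to 20 on
#' magnitude-10 outcomes) cannot overflow.
#'
#' @param u_i Utility of the option whose choice probability is returned.
#' @param u_j Utility of the alternative.
#' @return Probability in `(0, 1)` (up to floating point saturation).
#' @examples
#' softmax_prob(0, 0)        # 0.5
#' softmax_prob(log(3), 0)   # 0.75
#' @export
softmax_prob <- function(u_i, u_j) {
  stats::plogis(u_i - u_j)
}

#' Log choice probability, numerically stable
#'
#' `log p_i` computed as `-log(1 + exp(-(u_i - u_j)))` without overflow.
#'
#' @inheritParams softmax_prob
#' @keywords internal
log_softmax_prob <- function(u_i, u_j) {
  d <- u_i - u_j
  ifelse(d > 0, -log1p(exp(-d)), d - log1p(exp(d)))
}
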