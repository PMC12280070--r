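#' Priors and bounds for subject-level fitting
#'
#' Independent Gaussian priors: centred on a rate of 0.5 and a weight of
#' 0, with variance 16.25 for every parameter — deliberately broad so that
#' the likelihood dominates whenever the data are informative. Learning
#' rates live on `[0, 1]` and are fitted on the logit scale, where the
#' prior applies (the convention of hierarchical fitters for bounded
#' rates); decision weights are fitted in native space within
#' `[-20, 20]`.
#'
#' @param variance Prior variance (shared by every parameter).
#' @return List with `alpha_mean`, `beta_mean`, `variance`.
#' @export
default_priors <- function(variance = 16.25) {
  list(alpha_mean = 0.5, beta_mean = 0, variance = variance)
}

# Learning rates are optimized on the logit scale (the convention of
# hierarchical fitters for [0,1]-bounded rates): the Gaussian prior of
# variance `priors$variance` applies to the logit, centred on
# qlogis(alpha_mean), and the Laplace evidence is computed in that space.
# Decision weights are fitted in native space within their bounds.
param_table <- function(model_id, priors = default_priors()) {
  info <- model_info(model_id)
  nm <- c(info$alphas, info$betas)
  is_alpha <- nm %in% info$alphas
  data.frame(
    name = nm,
    is_rate = is_alpha,
    lower = ifelse(is_alpha, -16, -20),
    upper = ifelse(is_alpha, 16, 20),
    prior_mean = ifelse(is_alpha, stats::qlogis(priors$alpha_mean),
                        priors$beta_mean),
    prior_sd = sqrt(priors$variance),
    stringsAsFactors = FALSE
  )
}

to_native <- function(par, pt) {
  out <- ifelse(pt$is_rate, stats::plogis(par), par)
  stats::setNames(out, pt$name)
}

#' McFadden pseudo-R-squared of a binary-choice model
#'
#' `1 - LL_model / LL_null`, the null model choosing each of the two
#' options with probability 0.5, so `LL_null = n * log(0.5)`.
#'
#' @param ll_model Log-likelihood of the model (nats).
#' @param n_trials Number of scored choices.
#' @return Dimensionless value, at most 1; 0 means no improvement over
#'   coin-flipping.
#' @examples
#' pseudo_r2(240 * log(0.5), 240)  # 0
#' pseudo_r2(0, 240)               # 1
#' @export
pseudo_r2 <- function(ll_model, n_trials) {
  1 - ll_model / (n_trials * log(0.5))
}

#' Laplace approximation to the log model evidence
#'
#' `log p(data | model) ~ log posterior at the MAP + (d/2) log(2 pi)
#' - (1/2) log det(H)`, with `H` the Hessian of the negative log posterior
#' at the MAP. A Hessian that is not positive definite is
#' ridge-regularized (scaled identity added until Cholesky succeeds) and
#' flagged.
#'
#' @param log_posterior Unnormalized log posterior (log-likelihood plus log
#'   prior) at the MAP.
#' @param hessian Hessian matrix of the negative log posterior at the MAP;
#'   for a model with no free parameters pass `NULL` and the evidence is
#'   the log-likelihood itself.
#' @return List with `log_evidence` and `regularized` flag.
#' @export
laplace_log_evidence <- function(log_posterior, hessian) {
  if (is.null(hessian) || length(hessian) == 0) {
    return(list(log_evidence = log_posterior, regularized = FALSE))
  }
  hessian <- as.matrix(hessian)
  d <- nrow(hessian)
  regularized <- FALSE
  H <- (hessian + t(hessian)) / 2
  if (any(!is.finite(H))) {
    H[!is.finite(H)] <- 0
    regularized <- TRUE
  }
  scale <- max(1, max(abs(H)))
  ridge <- 0
  for (k in 0:30) {
    Hk <- H + diag(ridge, d)
    ch <- tryCatch(chol(Hk), error = function(e) NULL)
    if (!is.null(ch)) {
      logdet <- 2 * sum(log(diag(ch)))
      return(list(
        log_evidence = log_posterior + 0.5 * d * log(2 * pi) - 0.5 * logdet,
        regularized = regularized
      ))
    }
    regularized <- TRUE
    ridge <- if (ridge == 0) 1e-12 * scale else ridge * 10
  }
  list(log_evidence = NA_real_, regularized = TRUE)
}

# Objective factory: negative log posterior over the free parameters,
# in param_table order. Models without learning parameters get a fast path
# where the belief trajectory is computed once and reused.
make_objective <- function(model_id, rd, phase, pt) {
  info <- model_info(model_id)
  n_alpha <- length(info$alphas)
  qu <- info$decider == "qu"
  score <- if (phase == "learning") rd$is_learning else !rd$is_learning
  if (!any(score)) stop("no ", phase, " trials to score")
  prior_mean <- pt$prior_mean
  prior_sd <- pt$prior_sd
  log_prior <- function(par) sum(stats::dnorm(par, prior_mean, prior_sd,
                                              log = TRUE))
  if (n_alpha == 0) {
    traj <- replay_traj_cpp(
      learner_code(info$learner), info$track_sigma,
      rd$chosen, rd$other, rd$ctx, rd$outcome, rd$is_learning,
      rd$n_options, rd$n_ctx, rd$q0, rd$s20, numeric(0)
    )
    dq <- traj[score, 1] - traj[score, 2]
    ds <- traj[score, 3] - traj[score, 4]
    nll_fun <- function(par) {
      ud <- par[1] * dq
      if (qu) ud <- ud + par[2] * ds
      -sum(log_softmax_prob(ud, 0))
    }
  } else {
    nll_fun <- function(par) {
      replay_negll_cpp(
        learner_code(info$learner), qu, info$track_sigma,
        rd$chosen, rd$other, rd$ctx, rd$outcome, rd$is_learning, score,
        rd$n_options, rd$n_ctx, rd$q0, rd$s20,
        stats::plogis(par[seq_len(n_alpha)]), par[n_alpha + 1],
        if (qu) par[n_alpha + 2] else 0
      )
    }
  }
  list(
    negpost = function(par) {
      v <- nll_fun(par) - log_prior(par)
      if (!is.finite(v)) 1e10 else v
    },
    nll = nll_fun,
    n_scored = sum(score)
  )
}

#' MAP fit of one subject in one phase
#'
#' Maximizes log-likelihood plus log prior by bounded quasi-Newton
#' (`L-BFGS-B`) from multiple restarts (the prior mean plus uniform draws
#' in the non-saturated region). Learning rates are optimized on the logit
#' scale and reported in native units; decision weights in native space.
#' The best restart is kept. The Laplace approximation to the model
#' evidence is computed from a finite-difference Hessian at the MAP, in
#' the fitting parametrization.
#'
#' @param model_id Model identifier.
#' @param trials One subject's trials (learning rows required; test rows
#'   required and scored when `phase = "test"`).
#' @param phase `"learning"` or `"test"`.
#' @param design The `rl_design`.
#' @param priors See [default_priors()].
#' @param n_restarts Number of optimizer starts (default 10).
#' @param seed Seed for the restart draws.
#' @return List of class `rl_fit`: MAP estimates `par`, `log_lik`,
#'   `log_posterior`, `log_evidence`, `pseudo_r2`, `n_trials`,
#'   `convergence` (TRUE if any restart converged cleanly), `regularized`
#'   (Hessian ridge flag).
#' @export
fit_map <- function(model_id, trials, phase = c("learning", "test"),
                    design, priors = default_priors(), n_restarts = 10L,
                    seed = 1L, prior_table = NULL) {
  phase <- match.arg(phase)
  pt <- param_table(model_id, priors)
  if (!is.null(prior_table)) {
    i <- match(pt$name, prior_table$name)
    stopifnot(!anyNA(i))
    pt$prior_mean <- prior_table$prior_mean[i]
    pt$prior_sd <- prior_table$prior_sd[i]
  }
  rd <- replay_data(trials, design)
  obj <- make_objective(model_id, rd, phase, pt)
  d <- nrow(pt)
  set.seed(seed)
  starts <- matrix(NA_real_, n_restarts, d)
  starts[1, ] <- pmin(pmax(pt$prior_mean, pt$lower), pt$upper)
  if (n_restarts > 1) {
    for (j in seq_len(d)) {
      # rates start within logit(0.08)..logit(0.92), weights within
      # [-5, 5], where the likelihood is not saturated
      lo <- if (pt$is_rate[j]) -2.5 else -5
      hi <- if (pt$is_rate[j]) 2.5 else 5
      starts[2:n_restarts, j] <- stats::runif(n_restarts - 1, lo, hi)
    }
  }
  best <- NULL
  any_conv <- FALSE
  for (r in seq_len(n_restarts)) {
    res <- tryCatch(
      stats::optim(starts[r, ], obj$negpost, method = "L-BFGS-B",
                   lower = pt$lower, upper = pt$upper,
                   control = list(maxit = 300)),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$value)) next
    if (res$convergence == 0) any_conv <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    stop("all optimizer restarts failed for ", model_id)
  }
  par <- to_native(best$par, pt)
  ll <- -obj$nll(best$par)
  lp <- -best$value
  # curvature is evaluated just inside the bounds: at a bound-pinned MAP
  # the objective is kinked and central differences straddling the bound
  # produce spurious (even indefinite) curvature
  nudge <- 5e-3
  hess_par <- pmin(pmax(best$par, pt$lower + nudge), pt$upper - nudge)
  H <- tryCatch(stats::optimHess(hess_par, obj$negpost),
                error = function(e) NULL)
  ev <- if (is.null(H)) list(log_evidence = NA_real_, regularized = TRUE)
        else laplace_log_evidence(lp, H)
  structure(
    list(
      subject = if ("subject" %in% names(trials)) trials$subject[1] else NA,
      model_id = model_id, phase = phase,
      par = par, log_lik = ll, log_posterior = lp,
      log_evidence = ev$log_evidence,
      pseudo_r2 = pseudo_r2(ll, obj$n_scored),
      n_trials = obj$n_scored,
      convergence = any_conv, regularized = ev$regularized,
      n_restarts = n_restarts
    ),
    class = "rl_fit"
  )
}

#' @export
print.rl_fit <- function(x, ...) {
  cat("<rl_fit>", x$model_id, "/", x$phase,
      " LL =", round(x$log_lik, 2),
      " evidence =", round(x$log_evidence, 2), "\n")
  print(round(x$par, 4))
  invisible(x)
}

#' Fit every subject of a dataset with one model
#'
#' @param model_id Model identifier.
#' @param trials Trial table covering one or more subjects.
#' @param phase `"learning"` or `"test"`.
#' @param design The `rl_design`.
#' @param ... Passed to [fit_map()] (`priors`, `n_restarts`).
#' @param seed Base seed; subject `i` is fitted with `seed + i`.
#' @param empirical_bayes Refit every subject a second time under a group
#'   prior estimated from the first-pass MAP estimates (per-parameter mean
#'   and standard deviation on the fitting scale, the standard deviation
#'   floored at `eb_floor`). This emulates the shrinkage a hierarchical
#'   fitter applies, stabilizing weakly identified subjects; evidences are
#'   reported from the first (broad-prior) pass so that model comparison
#'   is unaffected.
#' @param eb_floor Lower bound on the empirical-Bayes prior standard
#'   deviation.
#' @return data.frame with one row per subject: `subject`, `model_id`,
#'   `log_lik`, `log_evidence`, `pseudo_r2`, `n_trials`, `convergence` and
#'   one column per MAP parameter.
#' @export
fit_dataset <- function(model_id, trials, phase, design, ..., seed = 1L,
                        empirical_bayes = FALSE, eb_floor = 0.5) {
  subjects <- unique(trials$subject)
  one_pass <- function(prior_table) {
    rows <- vector("list", length(subjects))
    for (i in seq_along(subjects)) {
      fit <- fit_map(model_id, trials[trials$subject == subjects[i], ],
                     phase, design, ..., seed = seed + i,
                     prior_table = prior_table)
      rows[[i]] <- cbind(
        data.frame(subject = subjects[i], model_id = model_id,
                   log_lik = fit$log_lik, log_evidence = fit$log_evidence,
                   pseudo_r2 = fit$pseudo_r2, n_trials = fit$n_trials,
                   convergence = fit$convergence,
                   stringsAsFactors = FALSE),
        as.data.frame(as.list(fit$par))
      )
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  }
  out <- one_pass(NULL)
  if (empirical_bayes && length(subjects) >= 3) {
    pt <- param_table(model_id)
    fitspace <- sapply(seq_len(nrow(pt)), function(j) {
      v <- out[[pt$name[j]]]
      if (pt$is_rate[j]) stats::qlogis(pmin(pmax(v, 1e-7), 1 - 1e-7)) else v
    })
    fitspace <- matrix(fitspace, ncol = nrow(pt))
    group <- data.frame(
      name = pt$name,
      prior_mean = apply(fitspace, 2, mean),
      prior_sd = pmax(apply(fitspace, 2, stats::sd), eb_floor)
    )
    refit <- one_pass(group)
    # keep broad-prior evidences; adopt the shrunk parameter estimates
    refit$log_evidence <- out$log_evidence
    out <- refit
  }
  out
}
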