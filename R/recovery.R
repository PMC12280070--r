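#' Parameter recovery
#'
#' Simulates a cohort with known generating parameters, re-fits the
#' generating model, and correlates generating against recovered values.
#' For `phase = "test"` the generating values of the decision weights are
#' the test-phase draws (the learning phase is simulated first and its
#' beliefs frozen, exactly as in the experiment).
#'
#' @param model_id Model identifier.
#' @param n_virtual Number of virtual participants.
#' @param design The `rl_design`.
#' @param phase `"learning"` or `"test"`.
#' @param seed Master seed.
#' @param sampler Generating parameter ranges, see [default_sampler()].
#' @param n_restarts Optimizer restarts per fit.
#' @param empirical_bayes Refit under a group prior estimated from the
#'   first pass (see [fit_dataset()]); on by default, mirroring the
#'   hierarchical shrinkage of the procedure the recovery emulates.
#' @return List of class `recovery_report`: `generating` and `recovered`
#'   data.frames (one row per subject), `correlation` (generating x
#'   recovered Pearson matrix), plus run metadata.
#' @export
run_parameter_recovery <- function(model_id, n_virtual, design,
                                   phase = c("learning", "test"), seed = 1L,
                                   sampler = default_sampler(model_id),
                                   n_restarts = 10L,
                                   empirical_bayes = TRUE) {
  phase <- match.arg(phase)
  info <- model_info(model_id)
  if (length(c(info$alphas, info$betas)) == 0) {
    stop("model has no free parameters")
  }
  cohort <- generate_cohort(n_virtual, model_id, design, seed = seed,
                            sampler = sampler)
  fits <- fit_dataset(model_id, cohort$trials, phase, design,
                      n_restarts = n_restarts, seed = seed,
                      empirical_bayes = empirical_bayes)
  gen_names <- c(info$alphas, info$betas)
  generating <- cohort$params[, c("subject", gen_names)]
  if (phase == "test") {
    generating[info$betas] <-
      cohort$params[, paste0("test_", info$betas)]
  }
  recovered <- fits[, c("subject", gen_names)]
  stopifnot(identical(generating$subject, recovered$subject))
  corr <- stats::cor(as.matrix(generating[gen_names]),
                     as.matrix(recovered[gen_names]))
  dimnames(corr) <- list(paste0("gen_", gen_names),
                         paste0("rec_", gen_names))
  structure(list(
    model_id = model_id, phase = phase, n_virtual = n_virtual,
    sampler = sampler, seed = seed,
    generating = generating, recovered = recovered,
    correlation = corr
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>", x$model_id, "/", x$phase,
      "-", x$n_virtual, "virtual subjects\n")
  print(round(x$correlation, 3))
  invisible(x)
}

# Final beliefs after replaying a subject's actual learning trials under a
# given model/parameters (used to simulate candidate-model test behavior on
# learning data generated by a different model).
replay_final_beliefs <- function(model_id, params, trials, design) {
  info <- model_info(model_id)
  rd <- replay_data(trials[trials$phase == "learning", ], design)
  beliefs <- init_beliefs(model_id, design)
  for (t in seq_along(rd$chosen)) {
    beliefs <- belief_step(
      beliefs,
      chosen = rd$options[rd$chosen[t] + 1L],
      unchosen = rd$options[rd$other[t] + 1L],
      pair_id = rd$trials$pair_id[t],
      outcome = rd$outcome[t],
      params = params
    )
  }
  beliefs
}

#' Model recovery (confusion matrix)
#'
#' For each generating model: simulate a cohort with parameters drawn from
#' the default sampler, fit every candidate model to each subject, and run
#' random-effects model selection; the confusion matrix row is the vector
#' of estimated model frequencies. For `phase = "test"` the learning-phase
#' behavior of every cohort is generated by `learning_model` (the most
#' parsimonious learning model); each generating model then replays that
#' learning history with its own sampled learning parameters to form
#' beliefs and simulates the test choices, and the candidate models are fit
#' to the test phase.
#'
#' @param model_ids Candidate (and generating) model identifiers.
#' @param n_virtual Virtual participants per generating model.
#' @param design The `rl_design`.
#' @param phase `"learning"` or `"test"`.
#' @param seed Master seed.
#' @param n_restarts Optimizer restarts per fit.
#' @param learning_model Model generating the learning history when
#'   `phase = "test"`.
#' @return List of class `confusion_matrix`: `frequencies` (generating x
#'   fitted model-frequency matrix, rows sum to 1), `protected_exceedance`
#'   (same shape), `n_virtual`.
#' @export
run_model_recovery <- function(model_ids = all_model_ids(), n_virtual,
                               design, phase = c("learning", "test"),
                               seed = 1L, n_restarts = 10L,
                               learning_model = "kalman_qu") {
  phase <- match.arg(phase)
  K <- length(model_ids)
  freq <- pxp <- matrix(NA_real_, K, K,
                        dimnames = list(generating = model_ids,
                                        fitted = model_ids))
  for (g in seq_len(K)) {
    gen <- model_ids[g]
    gseed <- seed + 1000L * g
    if (phase == "learning") {
      cohort <- generate_cohort(n_virtual, gen, design, seed = gseed)
      trials <- cohort$trials
    } else {
      trials <- simulate_test_cohort(gen, learning_model, n_virtual, design,
                                     gseed)
    }
    L <- matrix(NA_real_, n_virtual, K, dimnames = list(NULL, model_ids))
    for (m in seq_len(K)) {
      fits <- fit_dataset(model_ids[m], trials, phase, design,
                          n_restarts = n_restarts, seed = gseed + m)
      L[, m] <- fits$log_evidence
    }
    bms <- rfx_bms(L, seed = gseed)
    freq[g, ] <- bms$model_frequencies
    pxp[g, ] <- bms$protected_exceedance
  }
  structure(list(frequencies = freq, protected_exceedance = pxp,
                 n_virtual = n_virtual, phase = phase, seed = seed),
            class = "confusion_matrix")
}

# learning history from `learning_model`, test behavior from `gen_model`
simulate_test_cohort <- function(gen_model, learning_model, n_virtual,
                                 design, seed) {
  base <- generate_cohort(n_virtual, learning_model, design, seed = seed)
  info <- model_info(gen_model)
  set.seed(seed + 7L)
  gen_params <- sample_parameters(gen_model, n_virtual)
  subjects <- unique(base$trials$subject)
  out <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    sub <- base$trials[base$trials$subject == subjects[i], ]
    learn <- sub[sub$phase == "learning", ]
    test_sched <- sub[sub$phase == "test",
                      c("phase", "block", "trial", "pair_id", "pair_type",
                        "condition", "option_left", "option_right")]
    p <- unlist(gen_params[i, , drop = FALSE])
    beliefs <- replay_final_beliefs(gen_model, p, learn, design)
    test <- simulate_test_phase(gen_model, p, beliefs, test_sched,
                                seed = seed + 13L * i)
    test$subject <- subjects[i]
    out[[i]] <- rbind(learn, test[, names(learn)])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "gen_params") <- gen_params
  res
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix>", x$phase, "phase,", x$n_virtual,
      "virtual subjects per generating model\n")
  print(round(x$frequencies, 3))
  invisible(x)
}
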