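# shared fixtures, built in code at test time

main_design <- make_main_design()

# one simulated subject's full trial table (learning + test)
sim_subject_trials <- function(model_id, params_learn, params_test = NULL,
                               design = main_design, seed = 1L,
                               subject = "s1") {
  if (is.null(params_test)) params_test <- params_learn
  lsched <- build_learning_schedule(design, seed = seed)
  tsched <- build_test_schedule(design, lsched, seed = seed)
  sim <- simulate_learning_phase(model_id, params_learn, design, lsched,
                                 seed = seed)
  test <- simulate_test_phase(model_id, params_test, sim$beliefs, tsched,
                              seed = seed + 1L)
  lt <- sim$trials
  lt$pair_type <- NA_character_
  cols <- c("phase", "block", "trial", "pair_id", "pair_type", "condition",
            "option_left", "option_right", "choice", "outcome")
  out <- rbind(lt[, cols], test[, cols])
  out$subject <- subject
  out
}

# hand-rolled three-trial single-pair history for likelihood oracles
toy_history <- function() {
  data.frame(
    subject = "s1", phase = "learning", block = 1L, trial = 1:3,
    pair_id = "b1_p050", condition = "p050",
    option_left = c("b1_p050_G", "b1_p050_B", "b1_p050_G"),
    option_right = c("b1_p050_B", "b1_p050_G", "b1_p050_B"),
    choice = c("b1_p050_G", "b1_p050_G", "b1_p050_B"),
    outcome = c(1, 0, -1),
    stringsAsFactors = FALSE
  )
}
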