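#' Trial-table CSV dialect
#'
#' Datasets are exchanged as UTF-8 CSV files with one row per trial and the
#' columns `subject`, `phase` (`learning`/`test`), `block`, `trial`,
#' `pair_id`, `condition`, `option_left`, `option_right`, `choice`,
#' `outcome`. Test rows carry an empty outcome; the choice must equal one
#' of the two shown options. This mirrors the tabular layout of publicly
#' deposited bandit-task datasets; `col_map` adapts files whose columns are
#' named differently.
#'
#' @name trial-csv
NULL

TRIAL_COLUMNS <- c("subject", "phase", "block", "trial", "pair_id",
                   "condition", "option_left", "option_right", "choice",
                   "outcome")

#' Write a trial table to CSV
#'
#' @param trials Trial table (extra columns such as `pair_type` are
#'   dropped; they are derivable from the option ids).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  miss <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
  utils::write.csv(trials[, TRIAL_COLUMNS], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Read and validate a trial table from CSV
#'
#' Checks the header, that test rows carry no outcome, that learning rows
#' carry one, and that every choice matches one of the two shown options;
#' validation failures report the offending row numbers.
#'
#' @param path CSV file path.
#' @param col_map Optional named character vector mapping this package's
#'   column names to the file's (e.g. `c(subject = "participant_id")`).
#' @return A validated trial table data.frame.
#' @export
read_trials <- function(path, col_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (ours in names(col_map)) {
      theirs <- col_map[[ours]]
      if (!theirs %in% names(df)) stop("mapped column not found: ", theirs)
      names(df)[names(df) == theirs] <- ours
    }
  }
  miss <- setdiff(TRIAL_COLUMNS, names(df))
  if (length(miss) > 0) {
    stop("missing columns: ", paste(miss, collapse = ", "))
  }
  df <- df[, TRIAL_COLUMNS]
  df$outcome <- suppressWarnings(as.numeric(df$outcome))
  bad_phase <- which(!df$phase %in% c("learning", "test"))
  if (length(bad_phase) > 0) {
    stop("invalid phase in rows: ",
         paste(utils::head(bad_phase), collapse = ", "))
  }
  test_out <- which(df$phase == "test" & !is.na(df$outcome))
  if (length(test_out) > 0) {
    stop("test rows with an outcome: ",
         paste(utils::head(test_out), collapse = ", "))
  }
  learn_na <- which(df$phase == "learning" & is.na(df$outcome))
  if (length(learn_na) > 0) {
    stop("learning rows without outcome: ",
         paste(utils::head(learn_na), collapse = ", "))
  }
  bad_choice <- which(df$choice != df$option_left &
                        df$choice != df$option_right)
  if (length(bad_choice) > 0) {
    stop("choice is neither shown option in rows: ",
         paste(utils::head(bad_choice), collapse = ", "))
  }
  df
}
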