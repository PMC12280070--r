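#' Model-agnostic behavioral statistics
#'
#' Learning performance, sampling rates, test-phase selection rates, the
#' across-subject correlations linking them, and the permutation test for a
#' difference between two correlation coefficients. All functions work from
#' the plain trial table (see [read_trials()]); Good/Bad roles and
#' conditions are recovered from the option identifiers.
#'
#' @name behavior-stats
NULL

# relative value ordering of conditions: main "pXXX" ids order by
# p_appetitive; validation pairs order by reward magnitude (10 vs 1)
condition_value <- function(condition) {
  p <- suppressWarnings(as.numeric(sub("^p", "", condition)))
  ifelse(!is.na(p), p / 100,
         ifelse(substr(condition, 1, 1) == "A", 10, 1))
}

#' Learning performance per pair or condition
#'
#' Proportion of trials on which the Good option was chosen, per subject and
#' learning pair; with `by = "condition"` pairs of the same condition
#' (different blocks) are averaged.
#'
#' @param trials Trial table (learning rows are used).
#' @param by `"pair"` (default) or `"condition"`.
#' @return data.frame with `subject`, `condition`, (`block`, `pair_id`,)
#'   `n_trials`, `performance`.
#' @export
learning_performance <- function(trials, by = c("pair", "condition")) {
  by <- match.arg(by)
  learn <- trials[trials$phase == "learning", ]
  if (nrow(learn) == 0) stop("no learning trials")
  left_role <- parse_options(learn$option_left)$role
  good <- ifelse(left_role == "good", learn$option_left, learn$option_right)
  learn$correct <- as.numeric(learn$choice == good)
  # key blocks by the stimulus identity (matches the test-phase parsing),
  # not by presentation position
  learn$block <- parse_options(good)$block
  agg <- stats::aggregate(
    correct ~ subject + condition + block + pair_id, data = learn,
    FUN = function(x) c(mean(x), length(x))
  )
  out <- data.frame(
    subject = agg$subject, condition = agg$condition, block = agg$block,
    pair_id = agg$pair_id,
    n_trials = agg$correct[, 2], performance = agg$correct[, 1],
    stringsAsFactors = FALSE
  )
  if (by == "condition") {
    agg2 <- stats::aggregate(performance ~ subject + condition, data = out,
                             FUN = mean)
    n2 <- stats::aggregate(n_trials ~ subject + condition, data = out,
                           FUN = sum)
    out <- merge(agg2, n2, by = c("subject", "condition"))
    out <- out[, c("subject", "condition", "n_trials", "performance")]
  }
  out[order(out$subject, out$condition), ]
}

#' Sampling rates of Good and Bad options during learning
#'
#' For each learning pair the Good option's sampling rate equals the
#' learning performance and the Bad option's equals its complement — an
#' exact bookkeeping identity under two-option partial feedback, and the
#' model-agnostic handle on estimation-uncertainty (the more an option was
#' sampled, the lower its final uncertainty).
#'
#' @param trials Trial table.
#' @return Long data.frame: `subject`, `condition`, `block`, `pair_id`,
#'   `option`, `role`, `sampling_rate`.
#' @export
sampling_rates <- function(trials) {
  perf <- learning_performance(trials, by = "pair")
  learn <- trials[trials$phase == "learning", ]
  key <- !duplicated(learn[, c("subject", "pair_id")])
  pairs <- learn[key, c("subject", "pair_id", "option_left", "option_right")]
  lr <- parse_options(pairs$option_left)$role
  pairs$good <- ifelse(lr == "good", pairs$option_left, pairs$option_right)
  pairs$bad <- ifelse(lr == "good", pairs$option_right, pairs$option_left)
  m <- merge(perf, pairs, by = c("subject", "pair_id"))
  out <- rbind(
    data.frame(subject = m$subject, condition = m$condition, block = m$block,
               pair_id = m$pair_id, option = m$good, role = "good",
               sampling_rate = m$performance, stringsAsFactors = FALSE),
    data.frame(subject = m$subject, condition = m$condition, block = m$block,
               pair_id = m$pair_id, option = m$bad, role = "bad",
               sampling_rate = 1 - m$performance, stringsAsFactors = FALSE)
  )
  out[order(out$subject, out$pair_id, out$role), ]
}

#' Test-phase selection rates
#'
#' Per subject and unique test pair: the proportion of presentations on
#' which the reference option was chosen. The reference option is the Good
#' option in mixed (good-vs-bad) pairs, and the option from the more
#' valuable condition (larger `p_appetitive`, or larger reward magnitude in
#' the validation designs) in good-vs-good and bad-vs-bad pairs.
#'
#' @param trials Trial table (test rows are used).
#' @return data.frame: `subject`, `pair_id`, `pair_type`, `block`,
#'   `cond_ref`, `cond_other`, `n_trials`, `selection_rate`.
#' @export
test_selection_rates <- function(trials) {
  test <- trials[trials$phase == "test", ]
  if (nrow(test) == 0) stop("no test trials")
  pl <- parse_options(test$option_left)
  pr <- parse_options(test$option_right)
  pair_type <- ifelse(pl$role == pr$role,
                      ifelse(pl$role == "good", "GvG", "BvB"), "GvB")
  left_is_ref <- ifelse(pl$role != pr$role, pl$role == "good",
                        condition_value(pl$condition) >=
                          condition_value(pr$condition))
  ref <- ifelse(left_is_ref, test$option_left, test$option_right)
  test$ref_chosen <- as.numeric(test$choice == ref)
  test$pair_type <- pair_type
  test$cond_ref <- ifelse(left_is_ref, pl$condition, pr$condition)
  test$cond_other <- ifelse(left_is_ref, pr$condition, pl$condition)
  test$block_ref <- ifelse(left_is_ref, pl$block, pr$block)
  agg <- stats::aggregate(
    ref_chosen ~ subject + pair_id + pair_type + cond_ref + cond_other +
      block_ref,
    data = test, FUN = function(x) c(mean(x), length(x))
  )
  out <- data.frame(
    subject = agg$subject, pair_id = agg$pair_id, pair_type = agg$pair_type,
    block = agg$block_ref, cond_ref = agg$cond_ref,
    cond_other = agg$cond_other,
    n_trials = agg$ref_chosen[, 2], selection_rate = agg$ref_chosen[, 1],
    stringsAsFactors = FALSE
  )
  out[order(out$subject, out$pair_type, out$pair_id), ]
}

safe_cor_test <- function(x, y, method) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(estimate = NA_real_, p.value = NA_real_, degenerate = TRUE))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(estimate = unname(ct$estimate), p.value = ct$p.value,
       degenerate = FALSE)
}

#' Correlations between learning performance and test-phase selection
#'
#' The model-agnostic linchpin analysis. For good-vs-bad pairs, each
#' condition's learning performance is correlated (across subjects) with
#' the Good option's selection rate in that condition's test pairs. For
#' good-vs-good and bad-vs-bad pairs, the difference in learning
#' performance between the two conditions of a pairwise comparison
#' (block-matched, then averaged over blocks per subject) is correlated
#' with the selection rate of the option from the more valuable condition.
#' With uncertainty-averse subjects the good-vs-good correlations are
#' positive and the bad-vs-bad correlations negative, because the Bad
#' option of a well-learned condition was rarely sampled and so carries
#' high estimation-uncertainty.
#'
#' @param trials Trial table (learning and test rows).
#' @return List of class `perf_selection_correlations` with
#'   `by_comparison` (one row per pair type x pairwise comparison: Pearson
#'   and Spearman coefficients and p-values) and `pooled` (mean Pearson r
#'   per pair type).
#' @export
perf_selection_correlations <- function(trials) {
  perf_pair <- learning_performance(trials, by = "pair")
  perf_cond <- learning_performance(trials, by = "condition")
  rates <- test_selection_rates(trials)
  subjects <- unique(trials$subject)
  if (length(subjects) < 3) stop("need at least 3 subjects")
  rows <- list()

  gvb <- rates[rates$pair_type == "GvB", ]
  if (nrow(gvb) > 0) {
    m <- stats::aggregate(selection_rate ~ subject + cond_ref, data = gvb,
                          FUN = mean)
    m <- merge(m, perf_cond, by.x = c("subject", "cond_ref"),
               by.y = c("subject", "condition"))
    for (cid in unique(m$cond_ref)) {
      s <- m[m$cond_ref == cid, ]
      pe <- safe_cor_test(s$performance, s$selection_rate, "pearson")
      sp <- safe_cor_test(s$performance, s$selection_rate, "spearman")
      rows[[length(rows) + 1L]] <- data.frame(
        pair_type = "GvB", comparison = cid,
        pearson_r = pe$estimate, pearson_p = pe$p.value,
        spearman_rho = sp$estimate, spearman_p = sp$p.value,
        n = nrow(s), degenerate = pe$degenerate,
        stringsAsFactors = FALSE
      )
    }
  }

  same <- rates[rates$pair_type %in% c("GvG", "BvB"), ]
  if (nrow(same) > 0) {
    # block-matched performance difference between the two conditions
    m <- merge(same, perf_pair,
               by.x = c("subject", "cond_ref", "block"),
               by.y = c("subject", "condition", "block"))
    names(m)[names(m) == "performance"] <- "perf_ref"
    m <- merge(m, perf_pair,
               by.x = c("subject", "cond_other", "block"),
               by.y = c("subject", "condition", "block"))
    names(m)[names(m) == "performance"] <- "perf_other"
    m$dperf <- m$perf_ref - m$perf_other
    m$comparison <- paste(m$cond_ref, m$cond_other, sep = "|")
    agg <- stats::aggregate(cbind(dperf, selection_rate) ~
                              subject + pair_type + comparison,
                            data = m, FUN = mean)
    for (pt in c("GvG", "BvB")) {
      for (cmp in unique(agg$comparison[agg$pair_type == pt])) {
        s <- agg[agg$pair_type == pt & agg$comparison == cmp, ]
        if (nrow(s) < 3) next
        pe <- safe_cor_test(s$dperf, s$selection_rate, "pearson")
        sp <- safe_cor_test(s$dperf, s$selection_rate, "spearman")
        rows[[length(rows) + 1L]] <- data.frame(
          pair_type = pt, comparison = cmp,
          pearson_r = pe$estimate, pearson_p = pe$p.value,
          spearman_rho = sp$estimate, spearman_p = sp$p.value,
          n = nrow(s), degenerate = pe$degenerate,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  by_comparison <- do.call(rbind, rows)
  pooled <- stats::aggregate(pearson_r ~ pair_type, data = by_comparison,
                             FUN = function(x) mean(x, na.rm = TRUE))
  names(pooled)[2] <- "mean_pearson_r"
  structure(list(by_comparison = by_comparison, pooled = pooled),
            class = "perf_selection_correlations")
}

#' @export
print.perf_selection_correlations <- function(x, ...) {
  cat("<perf_selection_correlations>\n")
  print(x$pooled)
  invisible(x)
}

#' Group-level selection bias versus value and entropy differences
#'
#' For every good-vs-good and bad-vs-bad pairwise comparison: the group
#' mean selection rate of the more valuable option, the difference in
#' ground-truth expected value, and the difference in outcome entropy
#' between the two options; plus Pearson and Spearman correlations of the
#' bias with each difference, per pair type, across comparisons.
#'
#' @param trials Trial table.
#' @param design The `rl_design` (supplies ground-truth EV and entropy).
#' @return List with `table` (one row per pair type x comparison) and
#'   `correlations`.
#' @export
pairwise_bias_table <- function(trials, design) {
  rates <- test_selection_rates(trials)
  rates <- rates[rates$pair_type %in% c("GvG", "BvB"), ]
  if (nrow(rates) == 0) stop("no good-vs-good or bad-vs-bad test pairs")
  ot <- design_option_table(design)
  key <- paste(ot$condition, ot$role)
  rates$comparison <- paste(rates$cond_ref, rates$cond_other, sep = "|")
  agg <- stats::aggregate(selection_rate ~ pair_type + comparison +
                            cond_ref + cond_other,
                          data = rates, FUN = mean)
  role <- ifelse(agg$pair_type == "GvG", "good", "bad")
  agg$d_ev <- ot$ev[match(paste(agg$cond_ref, role), key)] -
    ot$ev[match(paste(agg$cond_other, role), key)]
  agg$d_entropy <- ot$entropy[match(paste(agg$cond_ref, role), key)] -
    ot$entropy[match(paste(agg$cond_other, role), key)]
  cors <- list()
  for (pt in unique(agg$pair_type)) {
    s <- agg[agg$pair_type == pt, ]
    for (v in c("d_ev", "d_entropy")) {
      pe <- safe_cor_test(s[[v]], s$selection_rate, "pearson")
      sp <- safe_cor_test(s[[v]], s$selection_rate, "spearman")
      cors[[length(cors) + 1L]] <- data.frame(
        pair_type = pt, against = v,
        pearson_r = pe$estimate, pearson_p = pe$p.value,
        spearman_rho = sp$estimate, spearman_p = sp$p.value,
        n = nrow(s), stringsAsFactors = FALSE
      )
    }
  }
  list(table = agg, correlations = do.call(rbind, cors))
}

#' Standardized effect size against a permutation null
#'
#' `(observed - mean(null)) / sd(null)`.
#'
#' @param observed Observed statistic.
#' @param null Numeric vector: the permutation null distribution.
#' @return Standardized effect size.
#' @examples
#' standardized_effect_size(0.5, c(0.1, 0.1, 0.1) + c(-0.2, 0, 0.2))
#' @export
standardized_effect_size <- function(observed, null) {
  s <- stats::sd(null)
  if (s == 0) stop("null distribution has zero variance")
  (observed - mean(null)) / s
}

#' Permutation test for a difference between two correlations
#'
#' Tests whether a vector of actual per-subject values correlates more
#' strongly with one model's fitted values than with another's:
#' `delta_r = cor(actual, fitted_a) - cor(actual, fitted_b)`. The null
#' distribution is built by shuffling the actual vector `n_perm` times and
#' recomputing `delta_r`; the two-tailed p-value is the proportion of
#' permuted `|delta_r|` exceeding the observed `|delta_r|` (strict
#' inequality, optionally add-one smoothed), the 95% CI spans the null's
#' 2.5 and 97.5 percentiles, and the standardized effect size divides the
#' null-centred observed value by the null's standard deviation.
#'
#' @param actual Numeric vector of observed per-subject values.
#' @param fitted_a,fitted_b Model-fitted values, same length as `actual`.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Seed for the shuffles.
#' @param smooth Add-one smoothing of the p-value (default `FALSE`, the
#'   plain proportion).
#' @return List of class `permutation_result`: `delta_r`, `r_a`, `r_b`,
#'   `p_value`, `ci95`, `ses`, `n_perm`, `null_mean`, `null_sd`.
#' @export
permutation_delta_r <- function(actual, fitted_a, fitted_b, n_perm = 1000L,
                                seed = 1L, smooth = FALSE) {
  stopifnot(length(actual) == length(fitted_a),
            length(actual) == length(fitted_b), n_perm >= 100)
  if (stats::sd(actual) == 0 || stats::sd(fitted_a) == 0 ||
      stats::sd(fitted_b) == 0) {
    stop("constant input vector")
  }
  r_a <- stats::cor(actual, fitted_a)
  r_b <- stats::cor(actual, fitted_b)
  delta <- r_a - r_b
  set.seed(seed)
  null <- replicate(n_perm, {
    perm <- sample(actual)
    stats::cor(perm, fitted_a) - stats::cor(perm, fitted_b)
  })
  # ties count as extreme (for continuous statistics this coincides with
  # the strict inequality almost surely, and it keeps p = 1 when the two
  # fitted vectors are identical)
  p <- if (smooth) {
    (sum(abs(null) >= abs(delta)) + 1) / (n_perm + 1)
  } else {
    mean(abs(null) >= abs(delta))
  }
  null_sd <- stats::sd(null)
  ses <- if (null_sd > 0) {
    standardized_effect_size(delta, null)
  } else if (delta == mean(null)) 0 else NA_real_
  structure(list(
    delta_r = delta, r_a = r_a, r_b = r_b,
    p_value = p,
    ci95 = unname(stats::quantile(null, c(0.025, 0.975))),
    ses = ses,
    n_perm = n_perm, null_mean = mean(null), null_sd = stats::sd(null)
  ), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("<permutation_result> delta_r =", round(x$delta_r, 4),
      " p =", signif(x$p_value, 3),
      " SES =", round(x$ses, 3), "\n")
  invisible(x)
}
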