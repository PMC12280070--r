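#' Random-effects Bayesian model selection
#'
#' Treats the model identity as a random effect across subjects: model
#' frequencies `r` follow a Dirichlet distribution whose posterior is
#' approximated variationally from the subjects x models matrix of log
#' model evidences (Stephan et al. 2009). The exceedance probability of a
#' model is the posterior probability that its frequency is the largest;
#' the protected exceedance probability shrinks it toward uniform by the
#' Bayes omnibus risk (BOR) — the posterior probability that all models are
#' equally frequent — estimated by comparing the variational free energy of
#' the random-effects model against the null (Rigoux et al. 2014).
#'
#' @param log_evidence Numeric matrix, subjects in rows, models in columns
#'   (column names label the models). All entries must be finite.
#' @param n_samples Monte-Carlo draws for the exceedance probabilities.
#' @param seed Seed for the Monte-Carlo draws (made explicit so results are
#'   reproducible).
#' @return List of class `bms` with `alpha` (Dirichlet posterior counts),
#'   `model_frequencies` (posterior mean frequencies, a simplex),
#'   `exceedance`, `protected_exceedance`, `bor`, and `attribution`
#'   (subjects x models posterior model assignment probabilities).
#' @examples
#' L <- cbind(m1 = c(-100, -102, -101), m2 = c(-104, -103, -105))
#' rfx_bms(L)$protected_exceedance
#' @export
rfx_bms <- function(log_evidence, n_samples = 2e5, seed = 1L) {
  L <- as.matrix(log_evidence)
  if (any(!is.finite(L))) stop("non-finite log evidences")
  n <- nrow(L)
  K <- ncol(L)
  models <- colnames(L)
  if (is.null(models)) models <- paste0("m", seq_len(K))
  if (K == 1) {
    return(structure(list(
      alpha = stats::setNames(n + 1, models),
      model_frequencies = stats::setNames(1, models),
      exceedance = stats::setNames(1, models),
      protected_exceedance = stats::setNames(1, models),
      bor = 0,
      attribution = matrix(1, n, 1, dimnames = list(NULL, models))
    ), class = "bms"))
  }
  alpha0 <- rep(1, K)
  alpha <- alpha0 + n / K
  u <- matrix(1 / K, n, K)
  for (it in seq_len(500)) {
    w <- sweep(L, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    w <- w - apply(w, 1, max)
    u_new <- exp(w)
    u_new <- u_new / rowSums(u_new)
    alpha_new <- alpha0 + colSums(u_new)
    if (max(abs(alpha_new - alpha)) < 1e-8) {
      alpha <- alpha_new; u <- u_new
      break
    }
    alpha <- alpha_new; u <- u_new
  }
  freq <- alpha / sum(alpha)

  # variational free energy of the random-effects model
  elog_r <- digamma(alpha) - digamma(sum(alpha))
  kl_dir <- lgamma(sum(alpha)) - sum(lgamma(alpha)) -
    lgamma(sum(alpha0)) + sum(lgamma(alpha0)) +
    sum((alpha - alpha0) * elog_r)
  u_safe <- pmax(u, 1e-300)
  f1 <- sum(u * sweep(L, 2, elog_r, "+")) - sum(u * log(u_safe)) - kl_dir
  # free energy of the null: every model equally frequent
  lse <- apply(L, 1, function(x) {
    m <- max(x); m + log(sum(exp(x - m)))
  })
  f0 <- sum(lse - log(K))
  bor <- 1 / (1 + exp(f1 - f0))

  xp <- dirichlet_exceedance(alpha, n_samples = n_samples, seed = seed)
  pxp <- xp * (1 - bor) + bor / K
  dimnames(u) <- list(rownames(L), models)
  structure(list(
    alpha = stats::setNames(alpha, models),
    model_frequencies = stats::setNames(freq, models),
    exceedance = stats::setNames(xp, models),
    protected_exceedance = stats::setNames(pxp, models),
    bor = bor,
    attribution = u
  ), class = "bms")
}

dirichlet_exceedance <- function(alpha, n_samples = 2e5, seed = 1L) {
  K <- length(alpha)
  if (K == 2) {
    # P(r1 > r2) = P(Beta(a1, a2) > 1/2), exact
    p1 <- 1 - stats::pbeta(0.5, alpha[1], alpha[2])
    return(c(p1, 1 - p1))
  }
  set.seed(seed)
  counts <- integer(K)
  block <- 5e4
  remaining <- n_samples
  while (remaining > 0) {
    m <- min(block, remaining)
    g <- matrix(stats::rgamma(m * K, shape = rep(alpha, each = m)), m, K)
    win <- max.col(g, ties.method = "first")
    counts <- counts + tabulate(win, K)
    remaining <- remaining - m
  }
  counts / n_samples
}

#' @export
print.bms <- function(x, ...) {
  cat("<bms>", length(x$model_frequencies), "models, BOR =",
      signif(x$bor, 3), "\n")
  print(round(rbind(frequency = x$model_frequencies,
                    exceedance = x$exceedance,
                    protected = x$protected_exceedance), 4))
  invisible(x)
}
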