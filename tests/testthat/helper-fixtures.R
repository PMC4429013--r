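# Shared fixtures and independent oracles for the suite.

# Build a moderated fit directly from condition means and a moderated
# variance, bypassing the estimation path, for tests that need exact
# control over estimates and standard errors.
make_fit <- function(means, s2_tilde, df_tilde = 8, d_g = 8,
                     n_c = c(C = 3, A = 3, B = 3, AB = 3)) {
  if (is.null(dim(means))) means <- matrix(means, nrow = 1)
  colnames(means) <- c("C", "A", "B", "AB")
  nfeat <- nrow(means)
  ids <- if (is.null(rownames(means))) sprintf("f%d", seq_len(nfeat)) else rownames(means)
  if (nfeat > 0) rownames(means) <- ids
  s2_tilde <- rep_len(s2_tilde, nfeat)
  structure(
    list(means = means,
         s2_tilde = stats::setNames(s2_tilde, ids),
         df_tilde = df_tilde,
         replicate_counts = n_c,
         degenerate = stats::setNames(rep(FALSE, nfeat), ids),
         feature_ids = ids,
         d_g = d_g,
         s2 = stats::setNames(s2_tilde, ids),
         prior = eb_prior(1, if (nfeat > 0) mean(s2_tilde) else 1),
         n_missing_excluded = 0L),
    class = "moderated_fit"
  )
}

# Independent upper-tail Student-t probability by numeric quadrature of
# the density, used as the oracle against which test p-values are
# checked (never via stats::pt).
t_upper_tail_quadrature <- function(q, df) {
  dens <- function(x) {
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df * pi) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  stats::integrate(dens, lower = q, upper = Inf, rel.tol = 1e-12)$value
}

# Brute-force classical contrast t-test computed from raw data alone:
# condition means by mean(), pooled variance from residual sums of
# squares, one-sided p from the classical t distribution on N - 4 df.
brute_force_contrast_p <- function(y, cond, weights, direction = "greater") {
  conds <- c("C", "A", "B", "AB")
  m <- sapply(conds, function(cc) mean(y[cond == cc]))
  n <- sapply(conds, function(cc) sum(cond == cc))
  ss <- sum(sapply(conds, function(cc) sum((y[cond == cc] - m[[cc]])^2)))
  df <- length(y) - 4
  s2 <- ss / df
  w <- stats::setNames(numeric(4), conds)
  w[names(weights)] <- weights
  est <- sum(w * m)
  se <- sqrt(s2 * sum(w^2 / n))
  tt <- est / se
  if (direction == "greater") stats::pt(tt, df, lower.tail = FALSE) else stats::pt(tt, df)
}

# End-to-end helper: simulate planted blocks with a common noise
# variance, run the full estimation + classification pipeline.
simulate_and_classify <- function(blocks, sigma2, seed,
                                  config = interplay_config(), effect_size = 1) {
  sim <- simulate_dataset(simulation_config(
    pattern_block_sizes = blocks,
    effect_size = effect_size,
    variance_prior = list(d0 = Inf, s0_2 = sigma2),
    seed = seed
  ))
  fit <- fit_condition_means(sim$matrix, sim$design)
  prior <- estimate_eb_prior(fit$s2[!fit$degenerate], fit$d_g)
  mfit <- moderate(fit, prior)
  list(result = classify_dataset(mfit, config), truth = sim$truth,
       fit = mfit, prior = prior, sim = sim)
}

all_pattern_blocks <- function(n_each) {
  nm <- names(enumerate_patterns(interplay_config()))
  stats::setNames(rep(n_each, length(nm)), nm)
}
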