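#' Fit per-condition means and pooled residual variances
#'
#' Fits the saturated cell-means model of the 2x2 design: for every
#' feature the four condition means on the log2 scale, plus the pooled
#' within-condition residual variance
#' \deqn{s_g^2 = \sum_c \sum_i (y_{ci} - \bar y_c)^2 / (N - 4)}
#' on `d_g = N - 4` degrees of freedom (the equal-n formula generalised
#' to unequal replication through the pooled sum of squares). Features
#' containing missing values are excluded with a logged count; features
#' whose replicates are all identical (zero residual variance) are
#' retained but flagged `degenerate` and are never classified, since
#' every downstream test statistic needs a positive standard error.
#'
#' @param matrix An [expression_matrix()].
#' @param design A [design_map()] covering exactly the matrix samples.
#' @return An object of class `interplay_fit`: `means` (features x 4
#'   matrix, columns `C`, `A`, `B`, `AB`), `s2`, `d_g`,
#'   `replicate_counts`, `degenerate` flags, `feature_ids`, and
#'   `n_missing_excluded`.
#' @export
fit_condition_means <- function(matrix, design) {
  stopifnot(inherits(matrix, "expression_matrix"), inherits(design, "design_map"))
  check_samples(matrix, design)

  y <- matrix$values[, names(design$assignment), drop = FALSE]
  complete <- stats::complete.cases(y)
  n_missing <- sum(!complete)
  if (n_missing > 0L) {
    message(n_missing, " feature(s) with missing values excluded from the fit")
    y <- y[complete, , drop = FALSE]
  }
  if (nrow(y) == 0L) stop_input("no complete features left to fit")

  cond <- design$assignment
  n_c <- design$replicate_counts
  means <- vapply(CONDITIONS,
                  function(cc) rowMeans(y[, cond == cc, drop = FALSE]),
                  numeric(nrow(y)))
  if (nrow(y) == 1L) means <- matrix(means, nrow = 1L, dimnames = list(rownames(y), CONDITIONS))

  fitted <- means[, cond, drop = FALSE]
  resid <- y - fitted
  d_g <- sum(n_c) - 4L
  s2 <- rowSums(resid^2) / d_g

  structure(
    list(means = means,
         s2 = s2,
         d_g = d_g,
         replicate_counts = n_c,
         degenerate = s2 == 0,
         feature_ids = rownames(y),
         n_missing_excluded = n_missing),
    class = "interplay_fit"
  )
}

#' Estimate the empirical Bayes variance prior
#'
#' Moment-matching on the log sample variances, as in the standard
#' moderated-statistics approach: writing `z_g = log(s_g^2)`, under a
#' scaled-inverse-chi-square prior with hyperparameters `(d0, s0^2)`
#' the spread of `z_g` in excess of the known sampling component
#' `trigamma(d_g/2)` equals `trigamma(d0/2)`, which is inverted for
#' `d0` by monotone root-finding (tolerance 1e-8, geometrically
#' expanded bracket). The prior scale `s0^2` follows from the mean of
#' `z_g` via the matching digamma terms. When the observed spread does
#' not exceed the pure-sampling expectation the prior is degenerate:
#' `d0 = +Inf` and `s0^2` is the mean observed variance.
#'
#' @param s2 Numeric vector of pooled residual variances. Zero or
#'   non-finite entries (degenerate features) are excluded.
#' @param d_g Residual degrees of freedom of each `s2` entry.
#' @return An object of class `eb_prior` with elements `d0` and `s0_2`.
#' @export
estimate_eb_prior <- function(s2, d_g) {
  usable <- is.finite(s2) & s2 > 0
  x <- s2[usable]
  if (length(x) < 2L) {
    stop_config("need at least 2 positive finite variances to estimate the prior")
  }
  if (d_g < 1L) stop_config("residual df must be >= 1")

  z <- log(x)
  # bias-corrected location of log sigma^2 contributed by chi^2_{d_g} sampling
  e <- z - digamma(d_g / 2) + log(d_g / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(d_g / 2)

  if (evar <= 0) {
    return(structure(list(d0 = Inf, s0_2 = mean(x)), class = "eb_prior"))
  }

  d0 <- 2 * invert_trigamma(evar)
  if (d0 > 1e8) {
    return(structure(list(d0 = Inf, s0_2 = mean(x)), class = "eb_prior"))
  }
  s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  structure(list(d0 = d0, s0_2 = s0_2), class = "eb_prior")
}

#' Construct an empirical Bayes variance prior directly
#'
#' Mostly useful for limits and what-if analyses: `d0 = 0` reproduces
#' the classical unmoderated test, `d0 = Inf` full pooling to `s0_2`.
#'
#' @param d0 Prior degrees of freedom, in `[0, Inf]`.
#' @param s0_2 Prior variance, positive.
#' @return An `eb_prior` object.
#' @export
eb_prior <- function(d0, s0_2) {
  if (!(d0 >= 0)) stop_config("d0 must be >= 0 (possibly Inf)")
  if (!(s0_2 > 0)) stop_config("s0_2 must be > 0")
  structure(list(d0 = d0, s0_2 = s0_2), class = "eb_prior")
}

# Solve trigamma(y) = x for y > 0. trigamma is strictly decreasing, so a
# geometrically expanded bracket plus uniroot suffices.
invert_trigamma <- function(x, tol = 1e-8) {
  stopifnot(x > 0)
  lo <- 0.5
  while (trigamma(lo) < x) lo <- lo / 2
  hi <- lo
  while (trigamma(hi) > x) hi <- hi * 2
  if (hi > 1e9) return(Inf)
  stats::uniroot(function(y) trigamma(y) - x, lower = lo, upper = hi,
                 tol = tol)$root
}

#' Shrink per-feature variances toward the prior
#'
#' Posterior (moderated) variance
#' \deqn{\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g)}
#' on `d0 + d_g` moderated degrees of freedom. The limits recover the
#' classical test (`d0 = 0`) and full pooling with normal tails
#' (`d0 = +Inf`).
#'
#' @param fit An [fit_condition_means()] result.
#' @param prior An [estimate_eb_prior()] result.
#' @return An object of class `moderated_fit` carrying the condition
#'   means, `s2_tilde`, `df_tilde`, replicate counts, degenerate flags
#'   and the prior used.
#' @export
moderate <- function(fit, prior) {
  stopifnot(inherits(fit, c("interplay_fit", "moderated_fit")),
            inherits(prior, "eb_prior"))
  if (!(prior$d0 >= 0) || !(prior$s0_2 > 0)) stop_config("invalid prior")
  if (is.infinite(prior$d0)) {
    s2_tilde <- rep_len(prior$s0_2, length(fit$s2))
    df_tilde <- Inf
  } else {
    s2_tilde <- (prior$d0 * prior$s0_2 + fit$d_g * fit$s2) / (prior$d0 + fit$d_g)
    df_tilde <- prior$d0 + fit$d_g
  }
  names(s2_tilde) <- fit$feature_ids
  structure(
    list(means = fit$means,
         s2_tilde = s2_tilde,
         df_tilde = df_tilde,
         replicate_counts = fit$replicate_counts,
         degenerate = fit$degenerate,
         feature_ids = fit$feature_ids,
         d_g = fit$d_g,
         s2 = fit$s2,
         prior = prior,
         n_missing_excluded = fit$n_missing_excluded),
    class = "moderated_fit"
  )
}
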