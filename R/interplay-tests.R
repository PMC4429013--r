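#' Define a linear contrast over the four conditions
#'
#' @param weights Named numeric vector over a subset of `C`, `A`, `B`,
#'   `AB`; must sum to zero with at least two nonzero entries.
#' @param label Human-readable label.
#' @return An object of class `interplay_contrast`.
#' @export
contrast <- function(weights, label = NULL) {
  unknown <- setdiff(names(weights), CONDITIONS)
  if (length(unknown)) stop_config("unknown condition(s) in contrast: ",
                                   paste(unknown, collapse = ", "))
  w <- stats::setNames(numeric(4L), CONDITIONS)
  w[names(weights)] <- weights
  if (abs(sum(w)) > 1e-12) stop_config("contrast weights must sum to zero")
  if (sum(w != 0) < 2L) stop_config("contrast needs at least two nonzero weights")
  structure(list(weights = w, label = label %||% paste(names(weights), collapse = ",")),
            class = "interplay_contrast")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The four canonical contrasts of the interplay framework
#'
#' `cA` and `cB` are the single-constituent effects A-C and B-C, `cInt`
#' the interaction AB-A-B+C (combined effect minus the sum of single
#' effects), and `cAB` the combined effect AB-C.
#'
#' @return Named list of [contrast()] objects.
#' @export
standard_contrasts <- function() {
  list(
    cA   = contrast(c(A = 1, C = -1), "A-C"),
    cB   = contrast(c(B = 1, C = -1), "B-C"),
    cInt = contrast(c(AB = 1, A = -1, B = -1, C = 1), "AB-A-B+C"),
    cAB  = contrast(c(AB = 1, C = -1), "AB-C")
  )
}

# Vectorised estimate and standard error of a contrast across all
# features of a moderated fit: psi_hat = sum w_c ybar_c,
# SE = s_tilde * sqrt(sum w_c^2 / n_c).
contrast_estimates <- function(fit, contrast) {
  w <- contrast$weights
  est <- drop(fit$means[, CONDITIONS, drop = FALSE] %*% w)
  se <- sqrt(fit$s2_tilde * sum(w^2 / fit$replicate_counts[CONDITIONS]))
  list(estimate = est, se = se)
}

#' One-sided moderated contrast test for a single feature
#'
#' Tests H0: psi = 0 against H1: psi > 0 (`direction = "greater"`) or
#' psi < 0 (`"less"`) with the moderated t statistic
#' `t = psi_hat / SE(psi_hat)` on the moderated degrees of freedom.
#' Degenerate features (zero residual variance) yield a flagged result
#' with an undefined p-value, treated as 1 downstream.
#'
#' @param fit A [moderate()]d fit.
#' @param feature Feature id or index.
#' @param c A [contrast()].
#' @param direction `"greater"` or `"less"`.
#' @return A `test_result` list: `estimate`, `se`, `statistic`, `df`,
#'   `p`, `direction`, `degenerate`.
#' @export
contrast_test <- function(fit, feature, c, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  i <- resolve_feature(fit, feature)
  ce <- contrast_estimates_one(fit, i, c)
  if (fit$degenerate[i]) {
    return(structure(list(estimate = ce$estimate, se = ce$se, statistic = NA_real_,
                          df = fit$df_tilde, p = NA_real_, direction = direction,
                          degenerate = TRUE),
                     class = "test_result"))
  }
  tstat <- ce$estimate / ce$se
  p <- if (direction == "greater") pt_upper(tstat, fit$df_tilde) else pt_upper(-tstat, fit$df_tilde)
  structure(list(estimate = ce$estimate, se = ce$se, statistic = tstat,
                 df = fit$df_tilde, p = p, direction = direction,
                 degenerate = FALSE),
            class = "test_result")
}

resolve_feature <- function(fit, feature) {
  i <- if (is.character(feature)) match(feature, fit$feature_ids) else as.integer(feature)
  if (is.na(i) || i < 1L || i > length(fit$feature_ids)) {
    stop_input("unknown feature: ", feature)
  }
  i
}

contrast_estimates_one <- function(fit, i, c) {
  w <- c$weights
  list(estimate = sum(fit$means[i, CONDITIONS] * w),
       se = sqrt(fit$s2_tilde[[i]] * sum(w^2 / fit$replicate_counts[CONDITIONS])))
}

#' Tolerance specification for a near-equality (TOST) test
#'
#' The equivalence interval is the symmetric `[-eps, eps]` on the log2
#' scale.
#'
#' @param eps Positive tolerance limit.
#' @return A `tost_spec` object.
#' @export
tost_spec <- function(eps) {
  if (!is.numeric(eps) || length(eps) != 1L || !(eps > 0)) {
    stop_config("tolerance limit eps must be a single positive number")
  }
  structure(list(eps = eps), class = "tost_spec")
}

#' Two-one-sided-tests equivalence test for a single feature
#'
#' Tests whether the contrast lies inside `[-eps, eps]` via the pair of
#' statistics `U_upper = (eps - psi_hat)/SE` and
#' `U_lower = (psi_hat + eps)/SE`, each referred to the upper tail of
#' Student's t on the moderated degrees of freedom. Near-equality is
#' accepted when both exceed `t_{df, 1-alpha}`, equivalently when the
#' TOST p-value `max(p_upper, p_lower)` is below `alpha`.
#'
#' @inheritParams contrast_test
#' @param spec A [tost_spec()].
#' @param alpha Significance level used to report the critical value.
#' @return A `tost_result` list: `u_upper`, `u_lower`, `p_upper`,
#'   `p_lower`, `p`, `critical`, `accepted`, `degenerate`.
#' @export
tost <- function(fit, feature, c, spec, alpha = 0.05) {
  stopifnot(inherits(spec, "tost_spec"))
  i <- resolve_feature(fit, feature)
  ce <- contrast_estimates_one(fit, i, c)
  if (fit$degenerate[i]) {
    return(structure(list(u_upper = NA_real_, u_lower = NA_real_,
                          p_upper = NA_real_, p_lower = NA_real_, p = NA_real_,
                          critical = qt_crit(alpha, fit$df_tilde),
                          accepted = FALSE, degenerate = TRUE),
                     class = "tost_result"))
  }
  u_upper <- (spec$eps - ce$estimate) / ce$se
  u_lower <- (ce$estimate + spec$eps) / ce$se
  p_upper <- pt_upper(u_upper, fit$df_tilde)
  p_lower <- pt_upper(u_lower, fit$df_tilde)
  p <- max(p_upper, p_lower)
  structure(list(u_upper = u_upper, u_lower = u_lower,
                 p_upper = p_upper, p_lower = p_lower, p = p,
                 critical = qt_crit(alpha, fit$df_tilde),
                 accepted = p < alpha, degenerate = FALSE),
            class = "tost_result")
}

#' Intersection-union compounding of partial tests
#'
#' The compound null (at least one partial relation fails) is rejected
#' in favour of the compound alternative (all relations hold) exactly
#' when every partial p-value is below `alpha`; the compound p-value is
#' the maximum of the partial p-values. Undefined (NA) partials count
#' as 1.
#'
#' @param partials Numeric vector of partial p-values (length >= 1).
#' @param alpha Significance level.
#' @return List with `accepted` (logical) and `p_compound`.
#' @export
compound_iut <- function(partials, alpha = 0.05) {
  if (length(partials) == 0L) stop_config("compound test needs at least one partial p-value")
  partials[is.na(partials)] <- 1
  p_compound <- max(partials)
  list(accepted = p_compound < alpha, p_compound = p_compound)
}

# Vectorised partial p-values for all features at once: one column per
# (contrast, kind) pair actually used by the taxonomy. Degenerate
# features get NA rows.
partial_p_matrix <- function(fit, eps) {
  cs <- standard_contrasts()
  df <- fit$df_tilde
  out <- list()
  est <- list()
  for (nm in names(cs)) {
    ce <- contrast_estimates(fit, cs[[nm]])
    est[[nm]] <- ce$estimate
    tstat <- ce$estimate / ce$se
    out[[paste0(nm, ".greater")]] <- pt_upper(tstat, df)
    out[[paste0(nm, ".less")]] <- pt_upper(-tstat, df)
    if (nm != "cAB") {
      p_up <- pt_upper((eps - ce$estimate) / ce$se, df)
      p_lo <- pt_upper((ce$estimate + eps) / ce$se, df)
      out[[paste0(nm, ".near_equal")]] <- pmax(p_up, p_lo)
    }
  }
  p <- do.call(cbind, out)
  p[fit$degenerate, ] <- NA_real_
  list(p = p, estimates = do.call(cbind, est))
}
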