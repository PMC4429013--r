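PATTERN_NAMES <- c("synergism", "additive", "antagonism",
                   "potentiation_by_A", "redundance_of_A", "reductive_by_A",
                   "potentiation_by_B", "redundance_of_B", "reductive_by_B",
                   "emergent")

#' Analysis configuration
#'
#' @param alpha Significance level for every partial test (default
#'   0.05). `alpha = 0` is allowed as a degenerate setting under which
#'   nothing is ever accepted.
#' @param eps Tolerance limit of the symmetric near-equality interval
#'   `[-eps, eps]`, log2 units (default 0.15).
#' @param require_ab_effective Append an explicit one-sided AB-vs-C
#'   partial to every pattern, making the premise "the combined
#'   manipulation is effective" a tested component (default `TRUE`).
#' @param fdr Apply Benjamini-Hochberg adjustment to the compound
#'   p-values across features, separately within each pattern, before
#'   thresholding (default `FALSE`; the framework's canonical report is
#'   per-feature level-alpha).
#' @return An `interplay_config` object.
#' @export
interplay_config <- function(alpha = 0.05, eps = 0.15,
                             require_ab_effective = TRUE, fdr = FALSE) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha >= 0.5) {
    stop_config("alpha must lie in [0, 0.5)")
  }
  if (!is.numeric(eps) || length(eps) != 1L || !(eps > 0)) {
    stop_config("eps must be a single positive number")
  }
  structure(list(alpha = alpha, eps = eps,
                 require_ab_effective = isTRUE(require_ab_effective),
                 fdr = isTRUE(fdr)),
            class = "interplay_config")
}

#' Enumerate the taxonomy of interplay patterns
#'
#' The taxonomy crosses the primary comparison -- combined effect
#' (AB-C) smaller than / near-equal to / larger than the sum of single
#' effects (A-C)+(B-C), i.e. the sign of the interaction contrast --
#' with the effectiveness of each single constituent. Of the 12 cells,
#' the two with both singles ineffective and a non-positive interaction
#' are logically impossible given an effective combination, leaving 10
#' forms. Each form exists in an up- and a down-regulated variant; the
#' down variant mirrors every strict inequality while near-equality
#' components are direction-free.
#'
#' @param config An [interplay_config()]; controls whether the AB-vs-C
#'   effectiveness partial is appended.
#' @return List of `pattern_spec` objects (20 when both directions),
#'   each with `name`, `direction` and `partials` (list of
#'   `(contrast, kind)` pairs, kinds `greater`, `less`, `near_equal`).
#' @export
enumerate_patterns <- function(config = interplay_config()) {
  base <- list(
    synergism         = list(c("cA", "greater"), c("cB", "greater"), c("cInt", "greater")),
    additive          = list(c("cA", "greater"), c("cB", "greater"), c("cInt", "near_equal")),
    antagonism        = list(c("cA", "greater"), c("cB", "greater"), c("cInt", "less")),
    potentiation_by_A = list(c("cA", "near_equal"), c("cB", "greater"), c("cInt", "greater")),
    redundance_of_A   = list(c("cA", "near_equal"), c("cB", "greater"), c("cInt", "near_equal")),
    reductive_by_A    = list(c("cA", "near_equal"), c("cB", "greater"), c("cInt", "less")),
    potentiation_by_B = list(c("cB", "near_equal"), c("cA", "greater"), c("cInt", "greater")),
    redundance_of_B   = list(c("cB", "near_equal"), c("cA", "greater"), c("cInt", "near_equal")),
    reductive_by_B    = list(c("cB", "near_equal"), c("cA", "greater"), c("cInt", "less")),
    emergent          = list(c("cA", "near_equal"), c("cB", "near_equal"), c("cInt", "greater"))
  )
  specs <- list()
  for (nm in names(base)) {
    for (dir in c("up", "down")) {
      partials <- lapply(base[[nm]], function(pp) {
        kind <- pp[2L]
        if (dir == "down" && kind != "near_equal") {
          kind <- if (kind == "greater") "less" else "greater"
        }
        list(contrast = pp[1L], kind = kind)
      })
      if (config$require_ab_effective) {
        partials <- c(partials, list(list(contrast = "cAB",
                                          kind = if (dir == "up") "greater" else "less")))
      }
      specs[[paste(nm, dir, sep = "_")]] <-
        structure(list(name = nm, direction = dir, partials = partials),
                  class = "pattern_spec")
    }
  }
  specs
}

# Compound p-values for every feature x pattern in one pass.
compound_p_matrix <- function(fit, config) {
  specs <- enumerate_patterns(config)
  pp <- partial_p_matrix(fit, config$eps)
  comp <- matrix(NA_real_, nrow = length(fit$feature_ids), ncol = length(specs),
                 dimnames = list(fit$feature_ids, names(specs)))
  for (j in seq_along(specs)) {
    cols <- vapply(specs[[j]]$partials,
                   function(p) paste(p$contrast, p$kind, sep = "."), character(1))
    comp[, j] <- do.call(pmax, lapply(cols, function(cc) pp$p[, cc]))
  }
  list(compound = comp, estimates = pp$estimates, specs = specs)
}

label_from_accepted <- function(accepted_names) {
  if (length(accepted_names) == 0L) "none"
  else if (length(accepted_names) == 1L) accepted_names
  else "ambiguous"
}

#' Classify a single feature
#'
#' Runs every partial test of every direction-specific pattern at level
#' `alpha`, compounds them by the intersection-union rule and reports
#' the accepted pattern(s). A feature is labelled by its unique
#' accepted pattern, `"none"` when no pattern is accepted,
#' `"ambiguous"` when several are (reported, never resolved by
#' priority), or `"degenerate"` for zero-variance features which are
#' not tested at all.
#'
#' @param fit A [moderate()]d fit.
#' @param feature Feature id or index.
#' @param config An [interplay_config()].
#' @return An `assignment` list: `feature_id`, `p_compound` (named, 20
#'   values), `accepted`, `label`, `direction`, `status`.
#' @export
classify_feature <- function(fit, feature, config = interplay_config()) {
  i <- resolve_feature(fit, feature)
  sub <- subset_fit(fit, i)
  if (fit$degenerate[i]) {
    return(structure(list(feature_id = fit$feature_ids[i],
                          p_compound = NULL, accepted = character(0),
                          label = "degenerate", direction = NA_character_,
                          status = "degenerate"),
                     class = "assignment"))
  }
  cm <- compound_p_matrix(sub, config)
  p <- cm$compound[1L, ]
  accepted <- names(p)[p < config$alpha]
  label <- label_from_accepted(accepted)
  structure(list(feature_id = fit$feature_ids[i],
                 p_compound = p,
                 accepted = accepted,
                 label = label,
                 direction = if (length(accepted) == 1L) sub("^.*_(up|down)$", "\\1", accepted) else NA_character_,
                 status = "ok"),
            class = "assignment")
}

subset_fit <- function(fit, idx) {
  structure(
    list(means = fit$means[idx, , drop = FALSE],
         s2_tilde = fit$s2_tilde[idx],
         df_tilde = fit$df_tilde,
         replicate_counts = fit$replicate_counts,
         degenerate = fit$degenerate[idx],
         feature_ids = fit$feature_ids[idx],
         d_g = fit$d_g, s2 = fit$s2[idx], prior = fit$prior),
    class = "moderated_fit"
  )
}

#' Classify every feature of a dataset
#'
#' Vectorised classification of all features, plus a summary table of
#' counts per form and direction (rows: the ten forms; columns: UP and
#' DOWN counts) and the total number of features displaying any form.
#'
#' @param fit A [moderate()]d fit.
#' @param config An [interplay_config()].
#' @return List of class `interplay_result` with elements
#'   `assignments` (data.frame: feature id, label, direction, compound
#'   p of the accepted pattern, all 20 compound p-values, the four
#'   contrast estimates, status), `summary` (counts data.frame),
#'   `n_classified`, `n_ambiguous`, `n_degenerate`, `config`.
#' @export
classify_dataset <- function(fit, config = interplay_config()) {
  nfeat <- length(fit$feature_ids)
  if (nfeat == 0L) {
    empty_summary <- data.frame(pattern = PATTERN_NAMES, up = 0L, down = 0L)
    return(structure(list(assignments = data.frame(), summary = empty_summary,
                          n_classified = 0L, n_ambiguous = 0L, n_degenerate = 0L,
                          config = config),
                     class = "interplay_result"))
  }
  cm <- compound_p_matrix(fit, config)
  comp <- cm$compound
  if (config$fdr) {
    comp <- apply(comp, 2L, function(p) stats::p.adjust(p, method = "BH"))
    if (is.null(dim(comp))) comp <- matrix(comp, nrow = nfeat,
                                           dimnames = dimnames(cm$compound))
  }
  acc <- !is.na(comp) & comp < config$alpha
  n_acc <- rowSums(acc)

  label <- rep_len("none", nfeat)
  direction <- rep_len(NA_character_, nfeat)
  p_accepted <- rep_len(NA_real_, nfeat)
  uniq <- which(n_acc == 1L)
  if (length(uniq)) {
    jj <- max.col(acc[uniq, , drop = FALSE], ties.method = "first")
    label[uniq] <- colnames(acc)[jj]
    direction[uniq] <- sub("^.*_(up|down)$", "\\1", label[uniq])
    p_accepted[uniq] <- comp[cbind(uniq, jj)]
  }
  label[n_acc > 1L] <- "ambiguous"
  label[fit$degenerate] <- "degenerate"

  status <- rep_len("ok", nfeat)
  status[fit$degenerate] <- "degenerate"

  assignments <- data.frame(
    feature_id = fit$feature_ids,
    label = label,
    direction = direction,
    p_accepted = p_accepted,
    stringsAsFactors = FALSE
  )
  assignments <- cbind(assignments,
                       as.data.frame(comp),
                       as.data.frame(cm$estimates),
                       status = status)
  rownames(assignments) <- NULL

  counts <- table(factor(label[n_acc == 1L & !fit$degenerate],
                         levels = names(enumerate_patterns(config))))
  summary <- data.frame(
    pattern = PATTERN_NAMES,
    up = as.integer(counts[paste0(PATTERN_NAMES, "_up")]),
    down = as.integer(counts[paste0(PATTERN_NAMES, "_down")])
  )
  structure(
    list(assignments = assignments,
         summary = summary,
         n_classified = sum(n_acc == 1L & !fit$degenerate),
         n_ambiguous = sum(label == "ambiguous"),
         n_degenerate = sum(fit$degenerate),
         config = config),
    class = "interplay_result"
  )
}

#' @export
print.interplay_result <- function(x, ...) {
  cat("2x2 interplay classification\n")
  cat(sprintf("  features: %d   classified: %d   ambiguous: %d   degenerate: %d\n",
              nrow(x$assignments), x$n_classified, x$n_ambiguous, x$n_degenerate))
  cat(sprintf("  alpha = %g, eps = %g, require_ab_effective = %s, fdr = %s\n",
              x$config$alpha, x$config$eps, x$config$require_ab_effective, x$config$fdr))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
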