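#' Configuration for the synthetic 2x2 expression generator
#'
#' Defaults mirror the kind of dataset the classifier targets: three
#' replicates per condition, Gaussian log2-scale noise with per-feature
#' variances drawn from a scaled-inverse-chi-square prior
#' (`d0_true = 4`, `s0_2_true = 0.04`), and planted effects of 1 log2
#' unit for strict-inequality components.
#'
#' @param pattern_block_sizes Named integer vector of feature counts
#'   per direction-specific pattern, names like `"synergism_up"`;
#'   a `"null"` entry plants all-equal means.
#' @param n_per_condition Replicates per condition (default 3).
#' @param effect_size Planted magnitude of strict-inequality
#'   components, log2 units (default 1).
#' @param interaction_size Planted magnitude of the interaction for
#'   super/sub-additive patterns (default `effect_size`). Reductive
#'   patterns always use `effect_size / 2` so that the combined effect
#'   stays strictly on the pattern's side of the control, as the
#'   taxonomy premise requires.
#' @param null_fraction Convenience alternative to a `"null"` block:
#'   fraction of the final dataset made of null features (default 0).
#' @param variance_prior List with `d0` and `s0_2`; `d0 = Inf` plants a
#'   common variance `s0_2` for every feature.
#' @param seed Mandatory integer seed; the generator is a pure function
#'   of its configuration.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(pattern_block_sizes,
                              n_per_condition = 3L,
                              effect_size = 1,
                              interaction_size = effect_size,
                              null_fraction = 0,
                              variance_prior = list(d0 = 4, s0_2 = 0.04),
                              seed) {
  if (missing(seed) || !is.numeric(seed)) stop_config("an integer seed is required")
  valid <- c(names(enumerate_patterns(interplay_config())), "null")
  bad <- setdiff(names(pattern_block_sizes), valid)
  if (length(bad)) stop_config("unknown pattern block(s): ", paste(bad, collapse = ", "))
  if (any(pattern_block_sizes < 0)) stop_config("block sizes must be >= 0")
  if (!(effect_size > 0)) stop_config("effect_size must be > 0")
  if (null_fraction < 0 || null_fraction >= 1) stop_config("null_fraction must be in [0, 1)")
  if (null_fraction > 0) {
    extra <- round(null_fraction / (1 - null_fraction) * sum(pattern_block_sizes))
    cur <- pattern_block_sizes["null"]
    pattern_block_sizes["null"] <- extra + if (is.na(cur)) 0 else cur
  }
  if (sum(pattern_block_sizes) == 0) stop_config("zero total features requested")
  structure(list(pattern_block_sizes = pattern_block_sizes,
                 n_per_condition = as.integer(n_per_condition),
                 effect_size = effect_size,
                 interaction_size = interaction_size,
                 variance_prior = variance_prior,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' True condition means of a planted pattern
#'
#' Near-equality components are planted at exactly 0 (the interior of
#' the tolerance interval), strict components at `effect_size`, and the
#' interaction so that the pattern's primary comparison holds. Down
#' patterns are the negation of their up counterparts.
#'
#' @param name Base pattern name (see [enumerate_patterns()]), or
#'   `"null"`.
#' @param direction `"up"` or `"down"` (ignored for `"null"`).
#' @param effect_size,interaction_size Magnitudes, log2 units.
#' @return Named numeric of length 4 (`C`, `A`, `B`, `AB`).
#' @export
pattern_true_means <- function(name, direction = "up",
                               effect_size = 1, interaction_size = effect_size) {
  if (name == "null") return(stats::setNames(numeric(4L), CONDITIONS))
  e <- effect_size
  g <- interaction_size
  m <- switch(name,
    synergism         = c(0, e, e, 2 * e + g),
    additive          = c(0, e, e, 2 * e),
    antagonism        = c(0, e, e, 2 * e - g),
    potentiation_by_A = c(0, 0, e, e + g),
    redundance_of_A   = c(0, 0, e, e),
    reductive_by_A    = c(0, 0, e, e - e / 2),
    potentiation_by_B = c(0, e, 0, e + g),
    redundance_of_B   = c(0, e, 0, e),
    reductive_by_B    = c(0, e, 0, e - e / 2),
    emergent          = c(0, 0, 0, g),
    stop_config("unknown pattern: ", name)
  )
  if (name == "antagonism" && !(2 * e - g > 0)) {
    stop_config("antagonism needs interaction_size < 2*effect_size to keep AB effective")
  }
  if (name %in% c("potentiation_by_A", "potentiation_by_B", "emergent") && !(g > 0)) {
    stop_config("super-additive patterns need interaction_size > 0")
  }
  if (direction == "down") m <- -m
  stats::setNames(m, CONDITIONS)
}

#' Simulate a 2x2 factorial log2 expression dataset with planted interplay
#'
#' For each feature a variance is drawn from the scaled-inverse-chi-
#' square prior (`sigma_g^2 = d0 * s0_2 / chisq(d0)`; a common variance
#' when `d0 = Inf`) and observations are i.i.d. Normal around the
#' planted condition means. Bit-identical output for identical
#' configurations.
#'
#' @param config A [simulation_config()].
#' @return List with `matrix` ([expression_matrix()]), `design`
#'   ([design_map()]) and `truth` (data.frame of class
#'   `synthetic_truth`: feature id, planted pattern, direction, the
#'   four true means, true variance).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  blocks <- config$pattern_block_sizes
  blocks <- blocks[blocks > 0]
  n <- config$n_per_condition
  nfeat <- sum(blocks)

  truth <- do.call(rbind, lapply(names(blocks), function(bk) {
    if (bk == "null") {
      name <- "null"; dir <- NA_character_
    } else {
      name <- sub("_(up|down)$", "", bk)
      dir <- sub("^.*_(up|down)$", "\\1", bk)
    }
    mu <- pattern_true_means(name, if (is.na(dir)) "up" else dir,
                             config$effect_size, config$interaction_size)
    data.frame(pattern = name, direction = dir,
               mu_C = mu[["C"]], mu_A = mu[["A"]], mu_B = mu[["B"]], mu_AB = mu[["AB"]],
               count = blocks[[bk]], stringsAsFactors = FALSE)
  }))
  truth <- truth[rep(seq_len(nrow(truth)), truth$count), setdiff(names(truth), "count")]
  truth$feature_id <- sprintf("feat_%05d", seq_len(nfeat))
  rownames(truth) <- NULL

  d0 <- config$variance_prior$d0
  s0_2 <- config$variance_prior$s0_2
  sigma2 <- if (is.finite(d0)) d0 * s0_2 / stats::rchisq(nfeat, df = d0) else rep_len(s0_2, nfeat)
  truth$sigma2 <- sigma2

  cond <- rep(CONDITIONS, each = n)
  sample_ids <- paste0(cond, "_", rep(seq_len(n), times = 4L))
  mu <- as.matrix(truth[, c("mu_C", "mu_A", "mu_B", "mu_AB")])
  colnames(mu) <- CONDITIONS
  noise <- matrix(stats::rnorm(nfeat * 4L * n, sd = sqrt(sigma2)), nrow = nfeat)
  values <- mu[, cond, drop = FALSE] + noise
  dimnames(values) <- list(truth$feature_id, sample_ids)

  truth <- truth[, c("feature_id", "pattern", "direction",
                     "mu_C", "mu_A", "mu_B", "mu_AB", "sigma2")]
  class(truth) <- c("synthetic_truth", "data.frame")
  list(matrix = expression_matrix(values),
       design = design_map(stats::setNames(cond, sample_ids)),
       truth = truth)
}

#' Score recovered labels against the planted truth
#'
#' Builds the 21 x 21 confusion matrix (20 direction-specific patterns
#' plus `none`; ambiguous and degenerate assignments count as not
#' recovered) and per-pattern sensitivity and specificity.
#'
#' @param truth The `truth` component of [simulate_dataset()].
#' @param assignments The `assignments` data.frame of
#'   [classify_dataset()] (or an `interplay_result`).
#' @return List with `confusion` (matrix), `sensitivity` (unique-label
#'   recovery), `sensitivity_accepted` (planted pattern member of the
#'   accepted set, counting ambiguous co-acceptances as recovered;
#'   `NA` when the per-pattern p-value columns are absent),
#'   `specificity` (named vectors over the 20 patterns), `accuracy`.
#' @export
evaluate_recovery <- function(truth, assignments, alpha = 0.05) {
  if (inherits(assignments, "interplay_result")) {
    alpha <- assignments$config$alpha
    assignments <- assignments$assignments
  }
  if (!setequal(truth$feature_id, assignments$feature_id)) {
    stop_input("truth and assignments cover different feature sets")
  }
  assignments <- assignments[match(truth$feature_id, assignments$feature_id), ]
  patterns <- names(enumerate_patterns(interplay_config()))
  lev <- c(patterns, "none")

  truth_lab <- ifelse(truth$pattern == "null", "none",
                      paste(truth$pattern, truth$direction, sep = "_"))
  assigned <- ifelse(assignments$label %in% patterns, assignments$label, "none")

  confusion <- table(truth = factor(truth_lab, levels = lev),
                     assigned = factor(assigned, levels = lev))
  sens <- vapply(patterns, function(p) {
    in_p <- truth_lab == p
    if (!any(in_p)) return(NA_real_)
    mean(assigned[in_p] == p)
  }, numeric(1))
  spec <- vapply(patterns, function(p) {
    out_p <- truth_lab != p
    if (!any(out_p)) return(NA_real_)
    mean(assigned[out_p] != p)
  }, numeric(1))
  sens_acc <- vapply(patterns, function(p) {
    in_p <- truth_lab == p
    pcol <- if (p %in% names(assignments)) p else paste0("p.", p)
    if (!any(in_p) || !(pcol %in% names(assignments))) return(NA_real_)
    mean(assignments[[pcol]][in_p] < alpha, na.rm = FALSE)
  }, numeric(1))
  list(confusion = unclass(confusion),
       sensitivity = sens,
       sensitivity_accepted = sens_acc,
       specificity = spec,
       accuracy = mean(assigned == truth_lab))
}
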