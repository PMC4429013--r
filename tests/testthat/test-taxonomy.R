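partial_key <- function(spec) {
  paste(vapply(spec$partials, function(p) paste(p$contrast, p$kind, sep = ":"),
               character(1)), collapse = ";")
}

test_that("the taxonomy holds ten forms in two directions with two impossible cells", {
  specs <- enumerate_patterns(interplay_config())
  expect_length(specs, 20L)
  expect_setequal(unique(vapply(specs, `[[`, "", "name")),
                  c("synergism", "additive", "antagonism",
                    "potentiation_by_A", "redundance_of_A", "reductive_by_A",
                    "potentiation_by_B", "redundance_of_B", "reductive_by_B",
                    "emergent"))

  # all 12 crossings of primary (interaction sign) x secondary (which
  # singles are effective): exactly the two with both singles inert and
  # a non-positive interaction are absent
  up <- specs[vapply(specs, `[[`, "", "direction") == "up"]
  core <- vapply(up, function(s) {
    pp <- s$partials[vapply(s$partials, `[[`, "", "contrast") != "cAB"]
    paste(sort(vapply(pp, function(p) paste(p$contrast, p$kind, sep = ":"),
                      character(1))), collapse = ";")
  }, character(1))
  secondary <- c("cA:greater;cB:greater", "cA:near_equal;cB:greater",
                 "cA:greater;cB:near_equal", "cA:near_equal;cB:near_equal")
  primary <- c("cInt:greater", "cInt:near_equal", "cInt:less")
  crossings <- as.vector(outer(secondary, primary, function(s, p)
    vapply(seq_along(s), function(i) paste(sort(c(strsplit(s[i], ";")[[1]], p[i])),
                                           collapse = ";"), character(1))))
  present <- crossings %in% core
  expect_equal(sum(present), 10L)
  impossible <- crossings[!present]
  expect_setequal(impossible, c(
    paste(sort(c("cA:near_equal", "cB:near_equal", "cInt:near_equal")), collapse = ";"),
    paste(sort(c("cA:near_equal", "cB:near_equal", "cInt:less")), collapse = ";")
  ))
})

test_that("pattern definitions encode the intended partial hypotheses", {
  specs <- enumerate_patterns(interplay_config(require_ab_effective = TRUE))
  expect_equal(partial_key(specs$synergism_up),
               "cA:greater;cB:greater;cInt:greater;cAB:greater")
  expect_equal(partial_key(specs$reductive_by_A_up),
               "cA:near_equal;cB:greater;cInt:less;cAB:greater")
  expect_equal(partial_key(specs$emergent_down),
               "cA:near_equal;cB:near_equal;cInt:less;cAB:less")
  expect_equal(partial_key(specs$antagonism_down),
               "cA:less;cB:less;cInt:greater;cAB:less")

  plain <- enumerate_patterns(interplay_config(require_ab_effective = FALSE))
  expect_true(all(vapply(plain, function(s) length(s$partials) == 3L, logical(1))))
  expect_true(all(vapply(specs, function(s) length(s$partials) == 4L, logical(1))))
})

test_that("clear-cut features are classified into the forced pattern", {
  cfg <- interplay_config()
  tiny <- 1e-4  # SE ~ 0.01, far below effects and eps

  cases <- list(
    list(means = c(0, 1, 1, 3), label = "synergism_up"),
    list(means = c(0, 0, 1, 3), label = "potentiation_by_A_up"),
    list(means = c(0, 1, 1, 1), label = "antagonism_up"),
    list(means = c(0, 0, 1, 1), label = "redundance_of_A_up"),
    list(means = c(0, -1, -1, -3), label = "synergism_down"),
    list(means = c(0, 0, 0, 1), label = "emergent_up"),
    list(means = c(0, 1, 0, 0.5), label = "reductive_by_B_up")
  )
  for (cs in cases) {
    fit <- make_fit(cs$means, s2_tilde = tiny, df_tilde = 8)
    a <- classify_feature(fit, 1, cfg)
    expect_identical(a$accepted, cs$label)
    expect_identical(a$label, cs$label)
  }
})

test_that("null features are almost never classified", {
  out <- simulate_and_classify(c(null = 2000), sigma2 = 0.01, seed = 404)
  labs <- out$result$assignments$label
  expect_lte(mean(labs != "none"), 0.05)
  expect_gt(mean(labs == "none"), 0.9)
})

test_that("conflicting patterns are never co-accepted on simulated data", {
  out <- simulate_and_classify(
    c(synergism_up = 300, antagonism_up = 300, additive_up = 300, null = 300),
    sigma2 = 0.01, seed = 505)
  a <- out$result$assignments
  alpha <- out$result$config$alpha
  specs <- names(enumerate_patterns(out$result$config))
  acc <- as.matrix(a[, specs]) < alpha
  expect_false(any(acc[, "synergism_up"] & acc[, "antagonism_up"]))
  expect_false(any(acc[, "synergism_down"] & acc[, "antagonism_down"]))
  for (nm in c("synergism", "additive", "antagonism", "emergent")) {
    expect_false(any(acc[, paste0(nm, "_up")] & acc[, paste0(nm, "_down")]))
  }
})

test_that("ambiguous co-acceptance is surfaced, not silently resolved", {
  # interaction estimate inside the window where both the strict test
  # and the equivalence test accept
  fit <- make_fit(c(0, 1, 1, 2.07), s2_tilde = 0.03^2 / (4 / 3), df_tilde = 8)
  a <- classify_feature(fit, 1, interplay_config())
  expect_identical(a$label, "ambiguous")
  expect_setequal(a$accepted, c("synergism_up", "additive_up"))
})

test_that("degenerate features are labelled and never tested", {
  vals <- rbind(flat = rep(1, 12),
                live = c(0, 0.1, -0.1, rep(1, 6), 2.9, 3, 3.1),
                live2 = c(0, 0.2, -0.2, rep(0, 6), 0.9, 1, 1.1))
  colnames(vals) <- paste0("s", 1:12)
  design <- design_map(stats::setNames(rep(c("C", "A", "B", "AB"), each = 3),
                                       colnames(vals)))
  fit <- fit_condition_means(expression_matrix(vals), design)
  mfit <- moderate(fit, estimate_eb_prior(fit$s2[!fit$degenerate], fit$d_g))
  expect_identical(classify_feature(mfit, "flat")$label, "degenerate")
  res <- classify_dataset(mfit)
  expect_identical(res$assignments$label[res$assignments$feature_id == "flat"],
                   "degenerate")
  expect_equal(res$n_degenerate, 1L)
})

test_that("dataset classification recovers well-separated planted patterns", {
  blocks <- c(synergism_up = 250, synergism_down = 250,
              antagonism_up = 250, antagonism_down = 250)
  out <- simulate_and_classify(blocks, sigma2 = 0.01, seed = 606)
  rec <- evaluate_recovery(out$truth, out$result)
  expect_true(all(rec$sensitivity[names(blocks)] >= 0.95))
  s <- out$result$summary
  expect_gte(s$up[s$pattern == "synergism"], 0.95 * 250)
  expect_gte(s$down[s$pattern == "antagonism"], 0.95 * 250)
})

test_that("an empty feature set classifies to an empty table with zero counts", {
  fit <- make_fit(matrix(numeric(0), nrow = 0, ncol = 4), s2_tilde = numeric(0))
  res <- classify_dataset(fit)
  expect_equal(nrow(res$assignments), 0L)
  expect_true(all(res$summary$up == 0L) && all(res$summary$down == 0L))
  expect_equal(res$n_classified, 0L)
})

test_that("alpha = 0 accepts nothing and BH adjustment only removes acceptances", {
  out <- simulate_and_classify(c(synergism_up = 100, null = 400), sigma2 = 0.01,
                               seed = 707, config = interplay_config(alpha = 0))
  expect_equal(out$result$n_classified, 0L)

  plain <- simulate_and_classify(c(synergism_up = 100, null = 400), sigma2 = 0.01,
                                 seed = 707)
  fdr <- classify_dataset(plain$fit, interplay_config(fdr = TRUE))
  expect_lte(fdr$n_classified, plain$result$n_classified)
  expect_gt(fdr$n_classified, 0L)
})
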