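#' Run the full classification pipeline on files
#'
#' Reads a log2 expression matrix and a targets file, fits condition
#' means, estimates and applies the empirical Bayes variance prior,
#' classifies every feature into the interplay taxonomy and writes
#' three outputs next to `out`: the per-feature results TSV (`out`),
#' a counts summary TSV (`<out>.summary.tsv`, rows the ten forms,
#' columns UP/DOWN) and a JSON metadata sidecar (`<out>.meta.json`)
#' sufficient to reproduce the run.
#'
#' @param matrix_path Expression TSV (see [read_expression()]).
#' @param targets_path Targets TSV (see [read_targets()]).
#' @param config An [interplay_config()].
#' @param out Output path for the results TSV; `NULL` skips writing.
#' @param condition_map Optional renaming of condition labels.
#' @return (Invisibly) a list with `result` ([classify_dataset()]
#'   output), `fit`, `prior`, `metadata`.
#' @export
run_classify <- function(matrix_path, targets_path,
                         config = interplay_config(),
                         out = NULL, condition_map = NULL) {
  mat <- read_expression(matrix_path)
  design <- read_targets(targets_path, condition_map = condition_map)
  fit <- fit_condition_means(mat, design)
  prior <- estimate_eb_prior(fit$s2[!fit$degenerate], fit$d_g)
  mfit <- moderate(fit, prior)
  result <- classify_dataset(mfit, config)

  metadata <- run_metadata(config, prior, fit,
                           inputs = c(matrix = matrix_path, targets = targets_path),
                           n_input_features = length(mat$feature_ids))
  if (!is.null(out)) {
    write_results(result, out)
    write_summary(result, paste0(out, ".summary.tsv"))
    jsonlite::write_json(metadata, paste0(out, ".meta.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(list(result = result, fit = mfit, prior = prior, metadata = metadata))
}

run_metadata <- function(config, prior, fit, inputs, n_input_features, seed = NULL) {
  list(
    software = paste0("interplay2x2 ", as.character(utils::packageVersion("interplay2x2"))),
    alpha = config$alpha,
    eps = config$eps,
    require_ab_effective = config$require_ab_effective,
    fdr = config$fdr,
    seed = seed,
    inputs = as.list(vapply(inputs, function(p) {
      unname(tools::md5sum(p))
    }, character(1))),
    n_input_features = n_input_features,
    n_missing_excluded = fit$n_missing_excluded,
    n_degenerate = sum(fit$degenerate),
    residual_df = fit$d_g,
    prior = list(d0 = prior$d0, s0_2 = prior$s0_2,
                 moderation = "plain (no trend, no robust fitting)")
  )
}

fmt_num <- function(x) ifelse(is.na(x), "NA", formatC(signif(x, 6), format = "g", digits = 6))
fmt_p <- function(x) ifelse(is.na(x), "NA", formatC(x, format = "e", digits = 5))

#' Write per-feature classification results to TSV
#'
#' Columns are documented in a `#`-prefixed header block: feature id,
#' label and direction, compound p of the accepted pattern, the 20
#' per-pattern compound p-values, the four contrast estimates and a
#' status flag. Estimates carry 6 significant digits; p-values are in
#' scientific notation.
#'
#' @param result An `interplay_result`.
#' @param path Output path.
#' @export
write_results <- function(result, path) {
  a <- result$assignments
  pat_cols <- names(enumerate_patterns(result$config))
  est_cols <- c("cA", "cB", "cInt", "cAB")
  header <- c(
    "# interplay2x2 per-feature classification",
    "# feature_id: input feature identifier",
    "# label: unique accepted pattern, or none/ambiguous/degenerate",
    "# direction: up/down regulation of the accepted pattern",
    "# p_accepted: compound p-value of the accepted pattern",
    paste0("# p.<pattern>_<direction>: intersection-union compound p-value (",
           length(pat_cols), " columns)"),
    "# est.cA, est.cB: single-effect contrast estimates A-C, B-C (log2)",
    "# est.cInt: interaction contrast AB-A-B+C (log2)",
    "# est.cAB: combined-effect contrast AB-C (log2)",
    "# status: ok or degenerate (zero residual variance, not classified)"
  )
  if (nrow(a)) {
    df <- data.frame(
      feature_id = a$feature_id,
      label = a$label,
      direction = ifelse(is.na(a$direction), "NA", a$direction),
      p_accepted = fmt_p(a$p_accepted),
      stringsAsFactors = FALSE
    )
    for (cc in pat_cols) df[[paste0("p.", cc)]] <- fmt_p(a[[cc]])
    for (cc in est_cols) df[[paste0("est.", cc)]] <- fmt_num(a[[cc]])
    df$status <- a$status
  } else {
    df <- data.frame(feature_id = character(0))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the counts summary to TSV
#'
#' @param result An `interplay_result`.
#' @param path Output path.
#' @export
write_summary <- function(result, path) {
  s <- result$summary
  s$total <- s$up + s$down
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# interplay2x2 counts per form of interplay",
               sprintf("# total features classified: %d", result$n_classified)), con)
  utils::write.table(s, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulated dataset to TSV files
#'
#' Companion of [simulate_dataset()] for the `simulate` CLI subcommand:
#' writes the expression matrix, the targets file and the planted-truth
#' table.
#'
#' @param sim Output of [simulate_dataset()].
#' @param prefix Path prefix; files `<prefix>.matrix.tsv`,
#'   `<prefix>.targets.tsv`, `<prefix>.truth.tsv` are produced.
#' @export
write_simulation <- function(sim, prefix) {
  write_expression(sim$matrix, paste0(prefix, ".matrix.tsv"))
  targets <- data.frame(sample_id = names(sim$design$assignment),
                        condition = unname(sim$design$assignment))
  utils::write.table(targets, paste0(prefix, ".targets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$truth, paste0(prefix, ".truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
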