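#' Construct an expression matrix object
#'
#' Wraps a numeric features x samples matrix of log2 expression values.
#' Feature and sample identifiers must be unique; values are kept on the
#' log2 scale as supplied and never re-transformed.
#'
#' @param values Numeric matrix, features in rows, samples in columns,
#'   with row and column names.
#' @return An object of class `expression_matrix` with elements
#'   `values`, `feature_ids`, `sample_ids`.
#' @export
expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_input("expression values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_input("expression matrix needs feature row names and sample column names")
  }
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup)) {
    stop_input("duplicated feature id(s): ", paste(unique(dup), collapse = ", "))
  }
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup)) {
    stop_input("duplicated sample id(s): ", paste(unique(dup), collapse = ", "))
  }
  structure(
    list(values = values,
         feature_ids = rownames(values),
         sample_ids = colnames(values)),
    class = "expression_matrix"
  )
}

#' Read a log2 expression matrix from TSV
#'
#' The file must have a header row; the first column holds feature
#' identifiers, the remaining columns one sample each. Duplicate feature
#' identifiers and non-numeric cells are rejected with an informative
#' error naming the offending row/column.
#'
#' @param path Path to a tab-separated file.
#' @return An [expression_matrix()] object.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop_input("expression file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 2L) stop_input("expression file needs a feature column plus >= 1 sample column")
  ids <- raw[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop_input("duplicated feature id(s): ", paste(dup, collapse = ", "))
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals), dimnames = dimnames(vals)))
  bad <- which(is.na(num) & !(toupper(vals) %in% c("NA", "NAN", "")), arr.ind = TRUE)
  if (nrow(bad)) {
    b <- bad[1L, ]
    stop_input(sprintf("non-numeric value '%s' at feature '%s', sample '%s'",
                       vals[b[1L], b[2L]], ids[b[1L]], colnames(vals)[b[2L]]))
  }
  rownames(num) <- ids
  expression_matrix(num)
}

#' Write an expression matrix to TSV
#'
#' Full-precision round-trip companion of [read_expression()].
#'
#' @param x An [expression_matrix()] object.
#' @param path Output path.
#' @param id_column Name for the feature-id column in the header.
#' @export
write_expression <- function(x, path, id_column = "feature_id") {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(x$feature_ids,
                   format(x$values, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(id_column, x$sample_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a design map for the 2x2 layout
#'
#' Validates that all four conditions (control `C`, single constituents
#' `A` and `B`, combination `AB`) are present and that the residual
#' degrees of freedom `N - 4` are at least 1 (a warning is raised at
#' exactly 1, where variance estimation is fragile).
#'
#' @param assignment Named character vector mapping sample id to one of
#'   `C`, `A`, `B`, `AB`.
#' @return An object of class `design_map` with elements `assignment`
#'   and `replicate_counts`.
#' @export
design_map <- function(assignment) {
  if (is.null(names(assignment)) || any(names(assignment) == "")) {
    stop_input("sample assignment must be a named vector (sample id -> condition)")
  }
  assignment <- vapply(assignment, as.character, character(1))
  unknown <- setdiff(unique(assignment), CONDITIONS)
  if (length(unknown)) {
    stop_config("unknown condition label(s): ", paste(unknown, collapse = ", "),
                " (expected C, A, B, AB; use a condition map to rename)")
  }
  missing <- setdiff(CONDITIONS, unique(assignment))
  if (length(missing)) {
    stop_config("condition(s) absent from targets: ", paste(missing, collapse = ", "))
  }
  counts <- vapply(CONDITIONS, function(cc) sum(assignment == cc), integer(1))
  d_g <- sum(counts) - 4L
  if (d_g < 1L) {
    stop_config("insufficient replication: N - 4 = ", d_g, " residual df (need >= 1)")
  }
  if (d_g == 1L) {
    warning("only 1 residual degree of freedom; >= 2 recommended", call. = FALSE)
  }
  structure(list(assignment = assignment, replicate_counts = counts),
            class = "design_map")
}

#' Read a targets file mapping samples to conditions
#'
#' Two tab-separated columns: sample id and condition label. Study-
#' specific labels (e.g. `UNSTIMULATED`, `CURDLAN`, `GM-CSF`,
#' `COMBINATION`) can be renamed to the canonical `C`/`A`/`B`/`AB` via
#' `condition_map`.
#'
#' @param path Path to the targets TSV (header optional; a header line
#'   is detected when its second field is not a known condition label).
#' @param condition_map Optional named character vector, names are the
#'   labels used in the file, values the canonical labels.
#' @return A [design_map()] object.
#' @export
read_targets <- function(path, condition_map = NULL) {
  if (!file.exists(path)) stop_input("targets file not found: ", path)
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 2L) stop_input("targets file needs two tab-separated columns")
  known <- c(CONDITIONS, names(condition_map))
  if (!(raw[[2L]][1L] %in% known) && nrow(raw) > 1L) raw <- raw[-1L, , drop = FALSE]
  assignment <- raw[[2L]]
  names(assignment) <- raw[[1L]]
  if (!is.null(condition_map)) {
    hit <- assignment %in% names(condition_map)
    assignment[hit] <- unname(condition_map[assignment[hit]])
  }
  design_map(assignment)
}

# Check that matrix and targets describe the same samples, both ways.
check_samples <- function(matrix, design) {
  extra <- setdiff(matrix$sample_ids, names(design$assignment))
  if (length(extra)) {
    stop_input("sample(s) in matrix but not in targets: ", paste(extra, collapse = ", "))
  }
  extra <- setdiff(names(design$assignment), matrix$sample_ids)
  if (length(extra)) {
    stop_input("sample(s) in targets but not in matrix: ", paste(extra, collapse = ", "))
  }
  invisible(TRUE)
}
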