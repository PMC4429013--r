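#' @keywords internal
"_PACKAGE"

CONDITIONS <- c("C", "A", "B", "AB")

# Classed conditions so the CLI can map error kinds to exit codes:
# input errors (malformed/missing files) vs configuration errors
# (invalid design, parameters out of range).
stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("interplay_input_error", "error")))
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("interplay_config_error", "error")))
}

# Upper-tail Student-t probability that degrades to the standard normal
# for infinite degrees of freedom (the d0 = +Inf moderation limit).
pt_upper <- function(q, df) {
  if (length(df) == 1L) df <- rep_len(df, length(q))
  p <- numeric(length(q))
  fin <- is.finite(df)
  if (any(fin)) p[fin] <- stats::pt(q[fin], df = df[fin], lower.tail = FALSE)
  if (any(!fin)) p[!fin] <- stats::pnorm(q[!fin], lower.tail = FALSE)
  p
}

# 1 - alpha Student-t quantile with the same infinite-df convention.
qt_crit <- function(alpha, df) {
  if (is.finite(df)) stats::qt(1 - alpha, df = df) else stats::qnorm(1 - alpha)
}
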