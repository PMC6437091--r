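# Internal helpers shared across modules.

# All user-facing failures carry a condition subclass so callers (and the
# test suite) can tell malformed input files from bad parameters and from
# analyses that are undefined on the given data.
pr_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "panrecom_error", "error")))
}

format_error <- function(...) pr_error(paste0(...), "panrecom_format_error")

param_error <- function(...) pr_error(paste0(...), "panrecom_parameter_error")

analysis_error <- function(...) pr_error(paste0(...), "panrecom_analysis_error")

# Exact rational comparison of an occupancy fraction k/n against a decimal
# threshold t. t is promoted to num/10^6; products of integers this size are
# exact in doubles, so boundary cases such as 19/21 vs 0.90 are decided
# without floating-point error.
frac_ge <- function(k, n, t) {
  den <- 1e6
  k * den >= round(t * den) * n
}

frac_lt <- function(k, n, t) !frac_ge(k, n, t)

# Drop comment ("#"-prefixed) and blank lines; keep original line numbers as
# an attribute so format errors can cite them.
read_body_lines <- function(path) {
  if (!file.exists(path)) format_error("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  structure(lines[keep], line_numbers = which(keep))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
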