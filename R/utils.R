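# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a classed condition
#' @noRd
dd_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "ddnetmap_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

dd_param_error <- function(msg) dd_stop(msg, "ddnetmap_parameter_error")
dd_format_error <- function(msg) dd_stop(msg, "ddnetmap_format_error")

#' Check a single finite numeric value
#' @noRd
assert_scalar <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    dd_param_error(sprintf("'%s' must be a single finite number", name))
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    dd_param_error(sprintf(
      "'%s' = %g is outside %s%g, %g%s", name, x,
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]"))
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  assert_scalar(x, name, lower = min)
  if (x != round(x))
    dd_param_error(sprintf("'%s' must be an integer count", name))
  invisible(as.integer(x))
}

#' Geometric mean of strictly positive values
#' @noRd
geomean <- function(x) exp(mean(log(x)))

#' Population (ddof = 0) standard deviation
#' @noRd
sd_pop <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

#' Deterministic seed derivation for sub-streams
#'
#' Keeps derived seeds in 32-bit integer range.
#' @noRd
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + offset) %% 2147483647)
}

#' Write a TSV with fixed conventions (no quotes, no row names)
#' @noRd
write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
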