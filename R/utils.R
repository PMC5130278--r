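# internal validation and formatting helpers

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop(sprintf("`%s` = %g is outside %s%g, %g%s", name, x,
                 if (open_lower) "(" else "[", lower, upper,
                 if (open_upper) ")" else "]"), call. = FALSE)
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < min)
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}

#' Format a p-value or threshold to two significant figures
#'
#' Reports use two significant figures in fixed notation (e.g. `0.00056`,
#' `0.000037`); machine-readable outputs keep full precision.
#'
#' @param p Numeric vector of p-values or thresholds.
#' @return Character vector.
#' @export
#' @examples
#' format_p(0.05 / 89)
format_p <- function(p) {
  format(signif(p, 2), scientific = FALSE, trim = TRUE)
}

# stable hash of a config (or any jsonlite-serialisable object)
config_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}
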