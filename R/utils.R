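# small internal helpers shared across modules

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

unitize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) abort("cannot normalize a zero vector")
  v / n
}

# stop with a classed condition so callers can distinguish error families
fc_abort <- function(message, class) {
  abort(message, class = c(class, "femcurve_error"))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         closed_lower = TRUE, closed_upper = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (closed_lower) x >= lower else x > lower) &&
    (if (closed_upper) x <= upper else x < upper)
  if (!ok) {
    fc_abort(sprintf(
      "`%s` must be a single finite number in %s%s, %s%s (got %s)",
      name, if (closed_lower) "[" else "(", format(lower), format(upper),
      if (closed_upper) "]" else ")", deparse(substitute(x))
    ), "femcurve_parameter_error")
  }
  invisible(x)
}
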