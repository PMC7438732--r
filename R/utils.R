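# internal input checks shared across modules

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_null = FALSE, strict_lower = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    abort(sprintf("`%s` must be supplied.", name), class = "ppasekin_validation_error")
  }
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` must be finite and numeric.", name),
          class = "ppasekin_validation_error")
  }
  bad <- if (strict_lower) any(x <= lower) else any(x < lower)
  if (bad || any(x > upper)) {
    abort(sprintf("`%s` must lie in %s%g, %g].", name,
                  if (strict_lower) "(" else "[", lower, upper),
          class = "ppasekin_validation_error")
  }
  invisible(x)
}

check_scalar <- function(x, name, ...) {
  if (length(x) != 1L) {
    abort(sprintf("`%s` must be a single value.", name),
          class = "ppasekin_validation_error")
  }
  check_number(x, name, ...)
}

abort_validation <- function(msg) {
  abort(msg, class = "ppasekin_validation_error")
}

# round half away from zero is irrelevant here; base round() (banker's) is fine
round_to_nearest <- function(x, unit) round(x / unit) * unit
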