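# internal helpers shared across modules

# round half away from zero; base round() rounds half to even
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

stop_input <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_number <- function(x, name, positive = FALSE, nonnegative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_input(name, " must be a single finite number")
  if (positive && x <= 0) stop_input(name, " must be > 0")
  if (nonnegative && x < 0) stop_input(name, " must be >= 0")
  invisible(x)
}
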