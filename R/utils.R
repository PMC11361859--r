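#' @keywords internal
"_PACKAGE"

# Round half away from zero (base round() rounds half to even, which does not
# match how screening probabilities are conventionally printed).
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Odd window length (in samples) >= the requested duration, for running medians.
odd_window <- function(duration_s, fs) {
  k <- max(3L, as.integer(round(duration_s * fs)))
  if (k %% 2L == 0L) k <- k + 1L
  k
}

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
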