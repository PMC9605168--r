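# Internal numeric helpers shared across modules.

# round half away from zero; base round() is banker's rounding, which would
# make stay counts depend on the parity of the integer part.
round_half_up <- function(x) floor(x + 0.5)

# Stochastic integerization of an expected count x*p: the integer part is
# deterministic, the fractional part is a Bernoulli draw. E[result] = x*p.
floor_bernoulli <- function(ev) {
  fl <- floor(ev)
  frac <- ev - fl
  fl + (stats::runif(length(ev)) < frac)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_prob <- function(p, what) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop(sprintf("%s must be in [0, 1]", what), call. = FALSE)
  }
  invisible(p)
}
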