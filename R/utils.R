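# internal helpers shared across modules

# round-half-up at `digits` decimals (report tables use half-up, not banker's)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# deterministic per-generator substream seed derived from one global seed,
# so adding a generator never perturbs the draws of another
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 31 + k) %% 2147483647
  as.integer((abs(seed) * 1000003 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

check_fraction <- function(x, name, open_left = FALSE, open_right = FALSE) {
  if (!is_scalar_number(x) ||
      (open_left  && x <= 0) || (!open_left  && x < 0) ||
      (open_right && x >= 1) || (!open_right && x > 1)) {
    stop_invalid("`%s` must be a fraction in %s0,1%s, got %s", name,
                 if (open_left) "(" else "[", if (open_right) ")" else "]",
                 format(x))
  }
  invisible(x)
}
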