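# Internal validation helpers. All user-facing errors are classed so callers
# and tests can distinguish input problems from numerical failures.

stop_spt <- function(msg, class = "sptkinetics_error", ...) {
  rlang::abort(msg, class = class, ...)
}

check_number <- function(x, name, min = -Inf, max = Inf, allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (!allow_inf && !is.finite(x))) {
    stop_spt(sprintf("`%s` must be a single finite number.", name),
             class = "sptkinetics_bad_argument")
  }
  if (x < min || x > max) {
    stop_spt(sprintf("`%s` must be in [%s, %s], got %s.", name,
                     format(min), format(max), format(x)),
             class = "sptkinetics_bad_argument")
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  check_number(x, name, min = min)
  if (x != as.integer(x)) {
    stop_spt(sprintf("`%s` must be a whole number.", name),
             class = "sptkinetics_bad_argument")
  }
  invisible(as.integer(x))
}

# Deterministic per-stream seed derived from a master seed. Knuth-style
# multiplicative hash keeps streams stable when the number of particles
# changes: stream i always gets the same seed for a given master seed.
derive_seed <- function(master, stream) {
  (as.double(master) * 48271 + as.double(stream) * 16807) %% 2147483647
}
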