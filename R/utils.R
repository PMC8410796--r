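# shared argument checks -------------------------------------------------

check_batch <- function(scores, labels, call = rlang::caller_env()) {
  if (length(scores) == 0L || length(labels) == 0L) {
    abort("`scores` and `labels` must be non-empty.",
          class = "melbalance_invalid_input", call = call)
  }
  if (length(scores) != length(labels)) {
    abort(sprintf("`scores` (%d) and `labels` (%d) must have equal length.",
                  length(scores), length(labels)),
          class = "melbalance_invalid_input", call = call)
  }
  if (anyNA(scores) || anyNA(labels)) {
    abort("`scores` and `labels` must not contain missing values.",
          class = "melbalance_invalid_input", call = call)
  }
  if (any(scores < 0 | scores > 1)) {
    abort("All `scores` must lie in [0, 1].",
          class = "melbalance_invalid_input", call = call)
  }
  if (!all(labels %in% c(0, 1))) {
    abort("All `labels` must be exactly 0 or 1.",
          class = "melbalance_invalid_input", call = call)
  }
  invisible(TRUE)
}

check_scalar <- function(x, name, min = -Inf, max = Inf,
                         call = rlang::caller_env()) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%s, %s].",
                  name, format(min), format(max)),
          class = "melbalance_invalid_input", call = call)
  }
  invisible(TRUE)
}

check_count <- function(x, name, min = 0L, call = rlang::caller_env()) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      x != round(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min),
          class = "melbalance_invalid_input", call = call)
  }
  invisible(TRUE)
}

# seed handling: functions taking `seed = NULL` draw from the current RNG
# stream; an explicit seed gives a reproducible, stream-isolated draw.
with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# derive a bounded sub-seed from (seed, k); keeps values well below 2^31
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + k * 104729) %% 2147480000)
}
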