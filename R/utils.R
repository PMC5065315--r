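# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL evaluates in the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer or NULL", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), expr)
}

check_scalar_number <- function(x, name, positive = FALSE, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  }
  if (x < min) {
    stop(sprintf("'%s' must be >= %s", name, format(min)), call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) || x < min) {
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

# Resolve a per-sample parameter given as a scalar, a vector named by
# condition, or a vector of length n_samples (in sample order).
resolve_per_sample <- function(x, name, samples) {
  n <- nrow(samples)
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("'%s' must be positive and finite", name), call. = FALSE)
  }
  if (length(x) == 1L) return(rep(unname(x), n))
  if (!is.null(names(x))) {
    if (!all(samples$condition %in% names(x))) {
      stop(sprintf("'%s' names must cover all conditions", name), call. = FALSE)
    }
    return(unname(x[samples$condition]))
  }
  if (length(x) == n) return(unname(x))
  stop(sprintf(
    "'%s' must be length 1, one value per condition (named), or one per sample",
    name
  ), call. = FALSE)
}
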