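# internal helpers shared across modules

# log-normal sigma for a target coefficient of variation
cv_to_sigma <- function(cv) sqrt(log(1 + cv^2))

# draw log-normal values with a given *median* and coefficient of variation
rlnorm_med <- function(n, med, cv) {
  rlnorm(n, meanlog = log(med), sdlog = cv_to_sigma(cv))
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min),
          class = "flowabc_invalid_argument")
  }
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1, open_lo = TRUE) {
  bad <- length(x) != 1L || !is.finite(x) || x > hi ||
    (if (open_lo) x <= lo else x < lo)
  if (bad) {
    abort(sprintf("`%s` must be a single number in %s%g, %g].",
                  name, if (open_lo) "(" else "[", lo, hi),
          class = "flowabc_invalid_argument")
  }
  as.numeric(x)
}

check_positive <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", name),
          class = "flowabc_invalid_argument")
  }
  as.numeric(x)
}

# deterministic sub-seed derived from a base seed and a stream label, kept
# inside the 32-bit integer range so set.seed() always accepts it
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h) %% .Machine$integer.max)
}

# sample coefficient of variation (n - 1 denominator); the package-wide
# convention for every reported CV
cv_of <- function(x) {
  if (length(x) < 2L) return(NA_real_)
  m <- mean(x)
  if (m == 0) return(NA_real_)
  sd(x) / m
}
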