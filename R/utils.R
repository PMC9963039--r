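#' @keywords internal
GRAVITY <- 9.81

# deterministic 32-bit substream seed from a master seed and integer keys;
# stays strictly below 2^31 so set.seed() never overflows
derive_seed <- function(seed, ...) {
  keys <- c(seed, ...)
  h <- 17
  for (k in keys) {
    # MINSTD multiplier; h * 48271 < 2^47 keeps exact double arithmetic
    h <- (h * 48271 + (abs(as.numeric(k)) %% 2147483647) + 1) %% 2147483647
  }
  as.integer(h)
}

# draw from N(mean, sd) truncated to +/- trunc*sd by resampling-free clamping
# of the quantile (keeps a single RNG draw per value for reproducibility)
rnorm_trunc <- function(n, mean = 0, sd = 1, trunc = 2) {
  lo <- stats::pnorm(-trunc)
  hi <- stats::pnorm(trunc)
  mean + sd * stats::qnorm(lo + (hi - lo) * stats::runif(n))
}

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_config("'%s' must be a single finite number", name)
  }
  if (x < lower || x > upper) {
    stop_config("'%s' = %g outside [%g, %g]", name, x, lower, upper)
  }
  invisible(x)
}

# central differences with one-sided endpoint stencils
central_diff <- function(y, dt) {
  n <- length(y)
  if (n < 3L) stop_config("need at least 3 samples to differentiate")
  d <- numeric(n)
  d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (2 * dt)
  d[1] <- (y[2] - y[1]) / dt
  d[n] <- (y[n] - y[n - 1]) / dt
  d
}

check_uniform_time <- function(time, tol = 1e-9) {
  dt <- diff(time)
  if (length(dt) < 1L || any(dt <= 0) || max(dt) - min(dt) > tol * max(dt)) {
    stop_config("time base must be strictly increasing and uniformly sampled")
  }
  mean(dt)
}

# centred moving average used on predicted moment series before peak
# extraction; width in seconds, truncated at the series ends
smooth_series <- function(v, fs, window) {
  if (is.null(window) || window <= 0) return(v)
  k <- max(1L, round(window * fs))
  if (k <= 1L) return(v)
  half <- k %/% 2
  cs <- cumsum(c(0, v))
  n <- length(v)
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
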