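# Internal helpers shared across modules.

stop_invalid <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "sourcefidelity_invalid_argument")
}

stop_singular <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "sourcefidelity_singular")
}

stop_format <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "sourcefidelity_format")
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x != round(x) || x < min) {
    stop_invalid("`%s` must be a single integer >= %d", name, min)
  }
  as.integer(x)
}

check_scalar <- function(x, name, min = -Inf, max = Inf, allow_inf = FALSE) {
  ok <- length(x) == 1L && is.numeric(x) && (is.finite(x) || (allow_inf && is.infinite(x) && x > 0))
  if (!ok || x < min || x > max) {
    stop_invalid("`%s` must be a single number in [%s, %s]", name, min, max)
  }
  as.numeric(x)
}

# Evaluate `code` under a fixed RNG state without disturbing the caller's.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Derive a stream-specific seed from a base seed; stays inside 32-bit range.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 7919 + as.double(stream) * 104729) %% 2147483647)
}

unit_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  m / pmax(n, 1e-300)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rowwise cross product of two n x 3 matrices.
cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Solve A X = B for symmetric positive definite A via Cholesky.
chol_solve <- function(A, B, context = "system") {
  R <- tryCatch(chol(A), error = function(e) {
    stop_singular("singular %s: Cholesky factorization failed", context)
  })
  backsolve(R, backsolve(R, B, transpose = TRUE))
}

# Full-precision number formatting for bit-exact text round trips.
fmt_double <- function(x) sprintf("%.17g", x)

trapezoid <- function(x, y) {
  o <- order(x, y)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}
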