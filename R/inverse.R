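new_inverse_kernel <- function(K, method, lambda2, weights = NULL, ...) {
  structure(list(K = K, method = method, lambda2 = lambda2,
                 weights = weights, ...),
            class = "inverse_kernel")
}

#' @export
print.inverse_kernel <- function(x, ...) {
  cat(sprintf("<inverse_kernel> %s, %d sources x %d sensors, lambda2 = %.3g%s\n",
              x$method, nrow(x$K), ncol(x$K), x$lambda2,
              if (!is.null(x$converged) && !x$converged) " (not converged)" else ""))
  invisible(x)
}

cov_matrix <- function(cov) {
  if (inherits(cov, "noise_covariance")) cov$C else as.matrix(cov)
}

#' Minimum-norm (MNE) inverse kernel
#'
#' `K = G' (G G' + lambda^2 C)^-1`, computed by a symmetric (Cholesky)
#' solve; no explicit inverse is formed. `lambda^2` is the Tikhonov
#' regularization parameter; the conventional coupling to the data SNR is
#' `lambda^2 = SNR^-2` (see [snr_lambda2()]), which presumes gain and noise
#' covariance on a common scale (see [balance_covariance()]).
#'
#' @param gain A `gain_matrix`.
#' @param cov A `noise_covariance` (or plain matrix); may be `NULL` when
#'   `lambda2 = 0`.
#' @param lambda2 Regularization scalar (>= 0).
#' @return An `inverse_kernel` with method `"MNE"`.
#' @export
mne_kernel <- function(gain, cov = NULL, lambda2 = 1) {
  lambda2 <- check_scalar(lambda2, "lambda2", min = 0)
  G <- gain$values
  A <- tcrossprod(G)
  if (lambda2 > 0) {
    if (is.null(cov)) stop_invalid("`cov` is required when lambda2 > 0")
    A <- A + lambda2 * cov_matrix(cov)
  }
  K <- t(chol_solve((A + t(A)) / 2, G, context = "sensor Gram matrix"))
  new_inverse_kernel(K, "MNE", lambda2)
}

#' dSPM standardization of an MNE kernel
#'
#' Each source is divided by the noise energy mapped to it:
#' `w_i = 1 / sqrt(diag_i(K C K'))`; the returned kernel is `diag(w) K`.
#'
#' @param kernel An MNE `inverse_kernel`.
#' @param cov The `noise_covariance` used for standardization.
#' @return An `inverse_kernel` with method `"dSPM"` and the weights stored.
#' @export
dspm_kernel <- function(kernel, cov) {
  C <- cov_matrix(cov)
  v <- rowSums((kernel$K %*% C) * kernel$K)
  if (any(v <= 0)) stop_invalid("degenerate source: zero mapped noise energy")
  w <- 1 / sqrt(v)
  new_inverse_kernel(w * kernel$K, "dSPM", kernel$lambda2, weights = w)
}

#' sLORETA standardization of an MNE kernel
#'
#' Weights are the inverse square roots of the diagonal of the MNE
#' resolution matrix: `w_i = 1 / sqrt(diag_i(K G))`.
#'
#' @param kernel An MNE `inverse_kernel`.
#' @param gain The `gain_matrix` the kernel was built from.
#' @return An `inverse_kernel` with method `"sLORETA"`.
#' @export
sloreta_kernel <- function(kernel, gain) {
  d <- rowSums(kernel$K * t(gain$values))
  if (any(d <= 0)) stop_invalid("degenerate source: non-positive resolution diagonal")
  w <- 1 / sqrt(d)
  new_inverse_kernel(w * kernel$K, "sLORETA", kernel$lambda2, weights = w)
}

#' eLORETA inverse kernel
#'
#' Iteratively determined diagonal depth weights `D`:
#' starting from `d_i = 1`, repeat `M = G D^-1 G' + lambda^2 C`,
#' `d_i <- sqrt(g_i' M^-1 g_i) / x0` (with `x0 = 1` A m keeping the units of
#' `D` at 1/(A m)^2) until the maximum relative change drops below `tol`.
#' The returned kernel is `K = D^-1 G' M^-1`. Non-convergence within
#' `max_iter` yields a warning and `converged = FALSE`, not a failure.
#'
#' @inheritParams mne_kernel
#' @param tol Relative-change stopping tolerance for the weights.
#' @param max_iter Iteration cap.
#' @return An `inverse_kernel` with method `"eLORETA"`, `weights = d`, and
#'   convergence status fields `converged`, `n_iter`.
#' @export
eloreta_kernel <- function(gain, cov = NULL, lambda2 = 1,
                           tol = 1e-6, max_iter = 100L) {
  lambda2 <- check_scalar(lambda2, "lambda2", min = 0)
  G <- gain$values
  if (lambda2 > 0 && is.null(cov)) stop_invalid("`cov` is required when lambda2 > 0")
  C <- if (lambda2 > 0) lambda2 * cov_matrix(cov) else 0
  n_src <- ncol(G)
  d <- rep(1, n_src)
  converged <- FALSE
  iter <- 0L
  B <- NULL
  repeat {
    iter <- iter + 1L
    M <- tcrossprod(sweep(G, 2, d, "/"), G) + C
    B <- chol_solve((M + t(M)) / 2, G, context = "eLORETA system") # M^-1 G
    q <- colSums(G * B)
    d_new <- sqrt(pmax(q, 0))
    rel <- max(abs(d_new - d) / pmax(abs(d), 1e-300))
    d <- d_new
    if (rel < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged) {
    warning(sprintf("eLORETA did not converge in %d iterations (last rel. change %.2e)",
                    iter, rel))
  }
  # recompute the kernel at the final weights
  M <- tcrossprod(sweep(G, 2, d, "/"), G) + C
  B <- chol_solve((M + t(M)) / 2, G, context = "eLORETA system")
  K <- t(B) / d
  new_inverse_kernel(K, "eLORETA", lambda2, weights = d,
                     converged = converged, n_iter = iter)
}

#' Apply an inverse kernel to sensor data
#'
#' `X_hat = K Y`; standardization weights are already folded into `K`.
#'
#' @param kernel An `inverse_kernel`.
#' @param Y `n_sensors x n_times` sensor data matrix (or a vector, treated
#'   as a single time point).
#' @return `n_sources x n_times` source-estimate matrix.
#' @export
apply_kernel <- function(kernel, Y) {
  if (is.vector(Y)) Y <- matrix(Y, ncol = 1)
  if (nrow(Y) != ncol(kernel$K)) {
    stop_invalid("sensor dimension mismatch: kernel expects %d rows, data has %d",
                 ncol(kernel$K), nrow(Y))
  }
  kernel$K %*% Y
}

#' Regularization from a target SNR
#'
#' The conventional coupling `lambda^2 = SNR^-2`, with `lambda^2 = 0` at
#' infinite SNR and a finite cap substituted at SNR = 0 (the lambda -> Inf
#' limit in which dSPM and sLORETA coincide).
#'
#' @param snr Amplitude SNR (>= 0, may be `Inf`).
#' @param cap Value substituted when `snr = 0`.
#' @return `lambda^2` scalar.
#' @export
snr_lambda2 <- function(snr, cap = 1e6) {
  snr <- check_scalar(snr, "snr", min = 0, allow_inf = TRUE)
  if (is.infinite(snr)) return(0)
  if (snr == 0) return(cap)
  min(1 / snr^2, cap)
}

#' Build a named linear kernel
#'
#' Convenience dispatcher over [mne_kernel()], [dspm_kernel()],
#' [sloreta_kernel()] and [eloreta_kernel()].
#'
#' @param method One of `"MNE"`, `"dSPM"`, `"sLORETA"`, `"eLORETA"`.
#' @inheritParams mne_kernel
#' @param ... Passed on to [eloreta_kernel()].
#' @return An `inverse_kernel`.
#' @export
linear_kernel <- function(method, gain, cov = NULL, lambda2 = 1, ...) {
  method <- match.arg(method, c("MNE", "dSPM", "sLORETA", "eLORETA"))
  switch(method,
    MNE = mne_kernel(gain, cov, lambda2),
    dSPM = dspm_kernel(mne_kernel(gain, cov, lambda2), cov),
    sLORETA = sloreta_kernel(mne_kernel(gain, cov, lambda2), gain),
    eLORETA = eloreta_kernel(gain, cov, lambda2, ...)
  )
}
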