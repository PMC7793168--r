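#' Mixed-norm estimate configuration
#'
#' @param alpha_pct Regularization strength as a percentage of `alpha_max`
#'   (the smallest value yielding an all-zero solution), in `(0, 100]`.
#'   100 gives exactly zero source activity.
#' @param tol Relative objective-decrease stopping tolerance.
#' @param max_iter Iteration cap.
#' @return An `mxne_config`.
#' @export
mxne_config <- function(alpha_pct = 55, tol = 1e-6, max_iter = 3000L) {
  alpha_pct <- check_scalar(alpha_pct, "alpha_pct", min = 0, max = 100)
  if (alpha_pct <= 0) stop_invalid("`alpha_pct` must be in (0, 100]")
  structure(list(alpha_pct = alpha_pct,
                 tol = check_scalar(tol, "tol", min = 0),
                 max_iter = check_count(max_iter, "max_iter")),
            class = "mxne_config")
}

# Symmetric inverse square root of a PD matrix.
inv_sqrt_matrix <- function(C) {
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  if (min(e$values) <= 0) stop_invalid("covariance is not positive definite")
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

mxne_objective <- function(Gt, Yt, X, alpha) {
  0.5 * sum((Yt - Gt %*% X)^2) + alpha * sum(sqrt(rowSums(X^2)))
}

#' L21 mixed-norm source estimate (MxNE)
#'
#' Solves `min_X 0.5 ||Yt - Gt X||_F^2 + alpha sum_i ||X_i,:||_2` in the
#' whitened domain (`Gt = C^-1/2 G`, `Yt = C^-1/2 Y`) by accelerated
#' proximal gradient (FISTA) with the block soft-threshold prox and step
#' `1/L`, `L` the largest squared singular value of `Gt`. The row-sparse
#' penalty selects sources: rows not selected are exactly zero.
#' `alpha = alpha_pct/100 * alpha_max` with
#' `alpha_max = max_i ||g_i' Yt||_2`.
#'
#' @param gain A `gain_matrix`.
#' @param Y `n_sensors x n_times` sensor data.
#' @param cov A `noise_covariance` (or plain PD matrix) used for whitening.
#' @param config An [mxne_config()].
#' @return An `mxne_fit` with fields `X` (`n_sources x n_times`), `active`
#'   (indices of nonzero rows), `alpha`, `alpha_max`, `objective`,
#'   `converged`, `n_iter`.
#' @export
mxne_solve <- function(gain, Y, cov, config = mxne_config()) {
  if (!inherits(config, "mxne_config")) stop_invalid("not an mxne_config")
  if (is.vector(Y)) Y <- matrix(Y, ncol = 1)
  G <- gain$values
  if (nrow(Y) != nrow(G)) stop_invalid("sensor dimension mismatch")
  W <- inv_sqrt_matrix(cov_matrix(cov))
  Gt <- W %*% G
  Yt <- W %*% Y
  n_src <- ncol(Gt); n_t <- ncol(Yt)

  corr <- crossprod(Gt, Yt) # n_src x n_t
  alpha_max <- max(sqrt(rowSums(corr^2)))
  alpha <- config$alpha_pct / 100 * alpha_max
  L <- svd(Gt, nu = 0, nv = 0)$d[1]^2

  X <- matrix(0, n_src, n_t)
  Xold <- X
  tk <- 1
  obj <- mxne_objective(Gt, Yt, X, alpha)
  converged <- FALSE
  iter <- 0L
  thr <- alpha / L
  while (iter < config$max_iter) {
    iter <- iter + 1L
    tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    Z <- X + ((tk - 1) / tk_new) * (X - Xold)
    tk <- tk_new
    V <- Z - crossprod(Gt, Gt %*% Z - Yt) / L
    nrm <- sqrt(rowSums(V^2))
    scale <- pmax(0, 1 - thr / pmax(nrm, 1e-300))
    Xold <- X
    X <- V * scale
    obj_new <- mxne_objective(Gt, Yt, X, alpha)
    if (abs(obj - obj_new) <= config$tol * max(abs(obj), 1e-300)) {
      obj <- obj_new
      converged <- TRUE
      break
    }
    obj <- obj_new
  }
  structure(list(X = X, active = which(rowSums(X^2) > 0),
                 alpha = alpha, alpha_max = alpha_max,
                 objective = obj, converged = converged, n_iter = iter,
                 config = config),
            class = "mxne_fit")
}

#' @export
print.mxne_fit <- function(x, ...) {
  cat(sprintf("<mxne_fit> %d/%d active rows, alpha = %.3g (%.0f%% of alpha_max), %d iters%s\n",
              length(x$active), nrow(x$X), x$alpha, x$config$alpha_pct,
              x$n_iter, if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Karush-Kuhn-Tucker residual correlations of an MxNE fit
#'
#' For each source row returns `||g_i' (Yt - Gt X)||_2` in the whitened
#' domain; at an exact solution this equals `alpha` for active rows and is
#' at most `alpha` for inactive rows.
#'
#' @inheritParams mxne_solve
#' @param fit An `mxne_fit`.
#' @return Tibble with columns `source`, `active`, `kkt_norm`.
#' @export
mxne_kkt <- function(fit, gain, Y, cov) {
  if (is.vector(Y)) Y <- matrix(Y, ncol = 1)
  W <- inv_sqrt_matrix(cov_matrix(cov))
  Gt <- W %*% gain$values
  Yt <- W %*% Y
  Rm <- crossprod(Gt, Yt - Gt %*% fit$X)
  tibble::tibble(source = seq_len(nrow(fit$X)),
                 active = seq_len(nrow(fit$X)) %in% fit$active,
                 kkt_norm = sqrt(rowSums(Rm^2)))
}
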