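#' Sigmoidal AUROC(SNR) model fit
#'
#' Fits `AUROC(SNR) = a * tanh(b * log10(SNR) + c) + d` by nonlinear least
#' squares with multistart (the canonical initialization
#' `a = 0.25, b = 1, c = 0, d = 0.75` plus seeded perturbations, best
#' residual sum of squares kept). SNR values of 0 or infinity are excluded
#' (log10 undefined); at least 4 finite-SNR points are required. A
#' degenerate (constant) response yields a flat fit with `r2 = 0` rather
#' than a failure.
#'
#' @param snr Numeric vector of SNR values.
#' @param auroc Matching AUROC values.
#' @param n_starts Number of multistart initializations (>= 1).
#' @param seed Seed for the perturbed starts.
#' @return A `sigmoid_fit` with fields `a, b, c, d`, `r2`, `data` tibble.
#' @export
fit_auroc_sigmoid <- function(snr, auroc, n_starts = 3L, seed = 1L) {
  keep <- is.finite(snr) & snr > 0 & is.finite(auroc)
  x <- log10(snr[keep])
  y <- auroc[keep]
  if (length(x) < 4L) stop_invalid("need at least 4 finite, positive SNR points")

  sstot <- sum((y - mean(y))^2)
  if (sstot == 0) {
    return(new_sigmoid_fit(c(a = 0, b = 1, c = 0, d = mean(y)), 0, x, y))
  }

  starts <- list(c(a = 0.25, b = 1, c = 0, d = 0.75))
  if (n_starts > 1L) {
    extra <- with_seed(derive_seed(seed, 41L), {
      lapply(seq_len(n_starts - 1L), function(i) {
        c(a = stats::runif(1, 0.05, 0.5), b = stats::runif(1, 0.3, 3),
          c = stats::runif(1, -2, 2), d = stats::runif(1, 0.4, 0.9))
      })
    })
    starts <- c(starts, extra)
  }

  best <- NULL
  best_ss <- Inf
  dat <- data.frame(x = x, y = y)
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * tanh(b * x + c) + d, data = dat, start = st,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      ss <- sum(stats::resid(fit)^2)
      if (ss < best_ss) { best_ss <- ss; best <- stats::coef(fit) }
    }
  }
  if (is.null(best)) {
    # flat fallback (degenerate optimization)
    return(new_sigmoid_fit(c(a = 0, b = 1, c = 0, d = mean(y)), 0, x, y))
  }
  r2 <- 1 - best_ss / sstot
  new_sigmoid_fit(best, r2, x, y)
}

new_sigmoid_fit <- function(coefs, r2, x, y) {
  pred <- coefs[["a"]] * tanh(coefs[["b"]] * x + coefs[["c"]]) + coefs[["d"]]
  structure(list(a = coefs[["a"]], b = coefs[["b"]], c = coefs[["c"]],
                 d = coefs[["d"]], r2 = r2,
                 data = tibble::tibble(log10_snr = x, auroc = y,
                                       fitted = pred)),
            class = "sigmoid_fit")
}

#' Evaluate a fitted sigmoid at given SNR values
#'
#' @param fit A `sigmoid_fit`.
#' @param snr Positive finite SNR values.
#' @return Predicted AUROC values.
#' @export
predict_sigmoid <- function(fit, snr) {
  fit$a * tanh(fit$b * log10(snr) + fit$c) + fit$d
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf(
    "<sigmoid_fit> AUROC(SNR) = %.3f tanh(%.3f log10 SNR + %.3f) + %.3f, r2 = %.3f\n",
    x$a, x$b, x$c, x$d, x$r2))
  invisible(x)
}

#' @rdname fit_auroc_sigmoid
#' @param x A `sigmoid_fit`.
#' @param ... Unused.
#' @method tidy sigmoid_fit
#' @export
tidy.sigmoid_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b", "c", "d"),
                 estimate = c(x$a, x$b, x$c, x$d))
}

#' @rdname fit_auroc_sigmoid
#' @method glance sigmoid_fit
#' @export
glance.sigmoid_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, nobs = nrow(x$data))
}
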