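#' Peak localization error
#'
#' Euclidean distance between the activated patch's center dipole (closest
#' member to the patch's center of gravity on the spherical reference
#' surface) and the dipole with the largest absolute estimated amplitude
#' (ties broken by lowest index). An all-zero estimate has no peak: `NA` is
#' returned and such cases are excluded from aggregates and counted
#' separately.
#'
#' @param x_hat Source amplitude vector (one entry per dipole).
#' @param space A `source_space`.
#' @param patch Integer vector of dipole indices of the activated patch.
#' @return Distance in meters, or `NA` for an all-zero estimate.
#' @export
peak_error <- function(x_hat, space, patch) {
  if (length(x_hat) != space$n_sources) {
    stop_invalid("estimate length %d does not match %d dipoles",
                 length(x_hat), space$n_sources)
  }
  a <- abs(x_hat)
  if (all(a == 0)) return(NA_real_)
  j <- which.max(a)
  i <- patch_center(patch, space)
  sqrt(sum((space$positions[i, ] - space$positions[j, ])^2))
}

#' Spatial dispersion
#'
#' Estimate-weighted L1 mean of the distances from the peak dipole:
#' `SD = sum_k d_jk |x_k| / sum_k |x_k|` with `d_jk` the Euclidean distance
#' from the peak dipole `j` to dipole `k`. Zero for an estimate
#' concentrated on a single dipole; `NA` for an all-zero estimate.
#'
#' @inheritParams peak_error
#' @return Dispersion in meters, or `NA`.
#' @export
spatial_dispersion <- function(x_hat, space) {
  if (length(x_hat) != space$n_sources) {
    stop_invalid("estimate length %d does not match %d dipoles",
                 length(x_hat), space$n_sources)
  }
  a <- abs(x_hat)
  s <- sum(a)
  if (s == 0) return(NA_real_)
  j <- which.max(a)
  d <- sqrt(rowSums((space$positions -
                       matrix(space$positions[j, ], space$n_sources, 3,
                              byrow = TRUE))^2))
  sum(d * a) / s
}

#' Center-of-gravity error
#'
#' Distance from the true source position to the amplitude-weighted
#' centroid of the estimate. On surface source spaces this measure is
#' biased toward the head center (the centroid of a spread-out cortical
#' estimate falls inside the surface); it is provided for comparison only.
#'
#' @inheritParams peak_error
#' @param r_true True source position (3-vector, meters).
#' @return Distance in meters, or `NA` for an all-zero estimate.
#' @export
cog_error <- function(x_hat, space, r_true) {
  a <- abs(x_hat)
  s <- sum(a)
  if (s == 0) return(NA_real_)
  cg <- colSums(space$positions * a) / s
  sqrt(sum((r_true - cg)^2))
}

#' Column-normalize a resolution matrix
#'
#' Divides each column by its maximum; all-zero (or all-NA) columns are
#' left as-is and flagged in the `zero_columns` attribute.
#'
#' @param m Numeric matrix (e.g. an empirical resolution matrix's values).
#' @return Normalized matrix with attribute `zero_columns`.
#' @export
normalize_columns <- function(m) {
  if (inherits(m, "empirical_resolution")) m <- m$values
  m <- as.matrix(m)
  mx <- suppressWarnings(apply(m, 2, max, na.rm = TRUE))
  zero <- which(!is.finite(mx) | mx == 0)
  scale <- mx
  scale[zero] <- 1
  out <- sweep(m, 2, scale, "/")
  attr(out, "zero_columns") <- zero
  out
}

#' Active/inactive classification counts at one threshold
#'
#' Entries strictly greater than `threshold` are classified active.
#' Diagonal entries are the true actives: TP = active diagonal, FN =
#' inactive diagonal, FP = active off-diagonal, TN = inactive off-diagonal.
#'
#' @param m_norm Column-normalized resolution matrix.
#' @param threshold Threshold in `[0, 1]`.
#' @return One-row tibble with columns `threshold, tp, fp, tn, fn`.
#' @export
classification_counts <- function(m_norm, threshold) {
  threshold <- check_scalar(threshold, "threshold", min = 0, max = 1)
  n <- nrow(m_norm)
  act <- m_norm > threshold
  diag_act <- diag(act)
  tp <- sum(diag_act, na.rm = TRUE)
  fn <- n - tp
  fp <- sum(act, na.rm = TRUE) - tp
  tn <- n^2 - n - fp
  tibble::tibble(threshold = threshold, tp = tp, fp = fp, tn = tn, fn = fn)
}

#' ROC and precision-recall curves by threshold sweep
#'
#' Sweeps a descending threshold grid over a column-normalized resolution
#' matrix, classifying entries strictly greater than the threshold as
#' active. TPR = TP/(TP+FN), FPR = FP/(FP+TN), PPV = TP/(TP+FP); at
#' thresholds with no positives the undefined PPV is replaced by the PPV of
#' the highest threshold below 1 that has positives (horizontal-asymptote
#' convention). The ROC curve is augmented with the (0,0) and (1,1)
#' endpoints; areas are trapezoidal over sorted abscissae.
#'
#' @param m_norm Column-normalized matrix (or an `empirical_resolution`,
#'   normalized internally).
#' @param thresholds Descending grid in `[0, 1]` (default 1001 evenly
#'   spaced values).
#' @return A `roc_prc` object: `curve` tibble
#'   (`threshold, tp, fp, tn, fn, tpr, fpr, ppv`), `auroc`, `auprc`.
#' @export
roc_prc <- function(m_norm, thresholds = seq(1, 0, length.out = 1001)) {
  if (inherits(m_norm, "empirical_resolution")) m_norm <- normalize_columns(m_norm)
  m_norm <- as.matrix(m_norm)
  if (anyNA(m_norm)) {
    keep <- !apply(is.na(m_norm), 2, any)
    m_norm <- m_norm[keep, keep, drop = FALSE]
  }
  thresholds <- sort(as.numeric(thresholds), decreasing = TRUE)
  n <- nrow(m_norm)
  d <- sort(diag(m_norm))
  o <- sort(m_norm[row(m_norm) != col(m_norm)])
  n_off <- length(o)
  tp <- n - findInterval(thresholds, d) # strictly greater than T
  fp <- n_off - findInterval(thresholds, o)
  fn <- n - tp
  tn <- n_off - fp
  tpr <- tp / n
  fpr <- fp / n_off
  ppv <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  if (anyNA(ppv)) {
    with_pos <- which(tp + fp > 0)
    fill <- if (length(with_pos)) ppv[min(with_pos)] else 0
    ppv[is.na(ppv)] <- fill
  }
  auroc <- trapezoid(c(0, fpr, 1), c(0, tpr, 1))
  auprc <- trapezoid(tpr, ppv)
  structure(list(curve = tibble::tibble(threshold = thresholds, tp = tp,
                                        fp = fp, tn = tn, fn = fn,
                                        tpr = tpr, fpr = fpr, ppv = ppv),
                 auroc = auroc, auprc = auprc, n_patches = n),
            class = "roc_prc")
}

#' @export
print.roc_prc <- function(x, ...) {
  cat(sprintf("<roc_prc> %d patches, %d thresholds, AUROC = %.4f, AUPRC = %.4f\n",
              x$n_patches, nrow(x$curve), x$auroc, x$auprc))
  invisible(x)
}

#' @rdname roc_prc
#' @param x A `roc_prc` object.
#' @param ... Unused.
#' @method tidy roc_prc
#' @export
tidy.roc_prc <- function(x, ...) x$curve

#' @rdname roc_prc
#' @method glance roc_prc
#' @export
glance.roc_prc <- function(x, ...) {
  tibble::tibble(auroc = x$auroc, auprc = x$auprc, n_patches = x$n_patches)
}

#' Per-patch fidelity metrics of an empirical resolution run
#'
#' Computes peak localization error, spatial dispersion and
#' center-of-gravity error for every patch from the source-level estimate
#' profiles of an [empirical_resolution()] run. All-zero estimates (typical
#' for MxNE at strong regularization) yield `NA` metrics and are flagged in
#' `zero_estimate`; their fraction is a reported statistic, not an error.
#'
#' @param er An `empirical_resolution`.
#' @param space The `source_space` used.
#' @param parc The `parcellation` used.
#' @return Tibble with one row per patch: `patch`, `size`, `center`, `pe`,
#'   `sd`, `ecg`, `zero_estimate`; attribute `zero_frac`.
#' @export
fidelity_metrics <- function(er, space, parc) {
  centers <- patch_centers(parc, space)
  rows <- purrr::map(seq_len(parc$n_patches), function(j) {
    x <- er$spread[, j]
    if (anyNA(x)) x <- rep(0, length(x)) # failed column -> treated as zero/NA
    tibble::tibble(
      patch = j,
      size = length(parc$patches[[j]]),
      center = centers[j],
      pe = peak_error(x, space, parc$patches[[j]]),
      sd = spatial_dispersion(x, space),
      ecg = cog_error(x, space, space$positions[centers[j], ]),
      zero_estimate = all(x == 0)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "zero_frac") <- mean(out$zero_estimate)
  out
}
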