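# ggplot2 displays for each result type.

#' @importFrom ggplot2 autoplot
NULL

#' Plot an empirical (or patch-reduced) resolution matrix
#'
#' Heatmap of the column-normalized matrix; the diagonal of a faithful
#' estimator dominates.
#'
#' @param object An `empirical_resolution`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot empirical_resolution
#' @export
autoplot.empirical_resolution <- function(object, ...) {
  m <- normalize_columns(object)
  df <- tidyr::expand_grid(activated = seq_len(ncol(m)),
                           observed = seq_len(nrow(m)))
  df$value <- as.vector(m)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$activated, y = .data$observed,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "normalized\namplitude") +
    ggplot2::labs(x = "activated patch", y = "observed patch",
                  title = sprintf("%s, SNR = %s", object$method,
                                  format(object$snr)))
}

#' Plot ROC and PRC curves
#'
#' @param object A `roc_prc`.
#' @param ... Unused.
#' @return A ggplot with ROC and PRC panels.
#' @method autoplot roc_prc
#' @export
autoplot.roc_prc <- function(object, ...) {
  cur <- object$curve
  df <- dplyr::bind_rows(
    tibble::tibble(panel = "ROC", x = cur$fpr, y = cur$tpr),
    tibble::tibble(panel = "PRC", x = cur$tpr, y = cur$ppv))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path() +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = "FPR (ROC) / TPR (PRC)", y = "TPR (ROC) / PPV (PRC)",
                  title = sprintf("AUROC = %.3f, AUPRC = %.3f",
                                  object$auroc, object$auprc))
}

#' Plot a fitted AUROC(SNR) sigmoid
#'
#' @param object A `sigmoid_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sigmoid_fit
#' @export
autoplot.sigmoid_fit <- function(object, ...) {
  grid <- tibble::tibble(log10_snr = seq(min(object$data$log10_snr),
                                         max(object$data$log10_snr),
                                         length.out = 200))
  grid$auroc <- object$a * tanh(object$b * grid$log10_snr + object$c) + object$d
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$log10_snr, y = .data$auroc)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid) +
    ggplot2::labs(x = "log10 SNR", y = "AUROC",
                  title = sprintf("a tanh(b log10 SNR + c) + d, r2 = %.3f",
                                  object$r2))
}

#' Plot an experiment summary
#'
#' Median localization error, spatial dispersion and AUROC as a function of
#' SNR per estimator (finite nonzero SNR points).
#'
#' @param object A `fidelity_experiment`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fidelity_experiment
#' @export
autoplot.fidelity_experiment <- function(object, ...) {
  s <- object$summary[is.finite(object$summary$snr) & object$summary$snr > 0, ]
  df <- tidyr::pivot_longer(
    s[, c("method", "snr", "pe", "sd", "auroc")],
    cols = c("pe", "sd", "auroc"), names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$snr, y = .data$value,
                                   color = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "SNR", y = NULL)
}
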