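#' Analytic resolution matrix
#'
#' `R = K G`: columns are point-spread functions, rows cross-talk functions
#' of a linear estimator (standardization weights already folded into `K`).
#'
#' @param kernel An `inverse_kernel`.
#' @param gain A `gain_matrix`.
#' @return A `resolution_matrix` with fields `values` (sources x sources),
#'   `method`, `lambda2`.
#' @export
analytic_resolution <- function(kernel, gain) {
  if (ncol(kernel$K) != nrow(gain$values) ||
      nrow(kernel$K) != ncol(gain$values)) {
    stop_invalid("kernel and gain dimensions disagree (R = KG must be square)")
  }
  structure(list(values = kernel$K %*% gain$values,
                 method = kernel$method, lambda2 = kernel$lambda2),
            class = "resolution_matrix")
}

#' @export
print.resolution_matrix <- function(x, ...) {
  cat(sprintf("<resolution_matrix> %s, %d x %d, lambda2 = %.3g\n",
              x$method, nrow(x$values), ncol(x$values), x$lambda2))
  invisible(x)
}

#' Uniform patch activation matrix
#'
#' Constant-amplitude activation of one patch: `X[k, t] = amplitude` for
#' dipoles `k` in the patch, 0 elsewhere, over `duration * sampling_rate`
#' samples (defaults: 10 nAm for 100 ms at 1000 Hz).
#'
#' @param parc A `parcellation`.
#' @param patch Patch index.
#' @param n_sources Total number of dipoles.
#' @param amplitude Dipole moment in A m.
#' @param duration Activation duration in seconds.
#' @param sampling_rate Hz.
#' @return `n_sources x n_times` source matrix.
#' @export
patch_activation <- function(parc, patch, n_sources, amplitude = 1e-8,
                             duration = 0.1, sampling_rate = 1000) {
  patch <- check_count(patch, "patch")
  if (patch > parc$n_patches) stop_invalid("patch index %d out of range", patch)
  if (amplitude <= 0 || duration <= 0) {
    stop_invalid("amplitude and duration must be positive")
  }
  n_t <- as.integer(round(duration * sampling_rate))
  X <- matrix(0, n_sources, n_t)
  X[parc$patches[[patch]], ] <- amplitude
  X
}

# n_sources x n_patches matrix of per-patch constant activation patterns.
activation_patterns <- function(parc, n_sources, amplitude) {
  A <- matrix(0, n_sources, parc$n_patches)
  for (j in seq_len(parc$n_patches)) A[parc$patches[[j]], j] <- amplitude
  A
}

#' Signal scaling factor for a target mean SNR
#'
#' Computes the dimensionless `alpha` multiplying the signal so that the
#' mean amplitude SNR across patch activations and sensor modalities equals
#' `target_snr`: per modality, the RMS amplitude of each patch's sensor
#' signal (over that modality's sensors and time) is averaged over patches
#' and divided by the modality's noise RMS; `alpha` is `target_snr` divided
#' by the mean of these modality ratios.
#'
#' @param gain A `gain_matrix` (its `modality` labels define the sets).
#' @param patterns `n_sources x n_patches` activation-pattern matrix
#'   (see `patch_activation`; time-constant, so one column per patch).
#' @param noise `n_sensors x n` noise matrix (columns may pool several
#'   draws); ignored when `target_snr` is infinite.
#' @param target_snr Target amplitude SNR (>= 0 or `Inf`).
#' @return An `snr_spec` with fields `target_snr`, `alpha`, `noise_omitted`.
#' @export
snr_alpha <- function(gain, patterns, noise, target_snr) {
  target_snr <- check_scalar(target_snr, "target_snr", min = 0, allow_inf = TRUE)
  if (is.infinite(target_snr)) {
    return(structure(list(target_snr = Inf, alpha = 1, noise_omitted = TRUE),
                     class = "snr_spec"))
  }
  S <- gain$values %*% patterns # n_sensors x n_patches, constant over time
  sets <- modality_sets(gain)
  ratios <- vapply(sets, function(idx) {
    sig <- sqrt(colMeans(S[idx, , drop = FALSE]^2)) # per-patch RMS
    nz <- sqrt(mean(noise[idx, , drop = FALSE]^2))
    if (nz == 0) stop_invalid("zero-energy noise with a finite target SNR")
    mean(sig) / nz
  }, numeric(1))
  structure(list(target_snr = target_snr, alpha = target_snr / mean(ratios),
                 noise_omitted = FALSE),
            class = "snr_spec")
}

# Patch-mean reduction of |x| profiles: columns of `m` are n_sources
# vectors; returns n_patches x ncol(m).
reduce_to_patches <- function(m, parc) {
  sizes <- lengths(parc$patches)
  rowsum(abs(m), group = parc$patch_of_source, reorder = TRUE) / sizes
}

#' Empirical resolution matrix from simulated patch activations
#'
#' Activates each patch in turn (uniform constant amplitude), scales the
#' signal to the target mean SNR, superposes a fresh evoked-noise draw per
#' patch, reconstructs with the requested estimator, and reduces the
#' absolute source estimates to patch means over time:
#' `R_hat[i, j] = sum_t sum_{k in P_i} |X_hat[k, t]| / (n_t |P_i|)`.
#'
#' The epoch set is split into an evoked pool (averaged noise added to the
#' data) and a held-out covariance pool (estimator's noise covariance).
#' `snr = Inf` omits the noise term entirely; `snr = 0` keeps the noise and
#' sets `alpha = 0`. Unless `lambda2` is given, `lambda2 = SNR^-2` (capped
#' via [snr_lambda2()]). The covariance used for kernels is balanced to the
#' gain scale when `balance = TRUE` (see [balance_covariance()]).
#'
#' @param method `"MNE"`, `"dSPM"`, `"sLORETA"`, `"eLORETA"` or `"MxNE"`.
#' @param space A `source_space`.
#' @param parc A `parcellation`.
#' @param gain A `gain_matrix`.
#' @param epochs An `epoch_set` of simulated resting noise.
#' @param snr Target amplitude SNR (>= 0 or `Inf`).
#' @param lambda2 Optional regularization override for linear methods.
#' @param amplitude Patch dipole moment, A m.
#' @param duration Activation duration, s.
#' @param n_evoked Epochs drawn for the evoked pool.
#' @param loading Diagonal loading for covariance estimation.
#' @param mxne An [mxne_config()] (MxNE only).
#' @param seed Integer seed driving the epoch split and all noise draws.
#' @param balance Balance the covariance to the gain scale for kernels.
#' @return An `empirical_resolution` with `values` (patch x patch, column j
#'   = response to activation of patch j), `spread` (n_sources x n_patches
#'   time-averaged |estimate| profiles), `alpha`, `lambda2`, `failed`
#'   (indices of patches whose estimator failed; columns are `NA`).
#' @export
empirical_resolution <- function(method, space, parc, gain, epochs,
                                 snr = Inf, lambda2 = NULL,
                                 amplitude = 1e-8, duration = 0.1,
                                 n_evoked = 49L, loading = 0.05,
                                 mxne = mxne_config(), seed = 1L,
                                 balance = TRUE) {
  method <- match.arg(method, c("MNE", "dSPM", "sLORETA", "eLORETA", "MxNE"))
  validate_parcellation(parc, space)
  snr <- check_scalar(snr, "snr", min = 0, allow_inf = TRUE)
  n_src <- space$n_sources
  n_p <- parc$n_patches
  n_t <- as.integer(round(duration * epochs$sampling_rate))

  pools <- split_epochs(epochs, n_evoked, seed = derive_seed(seed, 31L))
  cov <- estimate_covariance(pools$covariance, loading)
  kcov <- if (balance) balance_covariance(gain, cov) else cov
  if (is.null(lambda2)) lambda2 <- snr_lambda2(snr)

  patterns <- activation_patterns(parc, n_src, amplitude)
  if (is.infinite(snr)) {
    noise_list <- NULL
    spec <- snr_alpha(gain, patterns, NULL, Inf)
  } else {
    noise_list <- lapply(seq_len(n_p), function(j) {
      evoked_noise(pools$evoked, n_t, seed = derive_seed(seed, 100L + j))
    })
    spec <- snr_alpha(gain, patterns, do.call(cbind, noise_list), snr)
  }

  kernel <- if (method != "MxNE") linear_kernel(method, gain, kcov, lambda2)

  S <- gain$values %*% patterns # per-patch signal topographies
  spread <- matrix(NA_real_, n_src, n_p)
  failed <- integer(0)
  for (j in seq_len(n_p)) {
    Y <- spec$alpha * S[, j] %o% rep(1, n_t)
    if (!is.null(noise_list)) Y <- Y + noise_list[[j]]
    est <- tryCatch({
      if (method == "MxNE") mxne_solve(gain, Y, kcov, mxne)$X
      else apply_kernel(kernel, Y)
    }, error = function(e) NULL)
    if (is.null(est)) failed <- c(failed, j) else spread[, j] <- rowMeans(abs(est))
  }
  values <- matrix(NA_real_, n_p, n_p)
  ok <- setdiff(seq_len(n_p), failed)
  if (length(ok)) {
    values[, ok] <- reduce_to_patches(spread[, ok, drop = FALSE], parc)
  }
  if (length(failed)) {
    warning(sprintf("estimator failed on %d patch(es); columns flagged NA",
                    length(failed)))
  }
  structure(list(values = values, spread = spread, method = method,
                 snr = snr, lambda2 = lambda2, alpha = spec$alpha,
                 amplitude = amplitude, duration = duration,
                 seed = as.integer(seed), failed = failed),
            class = "empirical_resolution")
}

#' @export
print.empirical_resolution <- function(x, ...) {
  cat(sprintf("<empirical_resolution> %s, %d patches, SNR = %s, alpha = %.3g, seed %d\n",
              x$method, nrow(x$values), format(x$snr), x$alpha, x$seed))
  invisible(x)
}

#' Patch-reduce an analytic resolution matrix
#'
#' Applies each patch's constant activation to the analytic resolution
#' matrix and reduces the absolute response to patch means — the noiseless
#' single-time-point counterpart of [empirical_resolution()], used for the
#' infinite-SNR convergence check.
#'
#' @param res A `resolution_matrix`.
#' @param parc A `parcellation`.
#' @param amplitude Activation amplitude, A m.
#' @return `n_patches x n_patches` matrix.
#' @export
patch_reduce <- function(res, parc, amplitude = 1e-8) {
  patterns <- activation_patterns(parc, ncol(res$values), amplitude)
  reduce_to_patches(res$values %*% patterns, parc)
}
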